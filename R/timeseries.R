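#' Simple exponential smoothing
#'
#' The one-parameter recurrence `s_1 = x_1`, `s_t = alpha * x_t +
#' (1 - alpha) * s_{t-1}`. The smoothing constant may be given directly as
#' `alpha`, or through a span `k` via the exponential-moving-average
#' convention `alpha = 2 / (k + 1)` (the default span 7 gives `alpha = 0.25`).
#'
#' @param x Numeric series (finite, non-empty).
#' @param alpha Smoothing constant in `(0, 1]`; overrides `k` when given.
#' @param k Span; used only when `alpha` is `NULL`.
#' @return Smoothed series of the same length.
#' @export
ses_smooth <- function(x, alpha = NULL, k = 7) {
  if (length(x) == 0L || any(!is.finite(x))) stop_arg("x must be non-empty and finite")
  if (is.null(alpha)) {
    if (!is_number(k) || k <= 0) stop_arg("k must be positive")
    alpha <- 2 / (k + 1)
  }
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) {
    stop_arg("alpha must lie in (0, 1]")
  }
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1L]))
}

#' Multiplicative STL decomposition
#'
#' Decomposes a positive monthly series into trend, seasonal and remainder
#' factors, `x_t = T_t * S_t * R_t`, by running additive loess-based STL
#' (Cleveland's inner/outer loops, via [stats::stl()]) on the log series and
#' exponentiating the components back. After decomposition the seasonal
#' component is renormalised so that the log-seasonal factors average zero —
#' i.e. the seasonal factors have geometric mean one — over every full
#' period window (the balancing shift is absorbed into the trend), and the
#' remainder is recomputed so the multiplicative closure holds to machine
#' precision.
#'
#' A Shapiro-Wilk normality p-value for the log remainder is attached as a
#' diagnostic of the decomposition's adequacy (an approximately normal log
#' remainder supports the multiplicative model).
#'
#' @param x Positive numeric series with at least `2 * period` observations.
#' @param period Seasonal period (12 for monthly data).
#' @param s_window Odd loess span for the seasonal smoother (default 13).
#' @param robust Use robustness (outer-loop) iterations; 2 outer iterations
#'   are run when `TRUE`.
#' @param start_month Calendar month (1-12) of the first observation.
#' @return A `stl_decomposition`: data frame with columns `t`, `trend`,
#'   `seasonal`, `remainder` (all multiplicative factors) and attributes
#'   `series`, `period`, `start_month`, `mode` (`"multiplicative"`) and
#'   `shapiro_p`.
#' @export
stl_decompose <- function(x, period = 12L, s_window = 13L, robust = FALSE,
                          start_month = 1L) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_arg("series contains non-finite values; clean first")
  if (any(x <= 0)) {
    stop_arg("series contains values <= 0; the multiplicative (log) model ",
             "requires positive values - clean/impute first")
  }
  if (!is_count(period) || period < 2L) stop_arg("period must be an integer >= 2")
  if (length(x) < 2L * period) {
    stop_arg("need at least 2 * period = ", 2L * period, " observations, got ",
             length(x))
  }
  if (!is_count(s_window) || s_window < 3L || s_window %% 2L == 0L) {
    stop_arg("s_window must be an odd integer >= 3")
  }
  if (!is_count(start_month) || start_month < 1L || start_month > 12L) {
    stop_arg("start_month must be in 1..12")
  }
  lx <- log(x)
  if (length(x) > 2L * period) {
    # inner loop run to near-convergence (10 iterations) so no trend leaks
    # into the seasonal on trend-only series; locally constant (degree 0)
    # cycle-subseries smoothing keeps the seasonal stiff under pure noise
    fit <- stats::stl(stats::ts(lx, frequency = period), s.window = s_window,
                      s.degree = 0L, inner = 10L, robust = robust,
                      outer = if (robust) 2L else 0L)
    seas <- as.numeric(fit$time.series[, "seasonal"])
    trend <- as.numeric(fit$time.series[, "trend"])
  } else {
    # exactly two full periods: stats::stl requires more, so use a single
    # loess-trend / periodic-seasonal pass (one STL inner iteration with a
    # periodic seasonal smoother)
    tt <- seq_along(lx)
    cyc <- ((tt - 1L) %% period) + 1L
    trend <- stats::fitted(stats::loess(lx ~ tt, span = 0.75, degree = 1L))
    for (iter in 1:2) {
      seas_m <- tapply(lx - trend, cyc, mean)
      seas <- as.numeric(seas_m[cyc]) - mean(seas_m)
      trend <- stats::fitted(stats::loess((lx - seas) ~ tt, span = 0.75,
                                          degree = 1L))
    }
    seas_m <- tapply(lx - trend, cyc, mean)
    seas <- as.numeric(seas_m[cyc]) - mean(seas_m)
  }
  n <- length(x)
  n_full <- n %/% period
  # geometric-mean-1 normalisation over each full period window
  for (w in seq_len(n_full)) {
    idx <- ((w - 1L) * period + 1L):(w * period)
    m <- mean(seas[idx])
    seas[idx] <- seas[idx] - m
    trend[idx] <- trend[idx] + m
  }
  rem <- lx - trend - seas  # recomputed: closure exact by construction
  shapiro_p <- tryCatch(stats::shapiro.test(rem)$p.value,
                        error = function(e) NA_real_)
  out <- data.frame(t = seq_len(n), trend = exp(trend), seasonal = exp(seas),
                    remainder = exp(rem))
  attr(out, "series") <- x
  attr(out, "period") <- as.integer(period)
  attr(out, "start_month") <- as.integer(start_month)
  attr(out, "mode") <- "multiplicative"
  attr(out, "shapiro_p") <- shapiro_p
  class(out) <- c("stl_decomposition", "data.frame")
  out
}

#' @export
print.stl_decomposition <- function(x, ...) {
  cat("<stl_decomposition> multiplicative, n = ", nrow(x),
      ", period = ", attr(x, "period"),
      ", Shapiro-Wilk p(log remainder) = ",
      format(attr(x, "shapiro_p"), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Trend and seasonal strength of a decomposition
#'
#' The variance-ratio features
#' \deqn{F_T = \max\left(0, 1 - \frac{Var(R_t)}{Var(T_t + R_t)}\right), \qquad
#'       F_S = \max\left(0, 1 - \frac{Var(R_t)}{Var(S_t + R_t)}\right),}
#' computed on the additive (log-scale) components of a multiplicative
#' decomposition, with population variances. A series is scored seasonal
#' when `F_S >= 0.4`.
#'
#' @param dec An `stl_decomposition`, or a list/data frame with additive
#'   components `trend`, `seasonal`, `remainder` already on the log scale.
#' @return A `strength_result` list: `F_T`, `F_S`, `is_seasonal`.
#' @export
strength <- function(dec) {
  if (inherits(dec, "stl_decomposition")) {
    comp <- list(trend = log(dec$trend), seasonal = log(dec$seasonal),
                 remainder = log(dec$remainder))
  } else if (all(c("trend", "seasonal", "remainder") %in% names(dec))) {
    comp <- list(trend = as.numeric(dec$trend),
                 seasonal = as.numeric(dec$seasonal),
                 remainder = as.numeric(dec$remainder))
  } else {
    stop_arg("dec must be an stl_decomposition or carry trend/seasonal/remainder")
  }
  n <- length(comp$remainder)
  if (n < 3L) stop_arg("need at least 3 time points")
  if (length(comp$trend) != n || length(comp$seasonal) != n) {
    stop_arg("components must have equal length")
  }
  vr <- pop_var(comp$remainder)
  total <- pop_var(comp$trend + comp$seasonal + comp$remainder)
  ratio_strength <- function(signal) {
    denom <- pop_var(signal + comp$remainder)
    # a component whose variance is numerically zero relative to the series
    # carries no strength (guards exactly-decomposed noiseless series)
    if (denom <= 1e-12 * max(total, 1e-12)) return(0)
    max(0, 1 - vr / denom)
  }
  f_t <- ratio_strength(comp$trend)
  f_s <- ratio_strength(comp$seasonal)
  structure(list(F_T = f_t, F_S = f_s, is_seasonal = f_s >= 0.4),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat("F_T = ", format(x$F_T, digits = 4), ", F_S = ", format(x$F_S, digits = 4),
      if (x$is_seasonal) "  (seasonal: F_S >= 0.4)" else "  (not seasonal: F_S < 0.4)",
      "\n", sep = "")
  invisible(x)
}

#' Seasonal peak months and subseries table
#'
#' Summarises a decomposition's seasonal component per calendar month: the
#' mean seasonal factor per month (the numbers behind a subseries seasonal
#' plot), and the "peak period" — the months whose mean factor lies in the
#' top tercile of the months *and* exceeds 1. With a flat seasonal component
#' the peak set is empty.
#'
#' @param dec An `stl_decomposition` (monthly, period 12).
#' @return A list with `table` (data frame `month`, `month_name`,
#'   `mean_seasonal_factor`) and `peak_months` (integer vector, possibly
#'   empty).
#' @export
seasonal_peak <- function(dec) {
  if (!inherits(dec, "stl_decomposition")) stop_arg("dec must be an stl_decomposition")
  period <- attr(dec, "period")
  if (period != 12L) stop_arg("seasonal_peak expects monthly data (period 12)")
  start_month <- attr(dec, "start_month")
  month_of <- ((start_month - 1L + dec$t - 1L) %% 12L) + 1L
  fac <- tapply(dec$seasonal, month_of, mean)
  months <- as.integer(names(fac))
  tab <- data.frame(month = months, month_name = month_names[months],
                    mean_seasonal_factor = as.numeric(fac))
  tab <- tab[order(tab$month), , drop = FALSE]
  rownames(tab) <- NULL
  k <- ceiling(nrow(tab) / 3)  # top tercile of the 12 months
  cutoff <- sort(tab$mean_seasonal_factor, decreasing = TRUE)[k]
  # ">1" with a relative guard so a numerically flat seasonal never peaks
  peaks <- tab$month[tab$mean_seasonal_factor >= cutoff &
                       tab$mean_seasonal_factor > 1 + 1e-9]
  list(table = tab, peak_months = as.integer(peaks))
}

#' Decompose every region of a panel
#'
#' Runs [stl_decompose()] on each region's monthly series (regions with any
#' missing or non-positive value are rejected — clean first). A `"national"`
#' pseudo-region, the across-region mean of the index at each month, is
#' prepended when `national = TRUE`.
#'
#' @param panel A cleaned `search_panel` (no `NA`, all values > 0).
#' @param national Include the across-region mean series as `"national"`.
#' @param ses_alpha Optional smoothing constant: when non-`NULL` each series
#'   is [ses_smooth()]ed before decomposition.
#' @inheritParams stl_decompose
#' @return Named list of `stl_decomposition` objects.
#' @export
decompose_panel <- function(panel, s_window = 13L, robust = FALSE,
                            national = TRUE, ses_alpha = NULL) {
  panel <- as_search_panel(panel)
  if (anyNA(panel$value)) stop_arg("panel has missing values; run clean_panel first")
  series <- split(panel, panel$region_id)
  out <- list()
  if (national) {
    nat <- stats::aggregate(panel$value,
                            by = list(year = panel$year, month = panel$month),
                            FUN = mean)
    nat <- nat[order(nat$year, nat$month), , drop = FALSE]
    x <- nat$x
    if (!is.null(ses_alpha)) x <- ses_smooth(x, alpha = ses_alpha)
    out$national <- stl_decompose(x, s_window = s_window, robust = robust,
                                  start_month = nat$month[1L])
  }
  for (rid in names(series)) {
    d <- series[[rid]]
    x <- d$value
    if (!is.null(ses_alpha)) x <- ses_smooth(x, alpha = ses_alpha)
    out[[rid]] <- stl_decompose(x, s_window = s_window, robust = robust,
                                start_month = d$month[1L])
  }
  out
}

#' Strength table for a set of decompositions
#'
#' @param decs Named list of `stl_decomposition` objects, as returned by
#'   [decompose_panel()].
#' @return Data frame `region_id`, `F_T`, `F_S`, `is_seasonal`.
#' @export
panel_strength <- function(decs) {
  rows <- lapply(names(decs), function(rid) {
    s <- strength(decs[[rid]])
    data.frame(region_id = rid, F_T = s$F_T, F_S = s$F_S,
               is_seasonal = s$is_seasonal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subseries table for a set of decompositions
#'
#' Long table of per-month mean seasonal factors, one row per
#' (region, calendar month).
#'
#' @inheritParams panel_strength
#' @return Data frame `region_id`, `month`, `mean_seasonal_factor`.
#' @export
subseries_table <- function(decs) {
  rows <- lapply(names(decs), function(rid) {
    tab <- seasonal_peak(decs[[rid]])$table
    data.frame(region_id = rid, month = tab$month,
               mean_seasonal_factor = tab$mean_seasonal_factor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
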