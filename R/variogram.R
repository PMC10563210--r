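#' Empirical semivariogram
#'
#' Method-of-moments estimator
#' \deqn{\hat\gamma(h) = \frac{1}{2 N(h)} \sum_{(i,j) \in N(h)} (z_i - z_j)^2}
#' over equal-width lag bins on `(0, max_lag]`. Bins with no pairs are
#' dropped.
#'
#' @param coords Two-column matrix of planar point coordinates (>= 10 points).
#' @param values Numeric vector of point values.
#' @param n_bins Number of equal-width lag bins (default 12).
#' @param max_lag Largest lag considered; defaults to half the maximum
#'   pairwise distance.
#' @return An `empirical_variogram` data frame: `h` (mean lag per bin),
#'   `gamma`, `np` (pair count).
#' @export
empirical_semivariogram <- function(coords, values, n_bins = 12L, max_lag = NULL) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  n <- nrow(xy)
  if (n < 10L) stop_arg("need at least 10 points")
  if (length(z) != n || any(!is.finite(z)) || any(!is.finite(xy))) {
    stop_arg("coords/values must be finite and of matching length")
  }
  d <- stats::dist(xy)
  dmax <- max(d)
  if (dmax == 0) stop_arg("all points coincident")
  if (is.null(max_lag)) max_lag <- dmax / 2
  if (!is_number(max_lag) || max_lag <= 0 || max_lag > dmax * (1 + 1e-9)) {
    stop_arg("max_lag must be positive and <= the maximum pairwise distance")
  }
  if (!is_count(n_bins) || n_bins < 1L) stop_arg("n_bins must be a positive integer")
  dv <- as.numeric(d)
  sq <- as.numeric(stats::dist(cbind(z)))^2  # (z_i - z_j)^2 in matching pair order
  keep <- dv > 0 & dv <= max_lag
  dv <- dv[keep]; sq <- sq[keep]
  if (length(dv) == 0L) stop_arg("no pairs within max_lag")
  bin <- pmin(ceiling(dv / (max_lag / n_bins)), n_bins)
  out <- data.frame(
    h = as.numeric(tapply(dv, bin, mean)),
    gamma = as.numeric(tapply(sq, bin, mean)) / 2,
    np = as.integer(tapply(sq, bin, length)))
  out <- out[order(out$h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Theoretical semivariogram models
#'
#' Evaluates gamma(h) for the spherical, exponential or gaussian family with
#' nugget `c0`, partial sill `c` and range `a`. For the exponential and
#' gaussian families `a` is the practical range (95% of the sill). In all
#' families `gamma(0) = 0` exactly.
#'
#' @param model A `variogram_model` (see [fit_variogram()]).
#' @param h Vector of non-negative lags.
#' @return Vector of semivariances.
#' @export
variogram_gamma <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  h <- as.numeric(h)
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$family,
    spherical = ifelse(h >= a, c1, c1 * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = c1 * (1 - exp(-3 * h / a)),
    gaussian = c1 * (1 - exp(-3 * (h / a)^2)),
    stop_arg("unknown family ", model$family))
  ifelse(h > 0, c0 + g, 0)
}

new_variogram_model <- function(family, nugget, psill, range, wrss = NA_real_,
                                converged = TRUE) {
  if (nugget < 0 || psill < 0 || range <= 0) {
    stop_arg("variogram model needs nugget >= 0, psill >= 0, range > 0")
  }
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, wrss = wrss, converged = converged),
            class = "variogram_model")
}

#' Construct a variogram model directly
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget Nugget variance `c0 >= 0`.
#' @param psill Partial sill `c >= 0` (total sill = `nugget + psill`).
#' @param range Range `a > 0` (practical range for exponential/gaussian).
#' @return A `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget = 0, psill = 1, range = 1) {
  family <- match.arg(family)
  new_variogram_model(family, nugget, psill, range)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with weights `N(h) / h^2` (Cressie-style: short,
#' well-populated lags dominate), non-negativity constraints on nugget and
#' partial sill, and multiple range starts to avoid local minima.
#'
#' @param emp An `empirical_variogram` with at least 4 bins.
#' @param family Model family (default spherical).
#' @return A `variogram_model` with the weighted RSS attached as `wrss`.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian")) {
  stopifnot(inherits(emp, "empirical_variogram"))
  family <- match.arg(family)
  if (nrow(emp) < 4L) stop_arg("need at least 4 variogram bins")
  w <- emp$np / emp$h^2
  obj <- function(par) {
    m <- new_variogram_model(family, max(par[1L], 0), max(par[2L], 0),
                             max(par[3L], 1e-12))
    sum(w * (variogram_gamma(m, emp$h) - emp$gamma)^2)
  }
  sill0 <- max(mean(emp$gamma[emp$h >= stats::median(emp$h)]), 1e-12)
  nug0 <- max(min(emp$gamma[1L], sill0), 0)
  hmax <- max(emp$h)
  best <- NULL
  for (a0 in hmax * c(1 / 3, 2 / 3, 1)) {
    fit <- tryCatch(
      stats::optim(c(nug0 * 0.5, max(sill0 - nug0 * 0.5, 1e-8), a0), obj,
                   method = "L-BFGS-B",
                   lower = c(0, 0, hmax * 1e-4),
                   upper = c(Inf, Inf, hmax * 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_arg("variogram fit failed for every start")
  if (best$convergence != 0) {
    warning("variogram optimizer did not report convergence; returning best point",
            call. = FALSE)
  }
  new_variogram_model(family, best$par[1L], best$par[2L], best$par[3L],
                      wrss = best$value, converged = best$convergence == 0)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("<variogram_model> ", x$family, ": nugget = ", format(x$nugget, digits = 4),
      ", partial sill = ", format(x$psill, digits = 4),
      ", range = ", format(x$range, digits = 4),
      if (!is.na(x$wrss)) paste0(", WRSS = ", format(x$wrss, digits = 4)) else "",
      "\n", sep = "")
  invisible(x)
}
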