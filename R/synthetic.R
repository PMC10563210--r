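#' Configuration for the synthetic search-index panel generator
#'
#' Bundles the parameters of the generative model used by
#' [generate_panel()]. The model is multiplicative — trend x month-of-year x
#' spatial region effect x lognormal noise — mirroring the structure the
#' downstream multiplicative (log-scale) decomposition assumes.
#'
#' Defaults emulate a national search-index panel of the kind platform
#' extracts provide: 30 regions on a 6 x 5 grid (about the number of
#' provincial units in a large country), nine years of monthly data starting
#' in 2014, steady multiplicative growth, a spring (Mar-May) seasonal peak,
#' an east-to-west level gradient with local spatial clustering, and modest
#' multiplicative noise.
#'
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols >= 4`.
#' @param n_years Number of years (>= 2; the seasonal decomposition needs at
#'   least two full periods).
#' @param start_year First calendar year of the panel.
#' @param base_level Positive index level of the first month (index units).
#' @param trend_rate Per-year multiplicative growth rate (0.08 = +8%/year).
#' @param seasonal_amplitudes Twelve positive month-of-year factors; they are
#'   renormalised to geometric mean 1 so `base_level` stays interpretable.
#' @param gradient_strength Per-unit-x multiplicative factor: a region one
#'   planar unit further east has its level multiplied by
#'   `1 + gradient_strength`.
#' @param spatial_rho In `[0, 1)`: weight given to the rook-neighbour mean
#'   when smoothing the random region effects (induces positive spatial
#'   autocorrelation beyond the deterministic gradient).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (and of the region-level random effects). 0 gives a noiseless
#'   panel.
#' @param seed Integer seed; equal `(config, seed)` give identical panels.
#' @return A `panel_config` list.
#' @seealso [generate_panel()], [generate_geometry()]
#' @export
panel_config <- function(n_rows = 6L, n_cols = 5L, n_years = 9L,
                         start_year = 2014L, base_level = 100,
                         trend_rate = 0.08,
                         seasonal_amplitudes = spring_peak_amplitudes(),
                         gradient_strength = 0.15, spatial_rho = 0.5,
                         noise_cv = 0.1, seed = 1L) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop_arg("n_rows and n_cols must be positive integers")
  }
  if (n_rows * n_cols < 4L) stop_arg("need at least 4 regions (n_rows * n_cols >= 4)")
  if (!is_count(n_years) || n_years < 2L) {
    stop_arg("n_years must be an integer >= 2 (decomposition needs two full periods)")
  }
  if (!is_number(base_level) || base_level <= 0) stop_arg("base_level must be positive")
  if (!is_number(trend_rate) || trend_rate <= -1) stop_arg("trend_rate must be > -1")
  if (length(seasonal_amplitudes) != 12L || any(!is.finite(seasonal_amplitudes)) ||
      any(seasonal_amplitudes <= 0)) {
    stop_arg("seasonal_amplitudes must be 12 positive finite numbers")
  }
  if (!is_number(spatial_rho) || spatial_rho < 0 || spatial_rho >= 1) {
    stop_arg("spatial_rho must lie in [0, 1)")
  }
  if (!is_number(noise_cv) || noise_cv < 0) stop_arg("noise_cv must be >= 0")
  if (!is_count(seed)) stop_arg("seed must be an integer")
  # normalise to geometric mean 1
  seasonal_amplitudes <- seasonal_amplitudes / exp(mean(log(seasonal_amplitudes)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_years = as.integer(n_years), start_year = as.integer(start_year),
                 base_level = base_level, trend_rate = trend_rate,
                 seasonal_amplitudes = seasonal_amplitudes,
                 gradient_strength = gradient_strength,
                 spatial_rho = spatial_rho, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Month-of-year amplitude profile with a spring peak
#'
#' Twelve multiplicative month factors equal to `peak` in March-May and 1
#' elsewhere, renormalised to geometric mean 1.
#'
#' @param peak Relative height of the March-May months (default 1.25).
#' @return Numeric vector of length 12 with geometric mean 1.
#' @export
spring_peak_amplitudes <- function(peak = 1.25) {
  if (!is_number(peak) || peak <= 0) stop_arg("peak must be positive")
  a <- rep(1, 12L)
  a[3:5] <- peak
  a / exp(mean(log(a)))
}

#' Generate a rectangular grid of square regions
#'
#' Builds `n_rows * n_cols` axis-aligned square cells. x increases eastward
#' (with column index), y northward (with row index); `region_id` encodes
#' `(row, col)` as e.g. `"r02c03"`.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size Positive side length of each square cell (planar units).
#' @return A [region_set] of `n_rows * n_cols` square regions.
#' @export
generate_geometry <- function(n_rows, n_cols, cell_size = 1) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop_arg("n_rows and n_cols must be positive integers")
  }
  if (!is_number(cell_size) || cell_size <= 0) stop_arg("cell_size must be positive")
  ids <- character(n_rows * n_cols)
  polys <- vector("list", n_rows * n_cols)
  cents <- matrix(0, n_rows * n_cols, 2L)
  k <- 0L
  for (row in seq_len(n_rows)) {
    for (col in seq_len(n_cols)) {
      k <- k + 1L
      x0 <- (col - 1L) * cell_size
      y0 <- (row - 1L) * cell_size
      ring <- cbind(x = c(x0, x0 + cell_size, x0 + cell_size, x0, x0),
                    y = c(y0, y0, y0 + cell_size, y0 + cell_size, y0))
      ids[k] <- sprintf("r%02dc%02d", row, col)
      polys[[k]] <- list(ring)
      cents[k, ] <- c(x0 + cell_size / 2, y0 + cell_size / 2)
    }
  }
  new_region_set(ids, polys, cents)
}

#' Generate a synthetic search-index panel
#'
#' Draws one region-by-month panel from the multiplicative model
#' \deqn{x_{rt} = \mathrm{base} \cdot (1+\mathrm{trend})^{(t-1)/12}
#'   \cdot a_{m(t)} \cdot G_r \cdot \varepsilon_{rt},}
#' where \eqn{a_m} are the month-of-year amplitudes, \eqn{G_r} combines the
#' deterministic east-west gradient with a rook-neighbour-smoothed lognormal
#' region effect (smoothing weight `spatial_rho`), and
#' \eqn{\varepsilon_{rt}} is lognormal with mean 1 and coefficient of
#' variation `noise_cv`. The random region effects share `noise_cv` as their
#' coefficient of variation, so `noise_cv = 0` yields an exactly
#' deterministic panel.
#'
#' @param config A [panel_config()].
#' @param regions A [region_set] from [generate_geometry()]; its row/col grid
#'   must match `config`.
#' @return A `search_panel` data frame with columns `region_id`, `year`,
#'   `month`, `value`.
#' @export
generate_panel <- function(config, regions) {
  if (!inherits(config, "panel_config")) stop_arg("config must be a panel_config")
  if (!is_region_set(regions)) stop_arg("regions must be a region_set")
  n_reg <- nrow(regions)
  if (n_reg != config$n_rows * config$n_cols) {
    stop_arg("regions has ", n_reg, " regions but config expects ",
             config$n_rows * config$n_cols)
  }
  n_months <- 12L * config$n_years
  month_of <- rep(1:12, config$n_years)
  year_frac <- (seq_len(n_months) - 1L) / 12
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  set.seed(config$seed)
  # region effects: iid lognormal, one round of rook-neighbour smoothing
  eta <- stats::rnorm(n_reg, 0, sdlog)
  if (config$spatial_rho > 0) {
    W <- build_weights(regions, scheme = "rook")
    nb_mean <- vapply(seq_len(n_reg), function(i) {
      nb <- W$neighbours[[i]]
      if (length(nb) == 0L) eta[i] else mean(eta[nb])
    }, numeric(1L))
    eta <- (1 - config$spatial_rho) * eta + config$spatial_rho * nb_mean
  }
  eta <- eta - mean(eta)
  cx <- regions$cx
  G <- (1 + config$gradient_strength)^(cx - min(cx)) * exp(eta)

  eps <- matrix(stats::rnorm(n_reg * n_months, -sdlog^2 / 2, sdlog),
                nrow = n_reg)
  base_t <- config$base_level * (1 + config$trend_rate)^year_frac *
    config$seasonal_amplitudes[month_of]
  value <- G * exp(eps) * rep(base_t, each = n_reg)

  out <- data.frame(
    region_id = rep(regions$region_id, times = n_months),
    year = rep(config$start_year + (seq_len(n_months) - 1L) %/% 12L, each = n_reg),
    month = rep(month_of, each = n_reg),
    value = as.vector(value),
    stringsAsFactors = FALSE)
  out <- out[order(out$region_id, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  as_search_panel(out)
}

#' Generate an annual prevalence series tied to a panel
#'
#' Builds one value per panel year as a strictly monotone (exponential)
#' transform of the national annual mean index, optionally perturbed before
#' the transform by Gaussian noise with standard deviation `rank_noise`
#' (index units). `rank_noise = 0` therefore preserves the rank order of the
#' annual means exactly; noise much larger than the spread of the annual
#' means destroys it.
#'
#' @param panel A `search_panel` spanning at least two years.
#' @param rank_noise Non-negative standard deviation of the rank-perturbing
#'   noise, in index units.
#' @param seed Integer seed.
#' @param reverse If `TRUE` the transform is strictly decreasing
#'   (anti-concordant series, useful for testing).
#' @param base_value Level of the output series (e.g. prevalent cases per
#'   100,000).
#' @return An `annual_series` data frame with columns `year`, `value`.
#' @export
generate_prevalence <- function(panel, rank_noise = 0, seed = 1L,
                                reverse = FALSE, base_value = 9000) {
  panel <- as_search_panel(panel)
  if (nrow(panel) == 0L) stop_arg("panel is empty")
  a <- tapply(panel$value, panel$year, mean, na.rm = TRUE)
  years <- as.integer(names(a))
  a <- as.numeric(a)
  if (length(a) < 2L) stop_arg("panel must span at least 2 years")
  if (!is_number(rank_noise) || rank_noise < 0) stop_arg("rank_noise must be >= 0")
  set.seed(as.integer(seed))
  z <- a + stats::rnorm(length(a), 0, rank_noise)
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0) s <- max(abs(a), 1)
  dir <- if (isTRUE(reverse)) -1 else 1
  # strictly monotone, log-compressed transform: stays positive and finite
  # for any noise magnitude without saturating into ties
  u <- (z - mean(a)) / s
  value <- base_value * exp(dir * 0.25 * sign(u) * log1p(abs(u)))
  out <- data.frame(year = years, value = value)
  as_annual_series(out)
}

#' Generate a synthetic seasonal demand-term table
#'
#' Emulates the "related demand" feature of search platforms: for each
#' meteorological season, a set of query terms with non-negative search
#' volumes. The lead self-treatment query dominates every season (roughly
#' 30% of the top-8 total) and is boosted in winter; the remaining terms
#' follow a decaying volume profile with lognormal jitter.
#'
#' @param seed Integer seed.
#' @param n_terms Number of distinct terms per season (>= 8).
#' @return A data frame with columns `season`, `term`, `volume`.
#' @export
generate_demand_terms <- function(seed = 1L, n_terms = 10L) {
  if (!is_count(n_terms) || n_terms < 8L) stop_arg("n_terms must be an integer >= 8")
  terms <- c("how to treat migraine quickly and effectively",
             "headache",
             "trigeminal neuralgia",
             "migraine symptoms",
             "what causes migraine",
             "migraine medication",
             "migraine home remedies",
             "tension headache",
             "migraine aura",
             "cluster headache",
             "migraine and sleep",
             "migraine diet")[seq_len(max(n_terms, 8L))]
  seasons <- c("spring", "summer", "autumn", "winter")
  set.seed(as.integer(seed))
  rows <- lapply(seasons, function(s) {
    # lead self-treatment query ~30% of the top-8 total, runner-up ~16%,
    # then a gentle decay; the lead is boosted in winter
    base <- c(300, 165, 140, 110, 90, 75, 65, 55, 40, 30, 22, 16)[seq_along(terms)]
    if (s == "winter") base[1L] <- base[1L] * 1.30
    vol <- base * exp(stats::rnorm(length(terms), 0, 0.06))
    data.frame(season = s, term = terms, volume = vol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
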