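test_that("ses_smooth follows the recurrence and its limits", {
  expect_equal(ses_smooth(c(3, 1, 4, 1, 5), alpha = 1), c(3, 1, 4, 1, 5))
  expect_equal(ses_smooth(rep(7, 10), alpha = 0.3), rep(7, 10))
  expect_equal(ses_smooth(c(0, 1, 1), alpha = 0.5), c(0, 0.5, 0.75))
  # default span 7 gives alpha = 0.25
  x <- c(2, 4, 8)
  expect_equal(ses_smooth(x), ses_smooth(x, alpha = 0.25))
  expect_error(ses_smooth(x, alpha = 0), "alpha")
  expect_error(ses_smooth(x, alpha = 1.5), "alpha")
})

test_that("multiplicative closure holds to 1e-9 and seasonal factors have gm 1", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 4, noise_cv = 0.15,
                      seed = 11)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  for (rid in unique(p$region_id)) {
    x <- p$value[p$region_id == rid]
    d <- stl_decompose(x)
    rel <- abs(d$trend * d$seasonal * d$remainder - x) / x
    expect_lt(max(rel), 1e-9)
    for (w in seq_len(length(x) %/% 12)) {
      idx <- ((w - 1) * 12 + 1):(w * 12)
      expect_equal(exp(mean(log(d$seasonal[idx]))), 1, tolerance = 1e-12)
    }
  }
})

test_that("a constant series decomposes into constant trend and unit factors", {
  d <- stl_decompose(rep(5, 48))
  expect_equal(d$trend, rep(5, 48), tolerance = 1e-6)
  expect_equal(d$seasonal, rep(1, 48), tolerance = 1e-6)
  expect_equal(d$remainder, rep(1, 48), tolerance = 1e-6)
})

test_that("noiseless trend x seasonal structure is recovered", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 6, noise_cv = 0,
                      gradient_strength = 0, spatial_rho = 0)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  x <- p$value[p$region_id == "r01c01"]
  d <- stl_decompose(x)
  true_s <- log(cfg$seasonal_amplitudes[rep(1:12, 6)])
  expect_gt(cor(log(d$seasonal), true_s), 0.99)
  expect_lt(max(abs(d$remainder - 1)), 0.02)
})

test_that("decomposing a pure trend yields no spurious seasonal or remainder", {
  x <- 100 * 1.05^((0:47) / 12)
  d <- stl_decompose(x)
  expect_lt(max(abs(log(d$seasonal))), 1e-6)
  expect_lt(max(abs(log(d$remainder))), 1e-6)
})

test_that("stl_decompose rejects non-positive values and short series", {
  expect_error(stl_decompose(c(rep(1, 30), 0, rep(1, 17))), "clean")
  expect_error(stl_decompose(rep(2, 20)), "observations")
})

test_that("strength formulas match hand-computed variances and their limits", {
  # Var(R) = 0 => both strengths 1
  s <- strength(list(trend = 1:10, seasonal = sin(1:10), remainder = rep(0, 10)))
  expect_equal(s$F_T, 1)
  expect_equal(s$F_S, 1)
  # Var(R) = Var(T + R) => clamped to 0 (constant trend)
  r <- c(0.1, -0.1, 0.1, -0.1)
  s0 <- strength(list(trend = rep(2, 4), seasonal = rep(0, 4), remainder = r))
  expect_equal(s0$F_T, 0)
  # 4-point hand example, population variances computed independently
  tr <- c(1, 2, 3, 4); se <- c(0.5, -0.5, 0.5, -0.5)
  pv <- function(v) mean((v - mean(v))^2)
  expect_f_t <- max(0, 1 - pv(r) / pv(tr + r))
  expect_f_s <- max(0, 1 - pv(r) / pv(se + r))
  s1 <- strength(list(trend = tr, seasonal = se, remainder = r))
  expect_equal(s1$F_T, expect_f_t, tolerance = 1e-12)
  expect_equal(s1$F_S, expect_f_s, tolerance = 1e-12)
  expect_error(strength(list(trend = 1:2, seasonal = 1:2, remainder = 1:2)),
               "3 time points")
})

test_that("is_seasonal applies the 0.4 threshold on F_S", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 5, noise_cv = 0)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  d <- stl_decompose(p$value[p$region_id == "r01c01"])
  s <- strength(d)
  expect_true(s$is_seasonal)
  expect_gte(s$F_S, 0.4)
})

test_that("white-noise series rarely score as seasonal", {
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    x <- exp(rnorm(60, 0, 0.3))
    strength(stl_decompose(x))$F_S
  }, numeric(1))
  expect_gte(mean(hits < 0.4), 0.9)
})

test_that("F_S does not increase with generator noise", {
  med_fs <- vapply(c(0.05, 0.2, 0.6), function(cv) {
    fs <- vapply(1:20, function(s) {
      cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 4, noise_cv = cv,
                          seed = s)
      p <- generate_panel(cfg, generate_geometry(2, 2, 1))
      strength(stl_decompose(p$value[p$region_id == "r01c01"]))$F_S
    }, numeric(1))
    median(fs)
  }, numeric(1))
  expect_true(all(diff(med_fs) <= 0))
})

test_that("peak months follow the top-tercile-above-1 rule", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 6, noise_cv = 0,
                      seasonal_amplitudes = spring_peak_amplitudes(1.2))
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  d <- stl_decompose(p$value[p$region_id == "r01c01"])
  pk <- seasonal_peak(d)
  expect_equal(pk$peak_months, 3:5)  # March, April, May
  expect_equal(nrow(pk$table), 12L)
  # flat seasonal: empty peak set
  dflat <- stl_decompose(rep(10, 48))
  expect_length(seasonal_peak(dflat)$peak_months, 0L)
})

test_that("panel decomposition produces per-region strengths and subseries", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 3, seed = 5)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  decs <- decompose_panel(p)
  expect_named(decs, c("national", region_ids(generate_geometry(2, 2, 1))))
  st <- panel_strength(decs)
  expect_equal(nrow(st), 5L)
  expect_true(all(st$F_S >= 0 & st$F_S <= 1))
  sub <- subseries_table(decs)
  expect_equal(nrow(sub), 5L * 12L)
})
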