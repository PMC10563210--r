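test_that("generated grid geometry has the advertised cells, ids and areas", {
  rs <- generate_geometry(2, 2, 1.0)
  expect_s3_class(rs, "region_set")
  expect_equal(nrow(rs), 4L)
  expect_equal(anyDuplicated(region_ids(rs)), 0L)
  areas <- vapply(region_polygons(rs), function(p) sum(vapply(p, searchscape:::ring_area, numeric(1))), numeric(1))
  expect_equal(unname(areas), rep(1, 4))

  one <- generate_geometry(1, 1, 2.0)
  a1 <- searchscape:::ring_area(region_polygons(one)[[1]][[1]])
  expect_equal(a1, 4.0)

  expect_error(generate_geometry(0, 3), "positive")
})

test_that("rook adjacency of a 3x3 grid matches brute-force edge sharing", {
  rs <- generate_geometry(3, 3, 1.0)
  W <- build_weights(rs, scheme = "rook")
  n_edges <- sum(lengths(W$neighbours)) / 2
  expect_equal(n_edges, 12)  # 3x3 lattice graph
  expect_equal(n_edges, oracle_rook_edges(rs))
})

test_that("degenerate generator reproduces the deterministic trend x seasonal law", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 3, noise_cv = 0,
                      gradient_strength = 0, spatial_rho = 0,
                      base_level = 50, trend_rate = 0.1)
  rs <- generate_geometry(2, 2, 1)
  p <- generate_panel(cfg, rs)
  t_idx <- seq_len(36)
  expected <- 50 * 1.1^((t_idx - 1) / 12) * cfg$seasonal_amplitudes[rep(1:12, 3)]
  for (rid in region_ids(rs)) {
    expect_equal(p$value[p$region_id == rid], expected, tolerance = 1e-12)
  }
})

test_that("equal (config, seed) produce identical panels; all values positive", {
  cfg <- panel_config(n_rows = 3, n_cols = 3, n_years = 2, seed = 42)
  rs <- generate_geometry(3, 3, 1)
  p1 <- generate_panel(cfg, rs)
  p2 <- generate_panel(cfg, rs)
  expect_identical(p1, p2)
  expect_true(all(p1$value > 0))
})

test_that("a pure gradient makes per-region mean index strictly monotone in x", {
  cfg <- panel_config(n_rows = 3, n_cols = 4, n_years = 2, noise_cv = 0,
                      gradient_strength = 0.2, spatial_rho = 0.4)
  rs <- generate_geometry(3, 4, 1)
  p <- generate_panel(cfg, rs)
  means <- tapply(p$value, p$region_id, mean)[region_ids(rs)]
  ord <- order(rs$cx, rs$cy)
  by_x <- tapply(as.numeric(means), rs$cx, mean)
  expect_true(all(diff(as.numeric(by_x)) > 0))
  # within a column all means equal; across columns strictly increasing
  expect_true(all(diff(sort(unique(round(as.numeric(by_x), 9)))) > 0))
})

test_that("flat seasonal amplitudes induce no spurious seasonality", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 4, noise_cv = 0,
                      seasonal_amplitudes = rep(1, 12))
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  x <- p$value[p$region_id == "r01c01"]
  fs <- strength(stl_decompose(x))$F_S
  expect_lt(fs, 0.4)
})

test_that("prevalence is a monotone transform of the annual mean index", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 5)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  prev <- generate_prevalence(p, rank_noise = 0)
  annual <- as.numeric(tapply(p$value, p$year, mean))
  expect_equal(cor(annual, prev$value, method = "spearman"), 1)
  rev <- generate_prevalence(p, rank_noise = 0, reverse = TRUE)
  expect_equal(cor(annual, rev$value, method = "spearman"), -1)
  expect_true(all(prev$value > 0))
})

test_that("overwhelming rank noise decorrelates prevalence from the index", {
  cfg <- panel_config(n_rows = 2, n_cols = 2, n_years = 6, seed = 7)
  p <- generate_panel(cfg, generate_geometry(2, 2, 1))
  annual <- as.numeric(tapply(p$value, p$year, mean))
  big <- 100 * diff(range(annual)) + 100 * mean(annual)
  rhos <- vapply(1:500, function(s) {
    prev <- generate_prevalence(p, rank_noise = big, seed = s)
    cor(annual, prev$value, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("generator config invariants are enforced", {
  expect_error(panel_config(n_rows = 1, n_cols = 2), "at least 4")
  expect_error(panel_config(n_years = 1), "n_years")
  expect_error(panel_config(spatial_rho = 1), "spatial_rho")
  expect_error(panel_config(noise_cv = -0.1), "noise_cv")
  expect_error(panel_config(seasonal_amplitudes = rep(1, 11)), "12")
  # amplitudes are normalised to geometric mean 1
  cfg <- panel_config(seasonal_amplitudes = rep(2, 12))
  expect_equal(exp(mean(log(cfg$seasonal_amplitudes))), 1)
})

test_that("synthetic demand terms give every season at least 8 ranked terms", {
  d <- generate_demand_terms(seed = 3)
  counts <- table(d$season)
  expect_true(all(counts >= 8))
  expect_identical(d, generate_demand_terms(seed = 3))
  expect_true(all(d$volume > 0))
})
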