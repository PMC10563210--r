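test_that("empirical semivariogram matches its defining formula", {
  # constant field: gamma = 0 in every bin
  set.seed(1)
  xy <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  emp <- empirical_semivariogram(xy, rep(4, 15), n_bins = 5)
  expect_true(all(emp$gamma == 0))
  # bin values agree with a brute-force pair loop
  z <- rnorm(15)
  emp2 <- empirical_semivariogram(xy, z, n_bins = 4, max_lag = 8)
  for (k in 1:4) {  # bins of width 8/4 = 2
    o <- oracle_semivariogram_pairs(xy, z, (k - 1) * 2, k * 2)
    row <- emp2[emp2$h > (k - 1) * 2 & emp2$h <= k * 2, , drop = FALSE]
    if (is.null(o)) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$gamma, o$gamma, tolerance = 1e-12)
      expect_equal(row$np, o$np)
    }
  }
  expect_error(empirical_semivariogram(matrix(1, 12, 2), rnorm(12)), "coincident")
})

test_that("two points one bin: gamma = half the squared difference", {
  xy <- rbind(c(0, 0), c(1, 0), c(0, 5), c(1, 5), c(0, 10), c(1, 10),
              c(0, 15), c(1, 15), c(0, 20), c(1, 20))
  z <- rep(c(0, 2), 5)
  emp <- empirical_semivariogram(xy, z, n_bins = 1, max_lag = 1.5)
  # only the five horizontal pairs fall in (0, 1.5]; each contributes (2-0)^2
  expect_equal(emp$gamma, 2.0)
  expect_equal(emp$np, 5L)
})

test_that("an iid field has a flat semivariogram near its variance", {
  set.seed(42)
  xy <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  z <- rnorm(400, 0, 2)
  emp <- empirical_semivariogram(xy, z, n_bins = 8)
  expect_true(all(abs(emp$gamma - 4) / 4 < 0.15))
})

test_that("variogram fitting recovers exact spherical points and the nugget limit", {
  true <- variogram_model("spherical", nugget = 0, psill = 1, range = 10)
  h <- seq(0.5, 14, length.out = 12)
  emp <- structure(data.frame(h = h, gamma = variogram_gamma(true, h),
                              np = rep(30L, 12)),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_lt(abs(fit$psill - 1) / 1, 0.05)
  expect_lt(abs(fit$range - 10) / 10, 0.05)
  expect_lt(fit$nugget, 0.05)
  # flat empirical curve: pure nugget
  emp2 <- structure(data.frame(h = h, gamma = rep(2, 12), np = rep(30L, 12)),
                    class = c("empirical_variogram", "data.frame"))
  fit2 <- fit_variogram(emp2, "spherical")
  expect_lt(fit2$psill, 0.05)
  expect_equal(fit2$nugget, 2, tolerance = 0.05)
  # gamma(0) = 0 regardless of parameters
  expect_equal(variogram_gamma(fit, 0), 0)
  expect_equal(variogram_gamma(fit2, 0), 0)
})

test_that("polynomial trend removal is an exact least-squares projection", {
  set.seed(3)
  xy <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  # exactly quadratic surface: residuals vanish
  z <- 2 + 0.5 * xy[, 1] - xy[, 2] + 0.1 * xy[, 1]^2 -
    0.2 * xy[, 1] * xy[, 2] + 0.05 * xy[, 2]^2
  tr <- remove_trend(xy, z, order = 2)
  expect_lt(max(abs(tr$residuals)), 1e-8)
  # order 0: residuals are deviations from the mean
  z2 <- rnorm(40)
  tr0 <- remove_trend(xy, z2, order = 0)
  expect_equal(tr0$residuals, z2 - mean(z2), tolerance = 1e-12)
  expect_lt(abs(mean(tr0$residuals)), 1e-9)
  # order 1 on a tilted noisy plane reduces variance
  z3 <- 3 * xy[, 1] + rnorm(40)
  tr1 <- remove_trend(xy, z3, order = 1)
  expect_lt(var(tr1$residuals), var(z3))
  expect_lt(abs(mean(tr1$residuals)), 1e-9)
  # collinear coordinates break the order-2 design
  line <- cbind(1:10, 2 * (1:10))
  expect_error(remove_trend(line, rnorm(10), order = 2), "rank-deficient")
})

test_that("ordinary kriging is exact, unbiased in weights, and handles pure nugget", {
  set.seed(8)
  xy <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  z <- sin(xy[, 1]) + 0.2 * xy[, 2] + rnorm(15, 0, 0.1)
  vm <- variogram_model("spherical", nugget = 0, psill = 2, range = 6)
  # exactness at data locations with a nugget-free model
  kp <- krige_points(xy, z, vm, xy)
  expect_lt(max(abs(kp$prediction - z)), 1e-8)
  # weights sum to 1 at arbitrary nodes
  nodes <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  kw <- krige_points(xy, z, vm, nodes, weights = TRUE)
  expect_lt(max(abs(colSums(kw$lambda) - 1)), 1e-10)
  expect_true(all(kw$variance >= 0))
  # pure-nugget model: prediction = sample mean, weights all 1/n
  vn <- variogram_model("spherical", nugget = 3, psill = 0, range = 1)
  kn <- krige_points(xy, z, vn, cbind(5, 5), weights = TRUE)
  expect_equal(kn$prediction, mean(z), tolerance = 1e-10)
  expect_equal(as.numeric(kn$lambda), rep(1 / 15, 15), tolerance = 1e-10)
})

test_that("kriging degenerates gracefully with one point and duplicates", {
  vm <- variogram_model("exponential", nugget = 0.5, psill = 1, range = 4)
  k1 <- krige_points(cbind(2, 3), 7, vm, rbind(c(0, 0), c(9, 9)))
  expect_equal(k1$prediction, c(7, 7))
  # duplicated points are averaged with a warning, then solvable
  xy <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_warning(k2 <- krige_points(xy, c(1, 3, 2, 2, 4), vm, cbind(0.5, 0.5)),
                 "averaged")
  expect_true(is.finite(k2$prediction))
})

test_that("kriging predictions are shift-equivariant", {
  set.seed(12)
  xy <- cbind(runif(12, 0, 8), runif(12, 0, 8))
  z <- rnorm(12)
  vm <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 5)
  nodes <- cbind(runif(9, 0, 8), runif(9, 0, 8))
  k0 <- krige_points(xy, z, vm, nodes)
  k1 <- krige_points(xy, z + 100, vm, nodes)
  expect_equal(k1$prediction, k0$prediction + 100, tolerance = 1e-8)
  expect_equal(k1$variance, k0$variance, tolerance = 1e-10)
})

test_that("gridded kriging fills the grid and writes georeferencing", {
  rs <- generate_geometry(4, 4, 1)
  xy <- centroids(rs)
  z <- xy[, 1] + 0.5 * xy[, 2]
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 3)
  grid <- grid_over_regions(rs, ncols = 10)
  kr <- ordinary_krige(xy, z, vm, grid)
  expect_s3_class(kr$prediction, "grid_surface")
  expect_equal(dim(kr$prediction$values), c(grid$nrows, grid$ncols))
  expect_true(all(kr$variance$values >= 0))
  # row 1 is the northern row: predictions increase with y
  expect_gt(mean(kr$prediction$values[1, ]), mean(kr$prediction$values[grid$nrows, ]))
})

test_that("LOO cross-validation vanishes on a trend-explained surface", {
  set.seed(5)
  xy <- cbind(runif(25, 0, 10), runif(25, 0, 10))
  z <- 1 + xy[, 1] - 0.5 * xy[, 2] + 0.2 * xy[, 1]^2
  tr <- remove_trend(xy, z, order = 2)
  vm <- variogram_model("spherical", nugget = 0, psill = 1, range = 5)
  cv <- loo_cross_validate(xy, z, vm, trend = tr$model)
  expect_lt(cv$rmse, 1e-6)
  # permuting point order leaves the RMSE unchanged
  set.seed(6)
  z2 <- z + rnorm(25, 0, 0.5)
  cv2 <- loo_cross_validate(xy, z2, vm)
  perm <- sample(25)
  cv3 <- loo_cross_validate(xy[perm, ], z2[perm], vm)
  expect_equal(cv3$rmse, cv2$rmse, tolerance = 1e-10)
})

test_that("LOO standardized errors are calibrated on a field from a known model", {
  true <- variogram_model("spherical", nugget = 0.05, psill = 1, range = 6)
  xy <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  z <- simulate_gaussian_field(xy, true, seed = 77)
  cv <- loo_cross_validate(xy, z, true)
  expect_gte(cv$mse_standardized, -0.2)
  expect_lte(cv$mse_standardized, 0.2)
})

test_that("variogram fit + kriging recover a simulated spherical field's range", {
  true <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 8)
  xy <- as.matrix(expand.grid(x = 1:15, y = 1:15))
  hit <- vapply(1:20, function(s) {
    z <- simulate_gaussian_field(xy, true, seed = 500 + s)
    emp <- empirical_semivariogram(xy, z, n_bins = 12)
    fit <- fit_variogram(emp, "spherical")
    abs(fit$range - 8) / 8 < 0.3
  }, logical(1))
  expect_gte(mean(hit), 0.7)
})
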