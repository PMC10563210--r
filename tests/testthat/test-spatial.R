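test_that("lattice contiguity weights match the expected neighbour counts", {
  g2 <- generate_geometry(2, 2, 1)
  Wr <- build_weights(g2, "rook")
  expect_true(all(lengths(Wr$neighbours) == 2L))
  g3 <- generate_geometry(3, 3, 1)
  Wq <- build_weights(g3, "queen")
  expect_equal(lengths(Wq$neighbours)[5], 8L)  # centre cell
  # symmetry of contiguity
  m <- weights_matrix(Wq)
  expect_identical((m > 0), t(m > 0))
})

test_that("row standardization makes every row sum to 1", {
  W <- build_weights(generate_geometry(3, 4, 1), "queen", row_standardize = TRUE)
  sums <- rowSums(weights_matrix(W))
  expect_equal(unname(sums), rep(1, 12), tolerance = 1e-12)
})

test_that("distance-band auto threshold leaves no islands and knn gives k neighbours", {
  rs <- generate_geometry(4, 4, 1)
  Wd <- build_weights(rs, "distance_band")
  expect_true(all(lengths(Wd$neighbours) >= 1L))
  Wk <- build_weights(rs, "knn", k = 3)
  expect_true(all(lengths(Wk$neighbours) == 3L))
  Ws <- build_weights(rs, "distance_band", include_self = TRUE)
  expect_true(all(vapply(seq_len(Ws$n), function(i) i %in% Ws$neighbours[[i]],
                         logical(1))))
})

test_that("checkerboard on the 2x2 rook lattice gives Moran's I = -1 exactly", {
  W <- build_weights(generate_geometry(2, 2, 1), "rook")
  m <- global_morans_i(c(1, 0, 0, 1), W, n_perm = 99, seed = 1)
  expect_equal(m$I, -1.0)
  expect_equal(m$expected, -1 / 3)
})

test_that("global Moran matches the brute-force oracle on random lattice fields", {
  for (side in 4:6) {
    rs <- generate_geometry(side, side, 1)
    W <- build_weights(rs, "queen", row_standardize = TRUE)
    Wm <- weights_matrix(W)
    for (rep in 1:5) {
      set.seed(side * 100 + rep)
      x <- rnorm(side^2)
      m <- global_morans_i(x, W, n_perm = 19, seed = 1)
      expect_equal(m$I, oracle_global_moran(x, Wm), tolerance = 1e-12)
    }
  }
})

test_that("Moran permutation p respects its counting definition and seed", {
  rs <- generate_geometry(4, 4, 1)
  W <- build_weights(rs, "queen", row_standardize = TRUE)
  set.seed(9); x <- rnorm(16)
  m1 <- global_morans_i(x, W, n_perm = 199, seed = 7)
  m2 <- global_morans_i(x, W, n_perm = 199, seed = 7)
  expect_identical(m1$p_perm, m2$p_perm)
  expect_gte(m1$p_perm, 1 / 200)
  expect_lte(m1$p_perm, 1)
  # p_perm is k/(n_perm+1) for integer k
  expect_equal(m1$p_perm * 200, round(m1$p_perm * 200))
})

test_that("Moran errors on degenerate input", {
  W <- build_weights(generate_geometry(2, 2, 1), "rook")
  expect_error(global_morans_i(rep(3, 4), W), "constant field")
  Wself <- build_weights(generate_geometry(2, 2, 1), "rook", include_self = TRUE)
  expect_error(global_morans_i(1:4, Wself), "self")
})

test_that("local Moran matches the oracle and averages to global I", {
  rs <- generate_geometry(5, 5, 1)
  W <- build_weights(rs, "queen", row_standardize = TRUE)
  Wm <- weights_matrix(W)
  set.seed(21); x <- rnorm(25)
  lisa <- local_morans_i(x, W, n_perm = 99, seed = 2)
  expect_equal(lisa$I_i, oracle_local_moran(x, Wm), tolerance = 1e-12)
  g <- global_morans_i(x, W, n_perm = 19, seed = 1)
  expect_equal(mean(lisa$I_i), g$I, tolerance = 1e-9)
})

test_that("LISA labels follow the (z, lag) quadrants", {
  rs <- generate_geometry(4, 4, 1)
  W <- build_weights(rs, "queen", row_standardize = TRUE)
  # east half high, west half low: interior cells form clear clusters
  set.seed(4)
  x <- ifelse(rs$cx > 2, 10, 0) + rnorm(16, 0, 0.01)
  lisa <- local_morans_i(x, W, n_perm = 999, seed = 3, alpha = 0.4)
  z <- x - mean(x)
  lag <- as.numeric(weights_matrix(W) %*% z)
  sig <- lisa$p_perm <= 0.4
  expect_true(all(lisa$label[sig & z > 0 & lag > 0] == "High-High"))
  expect_true(all(lisa$label[sig & z < 0 & lag < 0] == "Low-Low"))
  expect_true(all(lisa$label[!sig] == "Not significant"))
})

test_that("a low-valued region embedded in a high cluster is a Low-High outlier", {
  # west half low, east half high, with one low region inside the east
  # cluster - the low-amid-high outlier pattern
  rs <- generate_geometry(4, 4, 1)
  W <- build_weights(rs, "queen", row_standardize = TRUE)
  set.seed(11)
  x <- ifelse(rs$cx > 2, 10, 1) + rnorm(16, 0, 0.05)
  low_in_east <- which(region_ids(rs) == "r02c04")
  x[low_in_east] <- 1
  lisa <- local_morans_i(x, W, n_perm = 999, seed = 1, alpha = 0.1)
  expect_equal(lisa$label[low_in_east], "Low-High")
})

test_that("Gi* z-scores equal the literal-translation oracle on random fields", {
  rs <- generate_geometry(4, 4, 1)
  W <- build_weights(rs, "distance_band", include_self = TRUE)
  Wm <- weights_matrix(W)
  for (rep in 1:100) {
    set.seed(rep)
    x <- rnorm(16, 10, 3)
    gi <- getis_ord_gi_star(x, W)
    expect_equal(gi$gi_z, oracle_gi_star(x, Wm), tolerance = 1e-10)
  }
})

test_that("a high central block is a 99%-confidence hot spot at its centre", {
  rs <- generate_geometry(5, 5, 1)
  W <- build_weights(rs, "distance_band", include_self = TRUE)
  x <- rep(1, 25)
  x[rs$cx >= 1.5 & rs$cx <= 3.5 & rs$cy >= 1.5 & rs$cy <= 3.5] <- 50
  gi <- getis_ord_gi_star(x, W)
  centre <- which(region_ids(rs) == "r03c03")
  expect_equal(which.max(gi$gi_z), centre)
  expect_equal(gi$bin[centre], "hot 99")
  expect_error(getis_ord_gi_star(rep(2, 25), W), "constant")
})

test_that("FDR correction only ever demotes bins", {
  rs <- generate_geometry(5, 5, 1)
  W <- build_weights(rs, "distance_band", include_self = TRUE)
  set.seed(17)
  x <- rnorm(25) + as.numeric(rs$cx > 2.5)
  lv <- function(bin) {
    out <- rep(0, length(bin))
    sig <- bin != "not significant"
    out[sig] <- as.numeric(sub("^(hot|cold) ", "", bin[sig]))
    out
  }
  g0 <- getis_ord_gi_star(x, W, correction = "none")
  g1 <- getis_ord_gi_star(x, W, correction = "fdr")
  expect_true(all(lv(g1$bin) <= lv(g0$bin)))
})

test_that("the SDE recovers symmetry, direction and degeneracy", {
  # symmetric cross: circular ellipse centred at the origin
  e <- std_dev_ellipse(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  expect_equal(unname(e$center), c(0, 0))
  expect_equal(e$sigma_x, e$sigma_y)
  expect_equal(e$sigma_x, sqrt(0.5))
  # points on y = x: 45 degrees clockwise from north
  e45 <- suppressWarnings(std_dev_ellipse(cbind(-2:2, -2:2)))
  expect_equal(e45$theta %% 180, 45, tolerance = 1e-9)
  # identical points: both axes zero, flagged degenerate
  expect_warning(ed <- std_dev_ellipse(matrix(1, 3, 2)), "degenerate")
  expect_equal(ed$sigma_x, 0)
  expect_equal(ed$sigma_y, 0)
})

test_that("the SDE is translation- and rotation-equivariant", {
  set.seed(33)
  pts <- cbind(rnorm(30, 0, 3), rnorm(30, 0, 1))
  w <- runif(30, 0.5, 2)
  e0 <- std_dev_ellipse(pts, w)
  # translation moves only the centre
  et <- std_dev_ellipse(sweep(pts, 2, c(5, -2), "+"), w)
  expect_equal(unname(et$center), unname(e0$center + c(5, -2)), tolerance = 1e-9)
  expect_equal(et$theta, e0$theta, tolerance = 1e-9)
  expect_equal(c(et$sigma_x, et$sigma_y), c(e0$sigma_x, e0$sigma_y),
               tolerance = 1e-9)
  # rotating the points by phi (counter-clockwise) subtracts phi from the
  # clockwise-from-north azimuth, axes unchanged
  for (phi_deg in c(20, 75, 130)) {
    phi <- phi_deg * pi / 180
    R <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
    er <- std_dev_ellipse(pts %*% t(R), w)
    ang_diff <- ((er$theta - (e0$theta - phi_deg) + 90) %% 180) - 90
    expect_equal(ang_diff, 0, tolerance = 1e-9)
    expect_equal(c(er$sigma_x, er$sigma_y), c(e0$sigma_x, e0$sigma_y),
                 tolerance = 1e-9)
  }
})

test_that("the ellipse polygon traces the stated axes", {
  e <- std_dev_ellipse(rbind(c(3, 0), c(-3, 0), c(0, 1), c(0, -1)))
  ring <- ellipse_polygon(e, n_vertices = 64)
  expect_equal(nrow(ring), 65L)
  expect_equal(ring[1, ], ring[65, ])
  d <- sqrt(rowSums(sweep(ring, 2, e$center)^2))
  expect_equal(max(d), max(e$sigma_x, e$sigma_y), tolerance = 1e-6)
  expect_equal(min(d), min(e$sigma_x, e$sigma_y), tolerance = 1e-6)
})
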