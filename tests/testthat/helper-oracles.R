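# Independent literal-translation oracles: naive double-loop implementations
# of the spatial statistics, kept free of any package internals so they can
# certify the vectorised implementations.

oracle_global_moran <- function(x, Wm) {
  n <- length(x)
  z <- x - mean(x)
  S0 <- 0
  cross <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S0 <- S0 + Wm[i, j]
      cross <- cross + Wm[i, j] * z[i] * z[j]
    }
  }
  (n / S0) * cross / sum(z^2)
}

oracle_local_moran <- function(x, Wm) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + Wm[i, j] * z[j]
    out[i] <- z[i] * lag / m2
  }
  out
}

oracle_gi_star <- function(x, Wm) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; sw2 <- 0; swx <- 0
    for (j in seq_len(n)) {
      sw <- sw + Wm[i, j]
      sw2 <- sw2 + Wm[i, j]^2
      swx <- swx + Wm[i, j] * x[j]
    }
    out[i] <- (swx - xbar * sw) / (S * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  out
}

oracle_semivariogram_pairs <- function(xy, z, lo, hi) {
  # mean of squared differences / 2 over pairs with lo < d <= hi
  n <- nrow(xy)
  s <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d > lo && d <= hi) {
        s <- s + (z[i] - z[j])^2
        np <- np + 1
      }
    }
  }
  if (np == 0) return(NULL)
  list(gamma = s / (2 * np), np = np)
}

# Rook adjacency of grid cells by brute-force edge sharing: two cells are
# rook neighbours iff their polygons share a full edge (two common vertices).
oracle_rook_edges <- function(regions) {
  polys <- region_polygons(regions)
  n <- length(polys)
  edges <- 0L
  for (i in seq_len(n - 1L)) {
    vi <- unique(apply(polys[[i]][[1]][-nrow(polys[[i]][[1]]), ], 1,
                       paste, collapse = "_"))
    for (j in (i + 1L):n) {
      vj <- unique(apply(polys[[j]][[1]][-nrow(polys[[j]][[1]]), ], 1,
                         paste, collapse = "_"))
      if (length(intersect(vi, vj)) >= 2L) edges <- edges + 1L
    }
  }
  edges
}

# Simulate a zero-mean Gaussian random field with covariance derived from a
# variogram model (C(h) = sill - gamma(h)) via Cholesky; small grids only.
simulate_gaussian_field <- function(xy, model, seed) {
  sill <- model$nugget + model$psill
  d <- as.matrix(dist(xy))
  C <- matrix(sill - variogram_gamma(model, as.numeric(d)), nrow(d))
  diag(C) <- sill
  set.seed(seed)
  L <- chol(C + diag(1e-10, nrow(C)))
  drop(t(L) %*% rnorm(nrow(C)))
}
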