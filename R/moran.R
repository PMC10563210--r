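#' Global Moran's I with analytic and permutation inference
#'
#' Computes
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with \eqn{z_i} the deviations from the mean and \eqn{S_0 = \sum w_{ij}},
#' together with the expectation `-1/(n-1)`, the variance under the
#' randomization (non-free sampling) assumption, the corresponding normal
#' z-score and two-sided analytic p-value, and a two-sided permutation
#' p-value from `n_perm` random relabellings of the values:
#' `p_perm = (1 + #\{|I* - E| >= |I - E|\}) / (n_perm + 1)`.
#'
#' @param values Numeric vector, one value per region, not all equal.
#' @param W A `spatial_weights` object without self-neighbours.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `moran_result` list: `I`, `expected`, `variance`, `z`,
#'   `p_analytic`, `p_perm`, `n_perm`, `seed`, `n`.
#' @export
global_morans_i <- function(values, W, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$includes_self) stop_arg("Moran's I requires weights without self-neighbours")
  x <- as.numeric(values)
  n <- W$n
  if (length(x) != n) stop_arg("values length ", length(x), " != n regions ", n)
  if (any(!is.finite(x))) stop_arg("values must be finite")
  if (stats::var(x) == 0) stop_arg("Moran's I undefined for constant field")
  if (!is_count(n_perm) || n_perm < 1L) stop_arg("n_perm must be a positive integer")

  Wm <- weights_matrix(W)
  S0 <- sum(Wm)
  z <- x - mean(x)
  m2 <- sum(z^2)
  I <- (n / S0) * drop(z %*% Wm %*% z) / m2

  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((Wm + t(Wm))^2)
  S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
  b2 <- n * sum(z^4) / m2^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(varI)
  p_analytic <- 2 * stats::pnorm(-abs(zscore))

  set.seed(as.integer(seed))
  Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  Istar <- (n / S0) * colSums(Z * (Wm %*% Z)) / m2
  p_perm <- (1 + sum(abs(Istar - EI) >= abs(I - EI))) / (n_perm + 1)

  structure(list(I = I, expected = EI, variance = varI, z = zscore,
                 p_analytic = p_analytic, p_perm = p_perm,
                 n_perm = as.integer(n_perm), seed = as.integer(seed), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Global Moran's I = ", format(x$I, digits = 4),
      " (E[I] = ", format(x$expected, digits = 4), ")\n",
      "  z = ", format(x$z, digits = 4),
      ", analytic p = ", format(x$p_analytic, digits = 4),
      ", permutation p = ", format(x$p_perm, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' Per region \eqn{I_i = z_i \sum_j w_{ij} z_j / m_2} with
#' \eqn{m_2 = \sum z^2 / n}. Significance is assessed by conditional
#' permutation: region i's value is held fixed while its neighbours' values
#' are drawn without replacement from the remaining n-1 values; the
#' two-sided p-value compares `|I_i - E_i|` with the permuted deviations,
#' where `E_i` is the conditional expectation
#' \eqn{-z_i^2 \sum_j w_{ij} / ((n-1) m_2)}. Regions with `p <= alpha` are
#' labelled by the quadrant of `(z_i, lag_i)`: High-High, Low-Low, Low-High
#' or High-Low; a spatial lag of exactly zero is labelled Not significant.
#'
#' With row-standardized weights the mean of the `I_i` equals global I.
#'
#' @param values Numeric vector, one value per region, not all equal.
#' @param W Row-standardized `spatial_weights` without self-neighbours.
#' @param n_perm Number of conditional permutations per region.
#' @param seed Integer seed.
#' @param alpha Significance level for labelling (default 0.05).
#' @return A `lisa_result` data frame: `region_id`, `I_i`, `z_i`, `p_perm`,
#'   `label`.
#' @export
local_morans_i <- function(values, W, n_perm = 999L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$includes_self) stop_arg("LISA requires weights without self-neighbours")
  if (!W$row_standardized) stop_arg("LISA requires row-standardized weights")
  x <- as.numeric(values)
  n <- W$n
  if (length(x) != n) stop_arg("values length ", length(x), " != n regions ", n)
  if (stats::var(x) == 0) stop_arg("local Moran's I undefined for constant field")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0,1)")

  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) {
    sum(W$weights[[i]] * z[W$neighbours[[i]]])
  }, numeric(1L))
  Ii <- z * lag / m2

  set.seed(as.integer(seed))
  p <- numeric(n)
  zsc <- numeric(n)
  for (i in seq_len(n)) {
    wi <- W$weights[[i]]
    ki <- length(wi)
    if (ki == 0L) { p[i] <- NA_real_; zsc[i] <- NA_real_; next }
    zother <- z[-i]
    lag_star <- vapply(seq_len(n_perm), function(r) {
      sum(wi * zother[sample.int(n - 1L, ki)])
    }, numeric(1L))
    Istar <- z[i] * lag_star / m2
    Ei <- -z[i]^2 * sum(wi) / ((n - 1) * m2)
    p[i] <- (1 + sum(abs(Istar - Ei) >= abs(Ii[i] - Ei))) / (n_perm + 1)
    s <- stats::sd(Istar)
    zsc[i] <- if (s > 0) (Ii[i] - mean(Istar)) / s else NA_real_
  }

  label <- rep("Not significant", n)
  sig <- !is.na(p) & p <= alpha & lag != 0 & z != 0
  label[sig & z > 0 & lag > 0] <- "High-High"
  label[sig & z < 0 & lag < 0] <- "Low-Low"
  label[sig & z < 0 & lag > 0] <- "Low-High"
  label[sig & z > 0 & lag < 0] <- "High-Low"

  out <- data.frame(region_id = W$ids, I_i = Ii, z_i = zsc, p_perm = p,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha") <- alpha
  class(out) <- c("lisa_result", "data.frame")
  out
}
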