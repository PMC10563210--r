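#' Getis-Ord Gi* hot-spot statistic
#'
#' For each region i (self included in its neighbourhood, as the * variant
#' requires),
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} \sum_j w_{ij}}
#'   {S \sqrt{\left[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right] / (n-1)}},}
#' where \eqn{\bar{X}} and \eqn{S} are the global mean and (population)
#' standard deviation of the field. Regions are binned by the conventional
#' confidence cut-offs on z: hot/cold at 90% (|z| >= 1.645), 95% (1.960)
#' and 99% (2.576). With `correction = "fdr"` a bin is additionally required
#' to pass the Benjamini-Hochberg adjusted two-sided p at the matching level,
#' demoting marginal spots.
#'
#' @param values Numeric vector, one value per region, not all equal.
#' @param W A `spatial_weights` object with `includes_self = TRUE`
#'   (binary or distance-band weights are conventional).
#' @param correction `"none"` (default) or `"fdr"`.
#' @return A `gistar_result` data frame: `region_id`, `gi_z`, `p`, `bin`
#'   (one of `"cold 99"`, `"cold 95"`, `"cold 90"`, `"not significant"`,
#'   `"hot 90"`, `"hot 95"`, `"hot 99"`).
#' @export
getis_ord_gi_star <- function(values, W, correction = c("none", "fdr")) {
  stopifnot(inherits(W, "spatial_weights"))
  correction <- match.arg(correction)
  if (!W$includes_self) stop_arg("Gi* requires weights with includes_self = TRUE")
  x <- as.numeric(values)
  n <- W$n
  if (length(x) != n) stop_arg("values length ", length(x), " != n regions ", n)
  if (any(!is.finite(x))) stop_arg("values must be finite")
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)
  if (S == 0) stop_arg("Gi* undefined for constant field")

  gi <- vapply(seq_len(n), function(i) {
    w <- W$weights[[i]]
    xi <- x[W$neighbours[[i]]]
    sw <- sum(w)
    num <- sum(w * xi) - xbar * sw
    den <- S * sqrt((n * sum(w^2) - sw^2) / (n - 1))
    num / den
  }, numeric(1L))
  p <- 2 * stats::pnorm(-abs(gi))

  level <- function(z, padj) {
    a <- abs(z)
    lv <- if (a >= 2.576) 0.99 else if (a >= 1.960) 0.95 else if (a >= 1.645) 0.90 else 0
    if (lv > 0 && !is.null(padj)) {
      # demote until the BH-adjusted p supports the level
      for (cand in c(lv, 0.95, 0.90)) {
        if (cand <= lv && padj <= 1 - cand) return(cand)
      }
      return(0)
    }
    lv
  }
  padj <- if (correction == "fdr") stats::p.adjust(p, method = "BH") else NULL
  bins <- vapply(seq_len(n), function(i) {
    lv <- level(gi[i], padj[i])
    if (lv == 0) return("not significant")
    paste(if (gi[i] > 0) "hot" else "cold", round(lv * 100))
  }, character(1L))

  out <- data.frame(region_id = W$ids, gi_z = gi, p = p, bin = bins,
                    stringsAsFactors = FALSE)
  attr(out, "correction") <- correction
  class(out) <- c("gistar_result", "data.frame")
  out
}
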