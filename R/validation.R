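#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes rho as the Pearson correlation of average ranks. For `n <= 10`
#' with no ties the exact two-sided p-value is obtained by full enumeration
#' of all `n!` rank orders: `p_exact` is the proportion of orders whose
#' |rho| is at least the observed |rho|. (For n = 10 the enumeration visits
#' 3,628,800 orders in blocks; still desk-scale.) With ties or larger n,
#' `p_exact` is `NA` and the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` provides `p_asymptotic`.
#'
#' @param x,y Paired numeric vectors, `n >= 4`, finite, neither constant.
#' @return A `spearman_result` list: `rho`, `p_exact`, `p_asymptotic`, `n`,
#'   `ties`.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_arg("x and y must have equal length")
  if (n < 4L) stop_arg("need at least 4 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_arg("x and y must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_arg("Spearman correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L

  p_exact <- NA_real_
  if (!ties && n <= 10L) {
    p_exact <- spearman_exact_p(rx, ry)
  }
  t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p_asym <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  structure(list(rho = rho, p_exact = p_exact, p_asymptotic = p_asym,
                 n = n, ties = ties),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat("Spearman rho = ", format(x$rho, digits = 4), " (n = ", x$n, ")\n",
      "  exact two-sided p = ",
      if (is.na(x$p_exact)) "NA (ties or n > 10)" else format(x$p_exact, digits = 4),
      ", asymptotic p = ", format(x$p_asymptotic, digits = 4), "\n", sep = "")
  invisible(x)
}

# All permutations of 1..n as an n x n! integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  cols <- ncol(sub)
  out <- matrix(0L, n, n * cols)
  for (v in seq_len(n)) {
    rest <- seq_len(n)[-v]
    block <- matrix(rest[sub], n - 1L, cols)
    out[, ((v - 1L) * cols + 1L):(v * cols)] <- rbind(rep.int(v, cols), block)
  }
  out
}

# Exact two-sided p for untied ranks by full enumeration.
# |rho*| >= |rho| is equivalent to a two-sided test on S = sum(d^2) around
# its centre n(n^2-1)/6.
spearman_exact_p <- function(rx, ry, tol = 1e-12) {
  n <- length(rx)
  denom <- n * (n^2 - 1)
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / denom
  # The null distribution of rho depends only on n, so enumerate permutations
  # of 1..n against the identity; the observed rho uses the actual ranks.
  count <- 0
  total <- 0
  if (n <= 9L) {
    P <- all_permutations(n)
    S <- colSums((P - seq_len(n))^2)
    rho_star <- 1 - 6 * S / denom
    count <- sum(abs(rho_star) >= abs(rho_obs) - tol)
    total <- ncol(P)
  } else {
    sub <- all_permutations(n - 1L)
    base <- seq_len(n)
    for (v in base) {
      rest <- base[-v]
      block <- rbind(rep.int(v, ncol(sub)), matrix(rest[sub], n - 1L, ncol(sub)))
      S <- colSums((block - base)^2)
      rho_star <- 1 - 6 * S / denom
      count <- count + sum(abs(rho_star) >= abs(rho_obs) - tol)
      total <- total + ncol(sub)
    }
  }
  count / total
}

#' Seasonal demand-share table
#'
#' For each meteorological season (spring = Mar-May, summer = Jun-Aug,
#' autumn = Sep-Nov, winter = Dec-Feb), keeps the eight highest-volume terms
#' (ties broken lexicographically by term) and reports each term's share of
#' the top-8 total, ranked.
#'
#' @param terms Data frame with columns `season`, `term`, `volume`
#'   (non-negative). Every listed season must carry at least 8 terms.
#' @return A `demand_table` data frame: `season`, `rank`, `term`, `volume`,
#'   `share` (shares sum to 1 within each season).
#' @export
seasonal_demand_shares <- function(terms) {
  if (!is.data.frame(terms) || !all(c("season", "term", "volume") %in% names(terms))) {
    stop_arg("terms needs columns season, term, volume")
  }
  known <- c("spring", "summer", "autumn", "winter")
  season <- tolower(as.character(terms$season))
  if (!all(season %in% known)) {
    stop_arg("unknown season(s): ",
             paste(setdiff(unique(season), known), collapse = ", "))
  }
  vol <- as.numeric(terms$volume)
  if (any(!is.finite(vol) | vol < 0)) stop_arg("volumes must be finite and >= 0")
  pieces <- lapply(intersect(known, unique(season)), function(s) {
    d <- terms[season == s, , drop = FALSE]
    if (nrow(d) < 8L) {
      stop_arg("season '", s, "' has only ", nrow(d), " terms; need at least 8")
    }
    ord <- order(-as.numeric(d$volume), as.character(d$term))
    top <- d[ord[1:8], , drop = FALSE]
    data.frame(season = s, rank = 1:8, term = as.character(top$term),
               volume = as.numeric(top$volume),
               share = as.numeric(top$volume) / sum(as.numeric(top$volume)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("demand_table", "data.frame")
  out
}
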