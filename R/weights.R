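#' Build a spatial weights structure
#'
#' Constructs the n x n neighbour weight structure shared by Moran's I, LISA
#' and Getis-Ord Gi*. Contiguity schemes derive neighbours from shared
#' polygon boundary vertices (snapped to a tolerance): `queen` requires at
#' least one shared vertex, `rook` at least two (i.e. a shared edge on
#' well-noded boundaries such as lattice grids). `knn` and `distance_band`
#' work on centroids; the distance-band threshold defaults to the smallest
#' distance at which every region has at least one neighbour.
#'
#' @param regions A [region_set].
#' @param scheme One of `"queen"`, `"rook"`, `"knn"`, `"distance_band"`.
#' @param k Number of neighbours for `knn` (must be `< n`).
#' @param threshold Distance-band radius; `NULL` for the auto threshold.
#' @param row_standardize Scale each region's weights to sum to 1.
#' @param include_self Give each region a self-neighbour with weight 1
#'   (the Gi* convention). Must be `FALSE` for Moran's I.
#' @param snap Vertex snapping tolerance for contiguity detection.
#' @return A `spatial_weights` object: fields `ids`, `n`, `neighbours`
#'   (list of integer vectors), `weights` (list of numeric vectors),
#'   `scheme`, `row_standardized`, `includes_self`, `islands`.
#' @export
build_weights <- function(regions, scheme = c("queen", "rook", "knn", "distance_band"),
                          k = 4L, threshold = NULL, row_standardize = FALSE,
                          include_self = FALSE, snap = 1e-8) {
  stopifnot(is_region_set(regions))
  scheme <- match.arg(scheme)
  n <- nrow(regions)
  if (n < 2L) stop_arg("need at least 2 regions")
  nb <- vector("list", n)

  if (scheme %in% c("queen", "rook")) {
    polys <- region_polygons(regions)
    vkeys <- lapply(polys, function(rings) {
      v <- do.call(rbind, lapply(rings, function(m) m[-nrow(m), , drop = FALSE]))
      unique(paste(round(v[, 1L] / snap), round(v[, 2L] / snap)))
    })
    # vertex -> regions index, then co-occurrence counts per region pair
    all_keys <- unlist(vkeys, use.names = FALSE)
    owner <- rep.int(seq_len(n), lengths(vkeys))
    by_key <- split(owner, all_keys)
    pair_count <- new.env(hash = TRUE, parent = emptyenv())
    for (regs in by_key) {
      if (length(regs) < 2L) next
      regs <- sort(unique(regs))
      for (a in seq_len(length(regs) - 1L)) {
        for (b in (a + 1L):length(regs)) {
          key <- paste0(regs[a], "_", regs[b])
          pair_count[[key]] <- (if (is.null(pair_count[[key]])) 0L else pair_count[[key]]) + 1L
        }
      }
    }
    need <- if (scheme == "rook") 2L else 1L
    for (key in ls(pair_count)) {
      if (pair_count[[key]] >= need) {
        ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
        nb[[ij[1L]]] <- c(nb[[ij[1L]]], ij[2L])
        nb[[ij[2L]]] <- c(nb[[ij[2L]]], ij[1L])
      }
    }
  } else {
    xy <- centroids(regions)
    d <- as.matrix(stats::dist(xy))
    if (scheme == "knn") {
      if (!is_count(k) || k < 1L || k >= n) stop_arg("knn needs 1 <= k < n")
      for (i in seq_len(n)) {
        nb[[i]] <- setdiff(order(d[i, ]), i)[seq_len(k)]
      }
    } else {
      if (is.null(threshold)) {
        diag(d) <- Inf
        threshold <- max(apply(d, 1L, min)) * (1 + 1e-9)
        diag(d) <- 0
      }
      if (!is_number(threshold) || threshold <= 0) stop_arg("threshold must be positive")
      for (i in seq_len(n)) {
        nb[[i]] <- setdiff(which(d[i, ] <= threshold), i)
      }
    }
  }

  nb <- lapply(nb, function(v) sort(unique(v)))
  islands <- regions$region_id[lengths(nb) == 0L]
  if (length(islands)) {
    warning("island region(s) with no neighbours: ",
            paste(islands, collapse = ", "), call. = FALSE)
  }
  if (include_self) nb <- lapply(seq_len(n), function(i) sort(unique(c(i, nb[[i]]))))
  wts <- lapply(nb, function(v) rep(1, length(v)))
  if (row_standardize) {
    wts <- lapply(wts, function(w) if (length(w)) w / sum(w) else w)
  }
  structure(list(ids = regions$region_id, n = n, neighbours = nb, weights = wts,
                 scheme = scheme, row_standardized = isTRUE(row_standardize),
                 includes_self = isTRUE(include_self), islands = islands,
                 threshold = if (scheme == "distance_band") threshold else NULL),
            class = "spatial_weights")
}

#' Dense weight matrix of a spatial_weights object
#'
#' @param W A `spatial_weights` object.
#' @return n x n numeric matrix with dimnames set to the region ids.
#' @export
weights_matrix <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  m <- matrix(0, W$n, W$n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(W$n)) {
    m[i, W$neighbours[[i]]] <- W$weights[[i]]
  }
  m
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", x$scheme, ", n = ", x$n,
      ", avg neighbours = ", format(mean(lengths(x$neighbours)), digits = 3),
      if (x$row_standardized) ", row-standardized" else "",
      if (x$includes_self) ", self included" else "",
      "\n", sep = "")
  if (length(x$islands)) cat("  islands: ", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}
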