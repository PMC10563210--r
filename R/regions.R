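#' Region geometries
#'
#' A `region_set` holds planar polygon geometries with unique region
#' identifiers, and is the source of spatial adjacency, centroid coordinates
#' for distance-based weights, the standard deviational ellipse and kriging.
#' Coordinates are abstract planar units: geographic inputs must be projected
#' to a planar frame before use; no projection handling is performed here.
#'
#' Internally a `region_set` is a data frame with columns `region_id`, `cx`,
#' `cy` (area-weighted centroids) and an attribute `polygons`: a named list,
#' one entry per region, each a list of outer rings (matrices with columns
#' x, y; first vertex repeated last). Multi-part regions carry several rings.
#'
#' @param regions An object to test or coerce.
#' @name region_set
NULL

new_region_set <- function(region_id, polygons, centroids) {
  stopifnot(length(region_id) == length(polygons),
            nrow(centroids) == length(region_id))
  if (anyDuplicated(region_id)) {
    stop_arg("duplicate region_id: ",
             paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  }
  df <- data.frame(region_id = as.character(region_id),
                   cx = centroids[, 1L], cy = centroids[, 2L],
                   stringsAsFactors = FALSE)
  names(polygons) <- df$region_id
  attr(df, "polygons") <- polygons
  class(df) <- c("region_set", "data.frame")
  df
}

#' @rdname region_set
#' @export
is_region_set <- function(regions) inherits(regions, "region_set")

#' @rdname region_set
#' @export
region_ids <- function(regions) {
  stopifnot(is_region_set(regions))
  regions$region_id
}

#' Region centroids as a two-column matrix
#'
#' @param regions A `region_set`.
#' @return Numeric matrix with columns `x`, `y`, one row per region.
#' @export
centroids <- function(regions) {
  stopifnot(is_region_set(regions))
  m <- cbind(x = regions$cx, y = regions$cy)
  rownames(m) <- regions$region_id
  m
}

#' @rdname region_set
#' @export
region_polygons <- function(regions) {
  stopifnot(is_region_set(regions))
  attr(regions, "polygons")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", nrow(x), " regions, planar coordinates\n", sep = "")
  cat("  bbox: x [", format(min(x$cx)), ", ", format(max(x$cx)),
      "]  y [", format(min(x$cy)), ", ", format(max(x$cy)), "] (centroids)\n",
      sep = "")
  invisible(x)
}

# Shoelace area of one closed ring (positive regardless of orientation).
ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

# Area centroid of one closed ring.
ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) {
    return(c(mean(x[-n]), mean(y[-n])))
  }
  cx <- sum((x[-n] + x[-1L]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1L]) * cr) / (6 * a)
  c(cx, cy)
}

# Area-weighted centroid across the parts of a (multi)polygon.
multipart_centroid <- function(rings) {
  areas <- vapply(rings, ring_area, numeric(1L))
  cents <- t(vapply(rings, ring_centroid, numeric(2L)))
  w <- areas / sum(areas)
  c(sum(cents[, 1L] * w), sum(cents[, 2L] * w))
}
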