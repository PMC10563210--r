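#' Read region polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features, each with
#' a `region_id` property. Only outer rings are used (the pipeline needs
#' areas, centroids and boundary adjacency, not holes). Centroids are
#' area-weighted across the parts of a MultiPolygon. Coordinates are taken as
#' planar; project geographic data before use.
#'
#' @param path GeoJSON file path.
#' @return A [region_set].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_arg("expected a GeoJSON FeatureCollection in ", path)
  }
  feats <- gj$features
  if (length(feats) == 0L) stop_arg("no features in ", path)
  ids <- character(length(feats))
  polys <- vector("list", length(feats))
  cents <- matrix(0, length(feats), 2L)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    rid <- f$properties$region_id
    if (is.null(rid)) stop_arg("feature ", i, " has no region_id property")
    ids[i] <- as.character(rid)
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = list(g$coordinates[[1L]]),
      MultiPolygon = lapply(g$coordinates, function(p) p[[1L]]),
      stop_arg("feature ", i, " (", rid, "): unsupported geometry type ", g$type))
    rings <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(v) as.numeric(v[1:2])))
      colnames(m) <- c("x", "y")
      if (nrow(m) < 4L || any(m[1L, ] != m[nrow(m), ])) {
        stop_arg("feature ", rid, ": ring not closed")
      }
      m
    })
    areas <- vapply(rings, ring_area, numeric(1L))
    if (sum(areas) <= 0) stop_arg("feature ", rid, ": zero-area geometry")
    polys[[i]] <- rings
    cents[i, ] <- multipart_centroid(rings)
  }
  new_region_set(ids, polys, cents)
}

#' Write a region set (with optional attributes) to GeoJSON
#'
#' Emits a FeatureCollection of Polygon/MultiPolygon features carrying
#' `region_id` plus any extra per-region columns in `properties` (e.g. LISA
#' labels or Gi* bins).
#'
#' @param regions A [region_set].
#' @param path Output path.
#' @param properties Optional data frame of extra per-region properties with
#'   a `region_id` column.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, properties = NULL) {
  stopifnot(is_region_set(regions))
  polys <- region_polygons(regions)
  extra <- NULL
  if (!is.null(properties)) {
    if (!is.data.frame(properties) || !"region_id" %in% names(properties)) {
      stop_arg("properties must be a data frame with a region_id column")
    }
    extra <- properties[match(regions$region_id, properties$region_id), , drop = FALSE]
  }
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    rings <- polys[[i]]
    coords <- lapply(rings, function(m) {
      lapply(seq_len(nrow(m)), function(j) c(m[j, 1L], m[j, 2L]))
    })
    geom <- if (length(rings) == 1L) {
      list(type = "Polygon", coordinates = coords)
    } else {
      list(type = "MultiPolygon", coordinates = lapply(coords, list))
    }
    props <- list(region_id = regions$region_id[i])
    if (!is.null(extra)) {
      for (nm in setdiff(names(extra), "region_id")) {
        v <- extra[[nm]][i]
        props[[nm]] <- if (is.na(v)) NULL else v
      }
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}

#' Kriged / gridded surfaces and ESRI ASCII grid I/O
#'
#' A `grid_surface` couples a value matrix with its georeferencing: cell
#' centres at `xll + (col - 1/2) * cellsize`, row 1 of the matrix being the
#' northernmost row (as in the ESRI ASCII `.asc` format).
#'
#' @param values Numeric matrix (`nrows x ncols`, row 1 = north).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Positive cell size.
#' @param nodata Value written for `NA` cells (default -9999).
#' @return A `grid_surface` object.
#' @export
grid_surface <- function(values, xll, yll, cellsize, nodata = -9999) {
  if (!is.matrix(values)) stop_arg("values must be a matrix")
  if (!is_number(cellsize) || cellsize <= 0) stop_arg("cellsize must be positive")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_surface")
}

#' @rdname grid_surface
#' @param surface A `grid_surface`.
#' @param path Output `.asc` path.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "grid_surface"))
  v <- surface$values
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", sprintf_num(surface$xll)),
           paste("yllcorner", sprintf_num(surface$yll)),
           paste("cellsize", sprintf_num(surface$cellsize)),
           paste("NODATA_value", sprintf_num(surface$nodata)))
  v[is.na(v)] <- surface$nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname grid_surface
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1L), 1L))
  vals <- as.numeric(vapply(hdr, `[`, character(1L), 2L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!identical(keys, need)) stop_arg("malformed ESRI ASCII grid header in ", path)
  ncols <- as.integer(vals[1L]); nrows <- as.integer(vals[2L])
  body <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  if (length(body) != ncols * nrows) {
    stop_arg("grid body has ", length(body), " values, expected ", ncols * nrows)
  }
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == vals[6L]] <- NA_real_
  grid_surface(m, vals[3L], vals[4L], vals[5L], vals[6L])
}

#' @export
print.grid_surface <- function(x, ...) {
  cat("<grid_surface> ", nrow(x$values), " x ", ncol(x$values),
      " cells of size ", format(x$cellsize),
      ", origin (", format(x$xll), ", ", format(x$yll), ")\n", sep = "")
  invisible(x)
}
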