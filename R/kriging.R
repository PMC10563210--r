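#' Polynomial trend surface removal
#'
#' Least-squares fit of a polynomial surface in (x, y) of order 0, 1 or 2
#' (monomials from {1, x, y, x^2, xy, y^2}), returning the fitted model and
#' the residuals. Kriging the residuals and re-adding the trend at
#' prediction time implements interpolation with external drift removed —
#' the usual prelude when a field shows a global (e.g. second-order) trend.
#'
#' @param coords Two-column matrix of planar coordinates.
#' @param values Numeric vector of values.
#' @param order Polynomial order: 0, 1 or 2.
#' @return A list with `model` (a `trend_model`: `order`, `coef`, `terms`)
#'   and `residuals`.
#' @export
remove_trend <- function(coords, values, order = 2L) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  if (!order %in% 0:2) stop_arg("order must be 0, 1 or 2")
  X <- trend_design(xy, order)
  if (nrow(X) <= ncol(X)) {
    stop_arg("need more points (", nrow(X), ") than monomials (", ncol(X), ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_arg("rank-deficient trend design (collinear coordinates?)")
  }
  beta <- qr.coef(qrX, z)
  fitted <- drop(X %*% beta)
  model <- structure(list(order = as.integer(order), coef = beta,
                          terms = colnames(X)),
                     class = "trend_model")
  list(model = model, residuals = z - fitted)
}

trend_design <- function(xy, order) {
  x <- xy[, 1L]; y <- xy[, 2L]
  X <- switch(as.character(order),
    "0" = cbind(`1` = rep(1, length(x))),
    "1" = cbind(`1` = 1, x = x, y = y),
    "2" = cbind(`1` = 1, x = x, y = y, `x^2` = x^2, xy = x * y, `y^2` = y^2))
  X
}

#' Evaluate a fitted trend surface
#'
#' @param model A `trend_model` from [remove_trend()].
#' @param coords Two-column matrix of planar coordinates.
#' @return Vector of trend values.
#' @export
predict_trend <- function(model, coords) {
  stopifnot(inherits(model, "trend_model"))
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  drop(trend_design(xy, model$order) %*% model$coef)
}

# Deduplicate coincident points by averaging their values.
dedup_points <- function(xy, z, tol = 1e-10) {
  key <- paste(round(xy[, 1L] / tol), round(xy[, 2L] / tol))
  if (!anyDuplicated(key)) return(list(xy = xy, z = z, deduped = FALSE))
  warning("coincident points averaged before kriging", call. = FALSE)
  idx <- split(seq_along(z), key)
  first <- vapply(idx, `[`, integer(1L), 1L)
  ord <- order(first)
  xy2 <- xy[first[ord], , drop = FALSE]
  z2 <- vapply(idx, function(i) mean(z[i]), numeric(1L))[ord]
  list(xy = xy2, z = z2, deduped = TRUE)
}

# Core ordinary-kriging solve: returns predictions and variances at newxy.
krige_core <- function(xy, z, model, newxy) {
  n <- nrow(xy)
  G <- matrix(0, n, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(xy))
    G[] <- variogram_gamma(model, d)
    diag(G) <- 0
  }
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(newxy[, 1L], xy[, 1L], "-")^2 +
               outer(newxy[, 2L], xy[, 2L], "-")^2)
  g0 <- matrix(variogram_gamma(model, d0), nrow = nrow(newxy))
  B <- rbind(t(g0), 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop_arg("singular ordinary-kriging system: ", conditionMessage(e))
  })
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- drop(crossprod(lambda, z))
  var <- colSums(lambda * t(g0)) + mu
  var <- pmax(var, 0)  # clip tiny negative round-off
  list(pred = pred, var = var, lambda = lambda, mu = mu)
}

#' Ordinary kriging onto a regular grid
#'
#' Solves the ordinary-kriging system (semivariance matrix augmented with
#' the unbiasedness constraint, so the weights sum to one at every node)
#' for each cell centre of a regular grid, returning the prediction surface
#' and the kriging variance. Coincident data points are averaged first with
#' a warning. When a `trend_model` is supplied, `values` must be the
#' residuals from [remove_trend()]; the trend is evaluated at the grid nodes
#' and re-added to the predictions.
#'
#' @param coords Two-column matrix of data point coordinates.
#' @param values Data values (residuals when `trend` is given).
#' @param model A `variogram_model`.
#' @param grid Grid specification: list with `xll`, `yll`, `cellsize`,
#'   `ncols`, `nrows` (cell-centre registration, as in the ESRI ASCII
#'   format). See [grid_over_regions()] for a convenient constructor.
#' @param trend Optional `trend_model` to re-add to predictions.
#' @return A list with `prediction` and `variance`, both [grid_surface]
#'   objects.
#' @export
ordinary_krige <- function(coords, values, model, grid, trend = NULL) {
  stopifnot(inherits(model, "variogram_model"))
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  if (length(z) != nrow(xy)) stop_arg("coords/values length mismatch")
  dd <- dedup_points(xy, z)
  xy <- dd$xy; z <- dd$z
  if (nrow(xy) < 1L) stop_arg("need at least one data point")
  need <- c("xll", "yll", "cellsize", "ncols", "nrows")
  if (!is.list(grid) || !all(need %in% names(grid))) {
    stop_arg("grid must be a list with ", paste(need, collapse = ", "))
  }
  gx <- grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  gy <- grid$yll + (seq_len(grid$nrows) - 0.5) * grid$cellsize
  newxy <- cbind(rep(gx, times = grid$nrows),
                 rep(rev(gy), each = grid$ncols))  # row 1 = north
  ok <- krige_core(xy, z, model, newxy)
  pred <- ok$pred
  if (!is.null(trend)) pred <- pred + predict_trend(trend, newxy)
  pm <- matrix(pred, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  vm <- matrix(ok$var, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  list(prediction = grid_surface(pm, grid$xll, grid$yll, grid$cellsize),
       variance = grid_surface(vm, grid$xll, grid$yll, grid$cellsize))
}

#' Ordinary kriging at arbitrary points
#'
#' Point-prediction variant of [ordinary_krige()], used by the
#' cross-validator and convenient in tests.
#'
#' @inheritParams ordinary_krige
#' @param newcoords Two-column matrix of prediction locations.
#' @param weights Also return the kriging weight matrix.
#' @return A list with `prediction`, `variance` and (optionally) `lambda`
#'   (n data x m prediction weight matrix).
#' @export
krige_points <- function(coords, values, model, newcoords, trend = NULL,
                         weights = FALSE) {
  stopifnot(inherits(model, "variogram_model"))
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  dd <- dedup_points(xy, z)
  ok <- krige_core(dd$xy, dd$z, model,
                   as.matrix(newcoords)[, 1:2, drop = FALSE])
  pred <- ok$pred
  if (!is.null(trend)) pred <- pred + predict_trend(trend, newcoords)
  out <- list(prediction = pred, variance = ok$var)
  if (weights) out$lambda <- ok$lambda
  out
}

#' Grid specification covering a region set
#'
#' @param regions A [region_set].
#' @param ncols Number of grid columns (rows follow from the aspect ratio).
#' @param pad Fractional padding added around the centroid bounding box.
#' @return A grid list for [ordinary_krige()].
#' @export
grid_over_regions <- function(regions, ncols = 40L, pad = 0.05) {
  stopifnot(is_region_set(regions))
  xr <- range(regions$cx); yr <- range(regions$cy)
  px <- diff(xr) * pad + 1e-9; py <- diff(yr) * pad + 1e-9
  xll <- xr[1L] - px; yll <- yr[1L] - py
  width <- diff(xr) + 2 * px
  cellsize <- width / ncols
  nrows <- max(1L, ceiling((diff(yr) + 2 * py) / cellsize))
  list(xll = xll, yll = yll, cellsize = cellsize,
       ncols = as.integer(ncols), nrows = as.integer(nrows))
}

#' Leave-one-out cross-validation of an ordinary-kriging model
#'
#' Each point is removed in turn and re-predicted from the remaining points.
#' When `trend` is given, `values` must be the trend residuals; errors are
#' then reported on the residual scale (the trend contribution cancels).
#'
#' @inheritParams ordinary_krige
#' @return A list with `errors` (data frame `observed`, `predicted`,
#'   `error`, `kriging_sd`), `rmse`, `me` (mean error) and
#'   `mse_standardized` (mean of error / kriging SD).
#' @export
loo_cross_validate <- function(coords, values, model, trend = NULL) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  n <- nrow(xy)
  if (n < 10L) stop_arg("need at least 10 points for cross-validation")
  if (!is.null(trend)) {
    z <- z - predict_trend(trend, xy)
  }
  pred <- numeric(n); kv <- numeric(n)
  for (i in seq_len(n)) {
    ok <- krige_core(xy[-i, , drop = FALSE], z[-i], model,
                     xy[i, , drop = FALSE])
    pred[i] <- ok$pred
    kv[i] <- ok$var
  }
  err <- pred - z
  ksd <- sqrt(kv)
  std <- ifelse(ksd > 0, err / ksd, NA_real_)
  list(errors = data.frame(observed = z, predicted = pred, error = err,
                           kriging_sd = ksd),
       rmse = sqrt(mean(err^2)),
       me = mean(err),
       mse_standardized = mean(std, na.rm = TRUE))
}
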