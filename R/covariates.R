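#' Resample a raster onto a target geometry
#'
#' Continuous layers are resampled by bilinear interpolation between the four
#' surrounding source cell centres; if any of the four is nodata the nearest
#' valid corner is used instead, and if all four are nodata the cell becomes
#' nodata. Categorical layers always take the nearest source cell centre.
#' Target cells whose centres fall outside the source extent become nodata.
#'
#' @param grid source [pod_raster].
#' @param target a [pod_raster] (only its geometry is used) or a list with
#'   `n_rows`, `n_cols`, `origin_x`, `origin_y`, `cell_size`.
#' @return a [pod_raster] on the target geometry.
#' @export
resample <- function(grid, target) {
  geo <- as_geometry(target)
  tx <- geo$origin_x + (seq_len(geo$n_cols) - 0.5) * geo$cell_size
  ty <- geo$origin_y - (seq_len(geo$n_rows) - 0.5) * geo$cell_size
  x <- rep(tx, each = geo$n_rows)
  y <- rep(ty, times = geo$n_cols)
  inside <- raster_contains(grid, x, y)
  if (!any(inside)) stop("source and target extents do not overlap", call. = FALSE)

  vals <- rep(NA_real_, length(x))
  if (grid$kind == "categorical") {
    idx <- raster_cell_index(grid, x[inside], y[inside])
    vals[inside] <- grid$values[cbind(idx$row, idx$col)]
  } else {
    vals[inside] <- bilinear_at(grid, x[inside], y[inside])
  }
  pod_raster(matrix(vals, geo$n_rows, geo$n_cols),
             origin_x = geo$origin_x, origin_y = geo$origin_y,
             cell_size = geo$cell_size, kind = grid$kind)
}

as_geometry <- function(target) {
  if (inherits(target, "pod_raster")) {
    list(n_rows = nrow(target$values), n_cols = ncol(target$values),
         origin_x = target$origin_x, origin_y = target$origin_y,
         cell_size = target$cell_size)
  } else {
    stopifnot(all(c("n_rows", "n_cols", "origin_x", "origin_y", "cell_size") %in% names(target)))
    target
  }
}

# bilinear interpolation on source cell centres; clamps to the outer centre
# ring so cells between the grid edge and the first centre take edge values
bilinear_at <- function(grid, x, y) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cell_size
  # fractional (0-based) centre coordinates
  fc <- (x - grid$origin_x) / cs - 0.5
  fr <- (grid$origin_y - y) / cs - 0.5
  fc <- pmin(pmax(fc, 0), nc - 1)
  fr <- pmin(pmax(fr, 0), nr - 1)
  c0 <- pmin(floor(fc), nc - 2); c0[nc == 1] <- 0
  r0 <- pmin(floor(fr), nr - 2); r0[nr == 1] <- 0
  if (nc == 1) fc <- fc * 0
  if (nr == 1) fr <- fr * 0
  wx <- fc - c0
  wy <- fr - r0
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, pmin(c0 + 2, nc))
  i10 <- cbind(pmin(r0 + 2, nr), c0 + 1)
  i11 <- cbind(pmin(r0 + 2, nr), pmin(c0 + 2, nc))
  v00 <- v[i00]; v01 <- v[i01]; v10 <- v[i10]; v11 <- v[i11]
  out <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)

  bad <- is.na(v00) | is.na(v01) | is.na(v10) | is.na(v11)
  if (any(bad)) {
    # nearest valid corner fallback
    corners <- array(c(v00, v01, v10, v11), dim = c(length(out), 4L))
    d <- cbind(
      wx^2 + wy^2, (1 - wx)^2 + wy^2,
      wx^2 + (1 - wy)^2, (1 - wx)^2 + (1 - wy)^2
    )
    d[is.na(corners)] <- Inf
    pick <- max.col(-d, ties.method = "first")
    fb <- corners[cbind(seq_along(pick), pick)]
    out[bad] <- fb[bad]
  }
  out
}

#' Align a set of rasters to a land mask
#'
#' Each grid is resampled (bilinear or nearest-neighbour according to its
#' `kind`) to the land-mask geometry; cells outside the mask, or outside the
#' grid's own extent, become nodata. Mirrors the extend/clip-and-align step
#' used to harmonise heterogeneous covariate sources.
#'
#' @param grids named list of [pod_raster]s.
#' @param land_mask 0/1 [pod_raster] defining the target geometry.
#' @return a [pod_stack].
#' @export
align_stack <- function(grids, land_mask) {
  if (length(grids) == 0L) stop("at least one grid is required", call. = FALSE)
  aligned <- lapply(grids, resample, target = land_mask)
  pod_stack(aligned, land_mask)
}

#' Terrain slope from elevation
#'
#' Horn's 3x3 finite-difference gradient with replicated borders;
#' slope = atan(sqrt(gx^2 + gy^2)) in degrees.
#'
#' @param elev elevation [pod_raster].
#' @param z_factor multiplier converting elevation units into the horizontal
#'   length units of `cell_size` (e.g. `0.001` for metre elevations on a
#'   kilometre grid).
#' @return a [pod_raster] of slope in degrees.
#' @export
slope_from_elevation <- function(elev, z_factor = 1) {
  v <- elev$values * z_factor
  if (all(is.na(v))) stop("elevation raster is all nodata", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  # replicated-border padding
  up <- v[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- v[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  lf <- v[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- v[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  ul <- up[, c(1, seq_len(nc - 1)), drop = FALSE]
  ur <- up[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  dl <- dn[, c(1, seq_len(nc - 1)), drop = FALSE]
  dr <- dn[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  cs <- elev$cell_size
  gx <- ((ur + 2 * rt + dr) - (ul + 2 * lf + dl)) / (8 * cs)
  gy <- ((dl + 2 * dn + dr) - (ul + 2 * up + ur)) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  pod_raster(slope, origin_x = elev$origin_x, origin_y = elev$origin_y,
             cell_size = elev$cell_size)
}

#' Straight-line distance to the nearest feature cell
#'
#' Euclidean distance from every cell centre to the nearest centre of a
#' feature cell (e.g. a water body), in the grid's length units. Feature
#' cells get distance 0. Exact all-pairs minimisation, computed in blocks.
#'
#' @param feature_mask binary [pod_raster]; cells with value 1 are features.
#' @return a [pod_raster] of distances.
#' @export
distance_to_feature <- function(feature_mask) {
  v <- feature_mask$values
  feat <- which(!is.na(v) & v == 1)
  if (length(feat) == 0L) stop("feature mask contains no feature cells", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v); cs <- feature_mask$cell_size
  fr <- ((feat - 1) %% nr) + 1
  fc <- ((feat - 1) %/% nr) + 1
  out <- matrix(NA_real_, nr, nc)
  rows <- seq_len(nr)
  # process column blocks to bound memory at ~length(feat) * nr * block
  block <- max(1L, floor(2e6 / (length(feat) * nr)) )
  for (c0 in seq(1L, nc, by = block)) {
    cols <- c0:min(c0 + block - 1L, nc)
    dr2 <- outer(rows, fr, function(a, b) (a - b)^2)
    for (cc in cols) {
      d2 <- dr2 + matrix((cc - fc)^2, nrow = nr, ncol = length(fc), byrow = TRUE)
      out[, cc] <- sqrt(matrixRowMins(d2)) * cs
    }
  }
  pod_raster(out, origin_x = feature_mask$origin_x, origin_y = feature_mask$origin_y,
             cell_size = cs)
}

matrixRowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Extract covariate values at survey points
#'
#' Looks up the containing cell of each point in every layer of the stack.
#'
#' @param stack a [pod_stack].
#' @param points a data frame with `lon` and `lat` columns (planar km
#'   coordinates) and optionally an id column carried through.
#' @param covariates layer names to extract (default all).
#' @return a tibble: the input columns plus one column per covariate and a
#'   logical `complete` flag (FALSE where any layer is nodata, e.g. masked
#'   sea cells).
#' @export
extract_at_points <- function(stack, points, covariates = names(stack)) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  mask <- stack$land_mask
  inside <- raster_contains(mask, points$lon, points$lat)
  if (any(!inside)) {
    stop(sum(!inside), " point(s) fall outside the stack extent", call. = FALSE)
  }
  idx <- raster_cell_index(mask, points$lon, points$lat)
  out <- tibble::as_tibble(points)
  for (nm in covariates) {
    g <- stack[[nm]]
    out[[nm]] <- g$values[cbind(idx$row, idx$col)]
  }
  out$complete <- stats::complete.cases(out[covariates])
  out
}

#' Collinearity screen for candidate covariates
#'
#' Computes pairwise Pearson correlations and greedily resolves every pair
#' with |r| above the threshold: the worst offending pair is found and the
#' member with the larger mean absolute correlation against all remaining
#' covariates is dropped, repeating until no pair exceeds the threshold.
#' Nonlinearly related covariates (e.g. x and x^2 over a symmetric range)
#' have small |r| and are retained untouched. Deterministic: exact ties are
#' broken by column-name order.
#'
#' @param design data frame of candidate covariate columns (non-numeric
#'   columns and `complete`/id columns are ignored); rows with missing values
#'   are dropped.
#' @param threshold correlation magnitude above which a pair is collinear
#'   (default 0.7).
#' @return a list of class `pod_collinearity`: `retained`, `dropped` (tibble
#'   with the correlation that triggered each drop), and `cor_matrix`.
#' @export
collinearity_filter <- function(design, threshold = 0.7) {
  num <- vapply(design, is.numeric, logical(1))
  skip <- names(design) %in% c("complete", "row", "col", "x", "y", "lon", "lat",
                               "point_id", "community_id")
  X <- as.data.frame(design[, num & !skip, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2L) stop("need at least two covariate columns", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least three complete rows", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(names(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  full_cor <- stats::cor(X)
  keep <- sort(colnames(full_cor))
  dropped <- list()
  repeat {
    cm <- abs(full_cor[keep, keep, drop = FALSE])
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    hit <- which(cm == worst, arr.ind = TRUE)[1L, ]
    pair <- keep[hit]
    mac <- rowMeans(cm[pair, , drop = FALSE])
    # drop the member more correlated with everything else; ties by name order
    drop_nm <- if (mac[1] > mac[2]) pair[1] else if (mac[2] > mac[1]) pair[2] else sort(pair)[2]
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      covariate = drop_nm,
      partner = setdiff(pair, drop_nm),
      abs_r = worst
    )
    keep <- setdiff(keep, drop_nm)
  }
  structure(
    list(
      retained = keep,
      dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
        tibble::tibble(covariate = character(), partner = character(), abs_r = numeric()),
      cor_matrix = full_cor,
      threshold = threshold
    ),
    class = "pod_collinearity"
  )
}

#' @export
print.pod_collinearity <- function(x, ...) {
  cat(sprintf("<pod_collinearity> threshold |r| > %g\n", x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped :", paste(sprintf("%s (|r|=%.2f with %s)", x$dropped$covariate,
                                     x$dropped$abs_r, x$dropped$partner),
                             collapse = "; "), "\n")
  } else {
    cat("  dropped : none\n")
  }
  invisible(x)
}
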