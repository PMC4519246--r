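#' Gridded raster surfaces
#'
#' `pod_raster()` builds the package's single-band raster container: a numeric
#' matrix with a planar geotransform. Row 1 is the top of the map (maximum y),
#' the origin is the *outer* corner of cell (1, 1), and values are referenced
#' to cell centres. Missing cells (sea, outside the land mask) are stored as
#' `NA`; a numeric nodata sentinel is only used on disk.
#'
#' @param values numeric matrix (rows top to bottom).
#' @param origin_x,origin_y coordinates of the top-left corner of the grid, in
#'   the same length units as `cell_size` (km throughout the package).
#' @param cell_size positive cell edge length (km per cell).
#' @param kind `"continuous"` (bilinear resampling) or `"categorical"`
#'   (nearest-neighbour resampling).
#' @return an object of class `pod_raster`.
#' @examples
#' r <- pod_raster(matrix(1:12, 3, 4), cell_size = 1)
#' r
#' @export
pod_raster <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                       cell_size = 1, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      values = values,
      origin_x = as.numeric(origin_x),
      origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      kind = kind
    ),
    class = "pod_raster"
  )
}

#' @export
print.pod_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<pod_raster> %d x %d cells, cell size %g, origin (%g, %g), %s\n",
    nrow(v), ncol(v), x$cell_size, x$origin_x, x$origin_y, x$kind
  ))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf(
      "  values: [%g, %g], %d nodata cells\n",
      min(v[ok]), max(v[ok]), sum(!ok)
    ))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @export
dim.pod_raster <- function(x) dim(x$values)

raster_same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell-centre coordinates of every cell
#'
#' @param grid a [pod_raster].
#' @return a tibble with one row per cell: `row`, `col`, `x`, `y`, `value`.
#' @export
raster_xy <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  tibble::tibble(
    row = row, col = col,
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y - (row - 0.5) * grid$cell_size,
    value = as.vector(v)
  )
}

#' @export
as.data.frame.pod_raster <- function(x, ...) as.data.frame(raster_xy(x))

#' @importFrom tibble as_tibble
#' @export
as_tibble.pod_raster <- function(x, ...) raster_xy(x)

# containing-cell index for point coordinates; points on a shared edge belong
# to the cell below/right of it (floor convention)
raster_cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  # points exactly on the far outer edge fall in the last cell
  col[x == grid$origin_x + ncol(grid$values) * grid$cell_size] <- ncol(grid$values)
  row[y == grid$origin_y - nrow(grid$values) * grid$cell_size] <- nrow(grid$values)
  list(row = as.integer(row), col = as.integer(col))
}

raster_contains <- function(grid, x, y) {
  xmax <- grid$origin_x + ncol(grid$values) * grid$cell_size
  ymin <- grid$origin_y - nrow(grid$values) * grid$cell_size
  x >= grid$origin_x & x <= xmax & y >= ymin & y <= grid$origin_y
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster I/O. The on-disk header records the
#' lower-left corner (`xllcorner`/`yllcorner`), cell size, and a nodata
#' sentinel; rows are written top to bottom. Values round-trip at full double
#' precision.
#'
#' @param grid a [pod_raster].
#' @param path file path (conventionally `.asc`).
#' @param nodata numeric sentinel written for `NA` cells; must not collide
#'   with a data value.
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns a
#'   [pod_raster].
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  if (any(v[!is.na(v)] == nodata)) {
    stop("nodata sentinel ", nodata, " collides with a data value", call. = FALSE)
  }
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %s", format(grid$origin_x, digits = 17)),
    sprintf("yllcorner %s", format(grid$origin_y - nrow(v) * grid$cell_size, digits = 17)),
    sprintf("cellsize %s", format(grid$cell_size, digits = 17)),
    sprintf("NODATA_value %s", format(nodata, digits = 17))
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @param kind passed to [pod_raster()] on read.
#' @export
read_asc <- function(path, kind = "continuous") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(sub("^\\S+\\s+", "", ln))
  }
  nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
  xll <- get("xllcorner"); yll <- get("yllcorner")
  cs <- get("cellsize"); nodata <- get("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) stop("ASCII grid body has wrong cell count", call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  pod_raster(m, origin_x = xll, origin_y = yll + nr * cs, cell_size = cs, kind = kind)
}

#' Covariate stacks
#'
#' A named collection of [pod_raster] layers sharing one geometry, plus a 0/1
#' land mask. Cells where the mask is 0 are forced to `NA` in every layer.
#'
#' @param grids named list of [pod_raster]s.
#' @param land_mask a 0/1 [pod_raster] on the same geometry.
#' @return an object of class `pod_stack`.
#' @export
pod_stack <- function(grids, land_mask) {
  if (length(grids) == 0L) stop("at least one grid is required", call. = FALSE)
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    stop("all grids must be named", call. = FALSE)
  }
  for (nm in names(grids)) {
    if (!raster_same_geometry(grids[[nm]], land_mask)) {
      stop("grid '", nm, "' does not share the land-mask geometry", call. = FALSE)
    }
  }
  sea <- !is.na(land_mask$values) & land_mask$values == 0
  grids <- lapply(grids, function(g) {
    g$values[sea | is.na(land_mask$values)] <- NA_real_
    g
  })
  structure(list(grids = grids, land_mask = land_mask), class = "pod_stack")
}

#' @export
print.pod_stack <- function(x, ...) {
  d <- dim(x$land_mask$values)
  cat(sprintf(
    "<pod_stack> %d layers on a %d x %d grid: %s\n",
    length(x$grids), d[1], d[2], paste(names(x$grids), collapse = ", ")
  ))
  invisible(x)
}

#' @export
names.pod_stack <- function(x) names(x$grids)

#' @export
`[[.pod_stack` <- function(x, name) x$grids[[name]]

#' Land-pixel design matrix of a stack
#'
#' Flattens a stack to one row per land cell with complete covariate values,
#' ready for model prediction over the map.
#'
#' @param stack a [pod_stack].
#' @param covariates layer names to include (default: all).
#' @return a tibble with `row`, `col`, `x`, `y` and one column per covariate;
#'   only cells on land with no nodata in any requested layer are kept.
#' @export
stack_design <- function(stack, covariates = names(stack)) {
  missing_cov <- setdiff(covariates, names(stack))
  if (length(missing_cov)) {
    stop("stack is missing covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  base <- raster_xy(stack$land_mask)
  out <- base[, c("row", "col", "x", "y")]
  for (nm in covariates) out[[nm]] <- as.vector(stack[[nm]]$values)
  land <- !is.na(base$value) & base$value == 1
  keep <- land & stats::complete.cases(out[covariates])
  out[keep, , drop = FALSE]
}
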