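#' Georeferenced grid raster
#'
#' A minimal matrix-backed raster: a rectangular grid of square cells in a
#' projected (planar, metre) coordinate system. Row 1 is the top of the map;
#' x increases with column, y decreases with row. Carries habitat suitability,
#' resistance, current density or binary masks throughout the package.
#'
#' @param values Numeric matrix (rows = y from top, cols = x).
#' @param cell_size Cell edge length in metres (default 30, the analysis
#'   resolution used for all grids).
#' @param origin Numeric length-2: (x0, y0) of the *upper-left corner* of the
#'   upper-left cell, in metres.
#' @param nodata Value in `values` to treat as missing; converted to `NA`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 30, origin = c(0, 0),
                        nodata = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be (x0, y0) in metres")
  if (!is.null(nodata)) values[values == nodata] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells @ %g m (origin %g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(fin), max(fin),
                sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-centre coordinates
#'
#' @param grid A `grid_raster`.
#' @param rows,cols Integer vectors of equal length (recycled).
#' @return Matrix with columns `x`, `y` (metres).
#' @export
cell_xy <- function(grid, rows, cols) {
  cs <- grid$cell_size
  cbind(x = grid$origin[1] + (cols - 0.5) * cs,
        y = grid$origin[2] - (rows - 0.5) * cs)
}

#' Cell indices for point coordinates
#'
#' Points outside the grid extent get `NA` row/col.
#'
#' @param grid A `grid_raster`.
#' @param x,y Point coordinates in metres.
#' @return Matrix with columns `row`, `col`.
#' @export
xy_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- ceiling((x - grid$origin[1]) / cs)
  row <- ceiling((grid$origin[2] - y) / cs)
  # points exactly on the top/left boundary belong to the first row/col
  col[col == 0L & x == grid$origin[1]] <- 1L
  row[row == 0L & y == grid$origin[2]] <- 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Do two rasters share grid geometry?
#' @param a,b `grid_raster` objects.
#' @return Logical.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_aligned <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b)) stop(what, " are not aligned (grid geometry differs)")
  invisible(TRUE)
}

#' Write a grid to an Esri ASCII (.asc) file
#'
#' Plain-text raster interchange format readable by every GIS. `NA` cells are
#' written as the nodata sentinel.
#'
#' @param grid A `grid_raster`.
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  yll <- grid$origin[2] - nrow(v) * grid$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Esri ASCII (.asc) raster
#'
#' @param path File path.
#' @return A `grid_raster` (nodata cells as `NA`).
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(p)
    c(tolower(p[1]), p[2]))
  hdr <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  ncols <- as.integer(hdr[["ncols"]]); nrows <- as.integer(hdr[["nrows"]])
  cs <- as.numeric(hdr[["cellsize"]])
  nd <- as.numeric(hdr[["nodata_value"]])
  vals <- scan(path, skip = 6L, quiet = TRUE)
  stopifnot(length(vals) == nrows * ncols)
  v <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  origin <- c(as.numeric(hdr[["xllcorner"]]),
              as.numeric(hdr[["yllcorner"]]) + nrows * cs)
  grid_raster(v, cell_size = cs, origin = origin, nodata = nd)
}
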