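#' Define a regular planar grid
#'
#' A `grid_spec` describes a regular grid of square cells in projected planar
#' coordinates (meters). Cells are half-open: a point belongs to cell
#' `(floor((x - x0)/res), floor((y - y0)/res))`, so a point exactly on a
#' shared edge belongs to the cell above/right of it.
#'
#' @param x0,y0 Coordinates of the lower-left corner of the grid, in meters.
#' @param res Cell size in meters (cells are square).
#' @param n_rows,n_cols Number of rows (y direction) and columns (x direction).
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(0, 0, res = 2000, n_rows = 30, n_cols = 30)
#' cell_of(spec, x = 1999, y = 0)  # cell 1 (row 1, col 1)
#' @export
grid_spec <- function(x0, y0, res, n_rows, n_cols) {
  stopifnot_scalar_number(x0, "x0")
  stopifnot_scalar_number(y0, "y0")
  stopifnot_scalar_number(res, "res")
  if (res <= 0) abort("`res` must be > 0.")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) abort("`n_rows` and `n_cols` must be >= 1.")
  structure(
    list(x0 = x0, y0 = y0, res = res, n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$res, x$x0, x$y0
  ))
  invisible(x)
}

n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Map points to grid cells
#'
#' Returns the linear cell index (1-based, column-major: `row + (col-1) *
#' n_rows`, rows counted from the bottom) for each point, or `NA` for points
#' outside the grid.
#'
#' @param spec A [grid_spec()].
#' @param x,y Numeric vectors of planar coordinates in meters.
#' @return Integer vector of cell indices (NA outside the grid).
#' @export
cell_of <- function(spec, x, y) {
  col <- floor((x - spec$x0) / spec$res) + 1
  row <- floor((y - spec$y0) / spec$res) + 1
  out <- row + (col - 1) * spec$n_rows
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    !is.finite(x) | !is.finite(y)
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `cell`, `x`, `y` (centers, meters), ordered
#'   by linear cell index.
#' @export
cell_centers <- function(spec) {
  rows <- seq_len(spec$n_rows)
  cols <- seq_len(spec$n_cols)
  tibble::tibble(
    cell = seq_len(n_cells(spec)),
    x = spec$x0 + (rep(cols, each = spec$n_rows) - 0.5) * spec$res,
    y = spec$y0 + (rep(rows, times = spec$n_cols) - 0.5) * spec$res
  )
}

#' Construct a raster grid
#'
#' A `raster_grid` couples a [grid_spec()] with one numeric value per cell
#' (a habitat covariate, an occurrence distribution, or a derived indicator).
#'
#' @param spec A [grid_spec()].
#' @param values Numeric vector of length `n_rows * n_cols` (column-major,
#'   rows from the bottom) or a matrix with `n_rows` rows and `n_cols` columns.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(spec, values) {
  if (!inherits(spec, "grid_spec")) abort("`spec` must be a grid_spec.")
  if (is.matrix(values)) {
    if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
      abort("`values` matrix dimensions do not match the grid spec.")
    }
    values <- as.numeric(values)
  }
  if (length(values) != n_cells(spec)) {
    abort("`values` must have one entry per grid cell.")
  }
  structure(list(spec = spec, values = as.numeric(values)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<raster_grid> %d x %d cells of %g m; values in [%.4g, %.4g]\n",
    x$spec$n_rows, x$spec$n_cols, x$spec$res, rng[1], rng[2]
  ))
  invisible(x)
}

#' Look up raster values at points
#'
#' @param grid A [raster_grid()].
#' @param x,y Planar coordinates in meters.
#' @param outside Value returned for points outside the grid (default `NA`).
#' @return Numeric vector of cell values.
#' @export
raster_value_at <- function(grid, x, y, outside = NA_real_) {
  idx <- cell_of(grid$spec, x, y)
  out <- rep(outside, length(idx))
  ok <- !is.na(idx)
  out[ok] <- grid$values[idx[ok]]
  out
}

grid_matrix <- function(grid) {
  matrix(grid$values, nrow = grid$spec$n_rows, ncol = grid$spec$n_cols)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values, the top row first. Internally rows are stored bottom-up, so
#' reading and writing flips row order.
#'
#' @param grid A [raster_grid()].
#' @param path File path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  spec <- grid$spec
  m <- grid_matrix(grid)
  m[is.na(m)] <- nodata
  header <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$x0),
    sprintf("yllcorner %.10g", spec$y0),
    sprintf("cellsize %.10g", spec$res),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- vapply(
    rev(seq_len(spec$n_rows)),
    function(r) paste(formatC(m[r, ], format = "g", digits = 17), collapse = " "),
    character(1)
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[[`, character(1), 2))
  names(vals) <- keys
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% keys)) {
    abort("Malformed ASCII grid header (need ncols/nrows/xllcorner/yllcorner/cellsize).")
  }
  spec <- grid_spec(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
                    n_rows = vals[["nrows"]], n_cols = vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != n_cells(spec)) {
    abort("ASCII grid body does not match ncols * nrows.")
  }
  m <- matrix(body, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  m <- m[rev(seq_len(spec$n_rows)), , drop = FALSE]  # top row first on disk
  if ("nodata_value" %in% keys) m[m == vals[["nodata_value"]]] <- NA_real_
  raster_grid(spec, m)
}
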