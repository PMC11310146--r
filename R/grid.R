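#' Define a raster grid
#'
#' A grid of square cells in projected metre coordinates, x increasing east
#' and y increasing north. The origin is the lower-left corner of the extent;
#' cell centres sit at `origin + (index + 0.5) * cell_size` with 0-based
#' indices. Rows of any matrix laid on this grid run north-to-south (row 1 is
#' the northernmost row), matching the usual raster convention.
#'
#' @param n_rows,n_cols Number of rows (north-south) and columns (east-west).
#' @param cell_size Cell edge length in metres (default 2).
#' @param origin_x,origin_y Coordinates of the lower-left corner in metres.
#' @return A `gs_grid` object.
#' @examples
#' grid_spec(224, 448)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 2, origin_x = 0, origin_y = 0) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
    ),
    class = "gs_grid"
  )
}

#' @export
print.gs_grid <- function(x, ...) {
  cat(sprintf(
    "<gs_grid> %d x %d cells (%.0f cells), %.3g m resolution, origin (%.6g, %.6g)\n",
    x$n_rows, x$n_cols, n_cells(x), x$cell_size, x$origin_x, x$origin_y
  ))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `gs_grid`.
#' @export
n_cells <- function(grid) as.numeric(grid$n_rows) * as.numeric(grid$n_cols)

#' Wrap a value matrix as a raster on a grid
#'
#' @param values Numeric matrix with `grid$n_rows` rows and `grid$n_cols`
#'   columns; row 1 is the northernmost row.
#' @param grid A [grid_spec()].
#' @param name Layer name used in printing and tidying.
#' @return A `gs_raster` object.
#' @export
new_raster <- function(values, grid, name = "layer") {
  values <- as.matrix(values)
  stopifnot(
    inherits(grid, "gs_grid"),
    nrow(values) == grid$n_rows, ncol(values) == grid$n_cols
  )
  structure(list(grid = grid, values = values, name = name), class = "gs_raster")
}

#' @export
print.gs_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<gs_raster> '%s' %d x %d @ %.3g m, range [%.4g, %.4g]\n",
    x$name, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, rng[1], rng[2]
  ))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param grid A `gs_grid`.
#' @param row,col 1-based row (from north) and column (from west) indices.
#' @return Tibble with `x`, `y` centre coordinates (metres).
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(length(row) == length(col))
  tibble::tibble(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}

#' Locate points on a grid
#'
#' Point-in-cell uses half-open intervals `[left, right)` x `[bottom, top)`,
#' so a point exactly on the shared edge of two cells belongs to the cell on
#' its east/north side.
#'
#' @param grid A `gs_grid`.
#' @param x,y Point coordinates in metres.
#' @return Tibble with `row`, `col` (NA for points outside the extent).
#' @export
point_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin_x) / cs) + 1
  row_from_bottom <- floor((y - grid$origin_y) / cs) + 1
  row <- grid$n_rows - row_from_bottom + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Extent of a grid
#'
#' @param grid A `gs_grid`.
#' @return Named numeric vector `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
grid_extent <- function(grid) {
  c(
    xmin = grid$origin_x,
    xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y,
    ymax = grid$origin_y + grid$n_rows * grid$cell_size
  )
}

in_extent <- function(grid, x, y) {
  e <- grid_extent(grid)
  x >= e["xmin"] & x < e["xmax"] & y >= e["ymin"] & y < e["ymax"]
}

#' Extract raster values at points
#'
#' Nearest-cell lookup (the value of the cell containing each point); no
#' interpolation.
#'
#' @param raster A `gs_raster`.
#' @param x,y Point coordinates in metres.
#' @return Numeric vector of cell values (NA outside the extent).
#' @export
raster_extract <- function(raster, x, y) {
  rc <- point_to_cell(raster$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' @exportS3Method tibble::as_tibble
as_tibble.gs_raster <- function(x, ...) {
  g <- x$grid
  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  ctr <- cell_center(g, idx$row, idx$col)
  vals <- x$values[cbind(idx$row, idx$col)]
  tibble::tibble(
    row = as.integer(idx$row), col = as.integer(idx$col),
    x = ctr$x, y = ctr$y,
    value = vals
  )
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values north to south.
#'
#' @param raster A `gs_raster`.
#' @param path Output file path.
#' @param digits Significant digits written (default 7, float32-like).
#' @return `path`, invisibly (`read_ascii_grid` returns a `gs_raster`).
#' @export
write_ascii_grid <- function(raster, path, digits = 7) {
  g <- raster$grid
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.6f", g$origin_x),
    sprintf("yllcorner %.6f", g$origin_y),
    sprintf("cellsize %.6f", g$cell_size),
    "NODATA_value -9999"
  )
  vals <- raster$values
  vals[is.na(vals)] <- -9999
  body <- apply(vals, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param name Layer name for the returned raster.
#' @export
read_ascii_grid <- function(path, name = "layer") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  h <- stats::setNames(vals, keys)
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  m[m == h[["nodata_value"]]] <- NA_real_
  grid <- grid_spec(
    n_rows = h[["nrows"]], n_cols = h[["ncols"]],
    cell_size = h[["cellsize"]],
    origin_x = h[["xllcorner"]], origin_y = h[["yllcorner"]]
  )
  new_raster(m, grid, name = name)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
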