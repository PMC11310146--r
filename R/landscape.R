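# Synthetic dune-lowland landscape: elevation built from anisotropic Gaussian
# ridges over a smooth lowland baseline, NDVI coupled to elevation with a
# period-dependent sign, and terrain covariates (slope, aspect, distance to
# water) derived from the elevation layer.

#' Default grid for the synthetic ranch
#'
#' 224 x 448 cells of 2 x 2 m (100,352 cells, about 20 ha), the scale at
#' which the foraging analysis operates.
#'
#' @return A [grid_spec()].
#' @export
default_grid <- function() grid_spec(n_rows = 224, n_cols = 448, cell_size = 2)

# Separable Gaussian smoothing with edge renormalisation.
smooth_field <- function(m, sigma_cells) {
  smooth1 <- function(mat) {
    # kernel must be shorter than the series it filters
    half <- max(1L, min(ceiling(3 * sigma_cells), (nrow(mat) - 1) %/% 2))
    w <- stats::dnorm(-half:half, sd = sigma_cells)
    w <- w / sum(w)
    out <- apply(mat, 2, function(col) stats::filter(col, w, sides = 2))
    norm <- apply(matrix(1, nrow(mat), ncol(mat)), 2,
                  function(col) stats::filter(col, w, sides = 2))
    out / norm
  }
  fill1 <- function(mat) {
    # filter() yields NA inside `half` cells of the edge; renormalised
    # convolution handles that except for all-NA stubs, so pad explicitly
    mat[is.na(mat)] <- mean(mat, na.rm = TRUE)
    mat
  }
  m1 <- fill1(smooth1(m))
  t(fill1(smooth1(t(m1))))
}

# One anisotropic Gaussian ridge evaluated over cell-centre coordinates.
ridge_field <- function(xg, yg, cx, cy, theta, length_m, width_m, height_m) {
  u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  v <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  sl <- length_m / 4
  sw <- width_m / 4
  height_m * exp(-0.5 * ((u / sl)^2 + (v / sw)^2))
}

#' Generate a synthetic dune-lowland landscape
#'
#' Builds an elevation surface as a gently undulating lowland baseline plus
#' elongated Gaussian dune ridges (400-600 m long, 20-40 m wide) until the
#' requested fraction of cells carries dune relief (> 2.5 m above baseline),
#' then derives slope, aspect and distance-to-water via
#' [derive_terrain_covariates()] and synthesises an NDVI layer whose coupling
#' to elevation depends on the grazing period: greenness concentrates in the
#' lowland early in the season (negative NDVI-elevation correlation) and
#' shifts weakly towards the dunes late in the season.
#'
#' @param grid A [grid_spec()]; defaults to [default_grid()].
#' @param dune_fraction Target fraction of cells with dune relief, in (0, 1).
#' @param dune_height_range Ridge crest heights in metres, within [0, 20].
#' @param water_point Length-2 numeric `c(x, y)` inside the extent.
#' @param period `"early"` (mid-July conditions) or `"late"` (early
#'   September).
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return A `gs_landscape`: rasters `elevation`, `slope`, `aspect`
#'   (1 = north-facing, 0 = south-facing), `dwp`, `ndvi` on one shared grid,
#'   plus `water_point` and `period`.
#' @examples
#' land <- generate_landscape(grid_spec(40, 80), seed = 1)
#' summary(as_tibble(land)$ndvi)
#' @export
generate_landscape <- function(grid = default_grid(),
                               dune_fraction = 0.6,
                               dune_height_range = c(5, 8),
                               water_point = NULL,
                               period = c("early", "late"),
                               seed = 1) {
  period <- match.arg(period)
  stopifnot(
    dune_fraction > 0, dune_fraction < 1,
    length(dune_height_range) == 2,
    all(dune_height_range >= 0), all(dune_height_range <= 20)
  )
  ext <- grid_extent(grid)
  if (is.null(water_point)) {
    water_point <- c(
      ext["xmin"] + 0.25 * (ext["xmax"] - ext["xmin"]),
      ext["ymin"] + 0.5 * (ext["ymax"] - ext["ymin"])
    )
  }
  water_point <- as.numeric(water_point)
  if (!in_extent(grid, water_point[1], water_point[2])) {
    stop("water_point lies outside the landscape extent", call. = FALSE)
  }

  with_substream(seed, paste0("landscape-", period), {
    idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
    ctr <- cell_center(grid, idx$row, idx$col)
    xg <- matrix(ctr$x, grid$n_rows, grid$n_cols)
    yg <- matrix(ctr$y, grid$n_rows, grid$n_cols)

    # lowland baseline: 100 m datum with ~0.5 m smooth undulation
    base_noise <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
    baseline <- 100 + 0.5 * smooth_field(base_noise, sigma_cells = 15)

    # stack ridges (pointwise max keeps crests inside the height range)
    relief <- matrix(0, grid$n_rows, grid$n_cols)
    dune_threshold <- 2.5
    max_ridges <- 400L
    n_ridges <- 0L
    while (mean(relief > dune_threshold) < dune_fraction && n_ridges < max_ridges) {
      n_ridges <- n_ridges + 1L
      cx <- stats::runif(1, ext["xmin"], ext["xmax"])
      cy <- stats::runif(1, ext["ymin"], ext["ymax"])
      theta <- stats::rnorm(1, mean = 0, sd = pi / 12) # ridges roughly E-W
      len <- stats::runif(1, 400, 600)
      wid <- stats::runif(1, 20, 40)
      hgt <- stats::runif(1, dune_height_range[1], dune_height_range[2])
      relief <- pmax(relief, ridge_field(xg, yg, cx, cy, theta, len, wid, hgt))
    }
    elevation <- new_raster(baseline + relief, grid, "elevation")

    terr <- derive_terrain_covariates(elevation, water_point)

    # NDVI: period-dependent elevation coupling plus smooth patchiness
    z <- elevation$values
    zs <- (z - mean(z)) / stats::sd(z)
    patch <- smooth_field(
      matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols),
      sigma_cells = 8
    )
    patch <- patch / stats::sd(patch)
    ndvi_vals <- if (period == "early") {
      0.42 - 0.08 * zs + 0.05 * patch
    } else {
      0.30 + 0.02 * zs + 0.05 * patch
    }
    ndvi_vals[ndvi_vals > 1] <- 1
    ndvi_vals[ndvi_vals < -1] <- -1
    ndvi <- new_raster(ndvi_vals, grid, "ndvi")

    structure(
      list(
        grid = grid,
        elevation = elevation, slope = terr$slope, aspect = terr$aspect,
        dwp = terr$dwp, ndvi = ndvi,
        water_point = c(x = water_point[1], y = water_point[2]),
        period = period
      ),
      class = "gs_landscape"
    )
  })
}

#' Derive slope, aspect and distance-to-water from an elevation raster
#'
#' Slope (degrees) is the arctangent of the central-difference gradient
#' magnitude; aspect is binary north/south facing (1 where the surface slopes
#' downhill towards the north, 0 otherwise); DWP is the Euclidean distance
#' from each cell centre to the water point.
#'
#' @param elevation A `gs_raster` of elevations in metres (at least 2 x 2).
#' @param water_point Length-2 numeric `c(x, y)` in metres.
#' @return A list of `gs_raster`s: `slope`, `aspect`, `dwp`.
#' @export
derive_terrain_covariates <- function(elevation, water_point) {
  g <- elevation$grid
  z <- elevation$values
  if (g$n_rows < 2 || g$n_cols < 2) {
    stop("elevation raster must be at least 2 x 2 to define gradients", call. = FALSE)
  }
  if (any(!is.finite(z))) stop("elevation must be finite", call. = FALSE)
  cs <- g$cell_size

  # d/dx (east), central differences with one-sided edges
  dzdx <- (z[, c(2:g$n_cols, g$n_cols)] - z[, c(1, 1:(g$n_cols - 1))]) /
    (cs * rep(c(1, rep(2, max(0, g$n_cols - 2)), 1), each = g$n_rows))
  # d/dy (north = decreasing row index)
  dzdy <- (z[c(1, 1:(g$n_rows - 1)), ] - z[c(2:g$n_rows, g$n_rows), ]) /
    (cs * rep(c(1, rep(2, max(0, g$n_rows - 2)), 1), times = g$n_cols))

  slope_deg <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  north_facing <- (dzdy < 0) * 1 # elevation drops towards north

  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  ctr <- cell_center(g, idx$row, idx$col)
  d <- sqrt((ctr$x - water_point[1])^2 + (ctr$y - water_point[2])^2)
  dwp <- matrix(d, g$n_rows, g$n_cols)

  list(
    slope = new_raster(slope_deg, g, "slope"),
    aspect = new_raster(north_facing, g, "aspect"),
    dwp = new_raster(dwp, g, "dwp")
  )
}

#' @export
print.gs_landscape <- function(x, ...) {
  cat(sprintf(
    "<gs_landscape> %s period, %d x %d cells @ %.3g m, water point (%.1f, %.1f)\n",
    x$period, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
    x$water_point["x"], x$water_point["y"]
  ))
  for (nm in c("elevation", "slope", "aspect", "dwp", "ndvi")) print(x[[nm]])
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.gs_landscape <- function(x, ...) {
  base <- as_tibble(x$elevation)
  slope <- as_tibble(x$slope)$value
  aspect <- as_tibble(x$aspect)$value
  dwp <- as_tibble(x$dwp)$value
  ndvi <- as_tibble(x$ndvi)$value
  tibble::tibble(
    row = base$row, col = base$col, x = base$x, y = base$y,
    elevation = base$value,
    slope = slope, aspect = aspect, dwp = dwp, ndvi = ndvi
  )
}

#' Write all landscape layers as ASCII grids
#'
#' @param landscape A `gs_landscape`.
#' @param dir Output directory (created if needed).
#' @return Tibble of layer names and file paths.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layers <- c("elevation", "slope", "aspect", "dwp", "ndvi")
  paths <- vapply(layers, function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(landscape[[nm]], p)
    p
  }, "")
  tibble::tibble(layer = layers, path = unname(paths))
}

#' @exportS3Method ggplot2::autoplot
autoplot.gs_landscape <- function(object, layer = "ndvi", ...) {
  df <- as_tibble(object[[layer]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::coord_equal() +
    ggplot2::annotate(
      "point",
      x = object$water_point["x"], y = object$water_point["y"],
      shape = 4, size = 3, colour = "white"
    ) +
    ggplot2::labs(
      x = "Easting (m)", y = "Northing (m)",
      title = sprintf("%s (%s grazing period)", layer, object$period)
    )
}

#' @importFrom rlang .data
NULL
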