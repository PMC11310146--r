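# Used-available design construction: uniform available sampling, covariate
# annotation from the landscape rasters, and pooled standardisation.

#' Sample available locations uniformly over the ranch
#'
#' Cells are sampled uniformly with replacement and each point is placed at
#' the sampled cell's centre.
#'
#' @param landscape A `gs_landscape`.
#' @param n Number of available points (>= 1).
#' @param seed Integer seed.
#' @return Tibble with `x_m`, `y_m`.
#' @export
sample_available <- function(landscape, n, seed = 1) {
  stopifnot(n >= 1)
  g <- landscape$grid
  with_substream(seed, "sampling", {
    cell <- sample.int(n_cells(g), n, replace = TRUE)
    # column-major unravel: cell = (col - 1) * n_rows + row
    row <- ((cell - 1) %% g$n_rows) + 1
    col <- ((cell - 1) %/% g$n_rows) + 1
    ctr <- cell_center(g, row, col)
    tibble::tibble(x_m = ctr$x, y_m = ctr$y)
  })
}

#' Sample used points from a known selection intensity
#'
#' Draws points (at cell centres, with replacement) with probability
#' proportional to `exp(eta)` where `eta` is the linear predictor of the
#' selection coefficients on cell covariates standardised over the whole
#' ranch. This is the selection intensity that the used-available logistic
#' estimator consistently recovers, so it is the generative model for
#' parameter-recovery and coverage experiments.
#'
#' @param landscape A `gs_landscape`.
#' @param beta Named coefficients on the ranch-standardised scale (see
#'   [true_params()]); the intercept only shifts all weights and does not
#'   affect the sample.
#' @param n Number of used points.
#' @param seed Integer seed.
#' @return Tibble with `x_m`, `y_m`.
#' @export
sample_used <- function(landscape, beta = true_params()$beta, n, seed = 1) {
  stopifnot(n >= 1)
  X <- landscape_covariate_matrix(landscape)
  eta <- drop(X %*% beta[colnames(X)])
  wts <- exp(eta - max(eta))
  g <- landscape$grid
  with_substream(seed, "used-sampling", {
    cell <- sample.int(n_cells(g), n, replace = TRUE, prob = wts)
    row <- ((cell - 1) %% g$n_rows) + 1
    col <- ((cell - 1) %/% g$n_rows) + 1
    ctr <- cell_center(g, row, col)
    tibble::tibble(x_m = ctr$x, y_m = ctr$y)
  })
}

#' Ranch-wide standardisation parameters
#'
#' Means and SDs of each covariate over all cells — the scale on which
#' ground-truth coefficients are defined. Pass the result to
#' [standardize_design()] to put a design on that scale instead of the
#' pooled used + available default.
#'
#' @param landscape A `gs_landscape`.
#' @return Tibble `covariate`, `mean`, `sd`.
#' @export
landscape_standardization <- function(landscape) {
  df <- as_tibble(landscape)
  purrr::map_dfr(c("elevation", "dwp", "slope", "ndvi"), function(v) {
    tibble::tibble(covariate = v, mean = mean(df[[v]]), sd = stats::sd(df[[v]]))
  })
}

#' Annotate points with landscape covariates
#'
#' Values are read from the cell containing each point (nearest-cell lookup,
#' no interpolation).
#'
#' @param points Tibble with `x_m`, `y_m` in metres.
#' @param landscape A `gs_landscape`.
#' @return The input tibble with `elevation`, `dwp`, `slope`, `aspect`,
#'   `ndvi` columns appended.
#' @export
annotate_points <- function(points, landscape) {
  outside <- !in_extent(landscape$grid, points$x_m, points$y_m)
  if (any(outside)) {
    stop(
      "points outside the landscape extent at indices: ",
      paste(utils::head(which(outside), 10), collapse = ", "),
      if (sum(outside) > 10) " ..." else "",
      call. = FALSE
    )
  }
  dplyr::mutate(
    tibble::as_tibble(points),
    elevation = raster_extract(landscape$elevation, .data$x_m, .data$y_m),
    dwp = raster_extract(landscape$dwp, .data$x_m, .data$y_m),
    slope = raster_extract(landscape$slope, .data$x_m, .data$y_m),
    aspect = raster_extract(landscape$aspect, .data$x_m, .data$y_m),
    ndvi = raster_extract(landscape$ndvi, .data$x_m, .data$y_m)
  )
}

#' Build a used-available design
#'
#' Stacks used (response 1) and available (response 0) points, annotates
#' both with landscape covariates, and optionally standardises.
#'
#' @param used Tibble of used points (`x_m`, `y_m`): fixes classified as
#'   foraging, at the native fix interval.
#' @param available Tibble of available points, e.g. from
#'   [sample_available()].
#' @param landscape A `gs_landscape`.
#' @param standardize Standardise covariates (default TRUE).
#' @param interactions List of length-2 character vectors naming main-effect
#'   pairs whose products are added as interaction columns.
#' @return A tibble (class `gs_design`) with `role` ("used"/"available"),
#'   coordinates, covariates and interaction columns; the standardisation
#'   table is stored in `attr(, "standardization")`.
#' @export
build_design <- function(used, available, landscape, standardize = TRUE,
                         interactions = list(
                           c("ndvi", "elevation"),
                           c("ndvi", "dwp"),
                           c("ndvi", "slope")
                         )) {
  u <- annotate_points(used[c("x_m", "y_m")], landscape)
  a <- annotate_points(available[c("x_m", "y_m")], landscape)
  design <- dplyr::bind_rows(
    dplyr::mutate(u, role = "used", .before = 1),
    dplyr::mutate(a, role = "available", .before = 1)
  )
  class(design) <- c("gs_design", class(design))
  attr(design, "interactions") <- interactions
  if (standardize) design <- standardize_design(design) else design
}

standardizable_covariates <- function(design) {
  intersect(c("elevation", "dwp", "slope", "ndvi"), names(design))
}

#' Standardise a used-available design
#'
#' Each continuous main covariate is centred and scaled by its pooled
#' (used + available) mean and SD; interaction columns are re-formed as
#' products of the standardised mains. The binary aspect covariate is left
#' unscaled. Standardisation parameters are stored on the result (and are
#' reused when `params` is supplied, e.g. to place prediction points on the
#' fitted scale).
#'
#' @param design A `gs_design` tibble.
#' @param params Optional standardisation tibble (`covariate`, `mean`, `sd`)
#'   from a previous call; default recomputes from `design`.
#' @return The design with standardised covariate columns, interaction
#'   columns named `<a>_x_<b>`, and `attr(, "standardization")` set.
#' @export
standardize_design <- function(design, params = NULL) {
  covs <- standardizable_covariates(design)
  if (is.null(params)) {
    params <- purrr::map_dfr(covs, function(v) {
      tibble::tibble(covariate = v, mean = mean(design[[v]]), sd = stats::sd(design[[v]]))
    })
    zero <- params$covariate[params$sd == 0 | !is.finite(params$sd)]
    if (length(zero) > 0) {
      stop(
        "zero-variance covariate(s): ", paste(zero, collapse = ", "),
        call. = FALSE
      )
    }
  }
  out <- design
  for (i in seq_len(nrow(params))) {
    v <- params$covariate[i]
    out[[v]] <- (design[[v]] - params$mean[i]) / params$sd[i]
  }
  interactions <- attr(design, "interactions")
  if (is.null(interactions)) {
    interactions <- list(c("ndvi", "elevation"), c("ndvi", "dwp"), c("ndvi", "slope"))
  }
  for (pair in interactions) {
    out[[paste(pair, collapse = "_x_")]] <- out[[pair[1]]] * out[[pair[2]]]
  }
  attr(out, "standardization") <- params
  attr(out, "interactions") <- interactions
  if (!inherits(out, "gs_design")) class(out) <- c("gs_design", class(out))
  out
}

#' @export
print.gs_design <- function(x, ...) {
  cat(sprintf(
    "<gs_design> %d used + %d available points%s\n",
    sum(x$role == "used"), sum(x$role == "available"),
    if (!is.null(attr(x, "standardization"))) ", standardized" else ""
  ))
  NextMethod()
}
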