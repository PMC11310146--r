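# Two-mode (foraging / non-foraging) correlated-random-walk simulator with
# habitat-weighted destination choice in the foraging mode. Provides the
# ground-truth tracks against which the classifier and the RSF are tested.

#' Ground-truth movement and selection parameters
#'
#' The selection coefficients act on covariates standardised over all ranch
#' cells, in the order (intercept, elevation, dwp, slope, ndvi,
#' ndvi x elevation, ndvi x dwp). Defaults are the early-season (July)
#' standardised-effect estimates for grazing cattle on a dune-lowland ranch.
#' Movement defaults give a slow, tortuous foraging gait (4 m per 50-s fix,
#' wide turns) against a fast, directed travelling gait (20 m, narrow
#' turns), with a mode chain whose stationary distribution is 80% foraging.
#'
#' @param beta Named numeric selection coefficients (standardised scale).
#' @param mode_transition 2x2 row-stochastic matrix, rows/cols
#'   (foraging, non-foraging).
#' @param forage_step_mean,travel_step_mean Mean step length per 50-s fix (m).
#' @param forage_turn_sd,travel_turn_sd SD of the wrapped-normal heading
#'   change (degrees).
#' @return A `gs_true_params` list.
#' @export
true_params <- function(beta = c(
                          intercept = -0.67, elevation = -0.20, dwp = -0.14,
                          slope = -0.06, ndvi = 0.22,
                          ndvi_x_elevation = 0.01, ndvi_x_dwp = 0.31
                        ),
                        mode_transition = matrix(
                          c(0.975, 0.025, 0.100, 0.900),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(
                            c("foraging", "non-foraging"),
                            c("foraging", "non-foraging")
                          )
                        ),
                        forage_step_mean = 4, travel_step_mean = 20,
                        forage_turn_sd = 70, travel_turn_sd = 15) {
  stopifnot(
    all(abs(rowSums(mode_transition) - 1) < 1e-12),
    all(mode_transition >= 0),
    forage_step_mean > 0, travel_step_mean > 0
  )
  structure(
    list(
      beta = beta, mode_transition = mode_transition,
      forage_step_mean = forage_step_mean, travel_step_mean = travel_step_mean,
      forage_turn_sd = forage_turn_sd, travel_turn_sd = travel_turn_sd
    ),
    class = "gs_true_params"
  )
}

# Standardised design columns for every cell, in true_params/beta order.
landscape_covariate_matrix <- function(landscape, standardize = TRUE) {
  df <- as_tibble(landscape)
  mains <- cbind(
    elevation = df$elevation, dwp = df$dwp,
    slope = df$slope, ndvi = df$ndvi
  )
  if (standardize) mains <- scale(mains)
  cbind(
    intercept = 1,
    mains,
    ndvi_x_elevation = mains[, "ndvi"] * mains[, "elevation"],
    ndvi_x_dwp = mains[, "ndvi"] * mains[, "dwp"]
  )
}

#' True selection-probability surface implied by ground-truth coefficients
#'
#' Evaluates the inverse-logit selection function over every cell, with
#' covariates standardised over the whole ranch.
#'
#' @param landscape A `gs_landscape`.
#' @param params A [true_params()].
#' @return A `gs_raster` of values in (0, 1).
#' @export
true_rsf_surface <- function(landscape, params) {
  X <- landscape_covariate_matrix(landscape)
  eta <- drop(X %*% params$beta[colnames(X)])
  w <- stats::plogis(eta)
  g <- landscape$grid
  new_raster(matrix(w, g$n_rows, g$n_cols), g, "true_rsf")
}

reflect_into <- function(v, lo, hi) {
  # mirror reflection into [lo, hi)
  width <- hi - lo
  v <- (v - lo) %% (2 * width)
  v <- ifelse(v > width, 2 * width - v, v)
  pmin(lo + v, hi - 1e-9)
}

#' Simulate a cattle GPS track
#'
#' A two-state Markov chain switches each 50-s fix between foraging and
#' non-foraging. At each step a set of candidate destinations is drawn from
#' the current mode's kernel (gamma step lengths with the mode's mean,
#' wrapped-normal heading changes); in foraging mode one candidate is
#' accepted with probability proportional to the true selection surface
#' `w(x)`, in non-foraging mode uniformly. The track reflects off the ranch
#' boundary, so no fix ever leaves the extent.
#'
#' @param landscape A `gs_landscape`.
#' @param params A [true_params()].
#' @param n_fixes Number of fixes (>= 2).
#' @param start Length-2 numeric start coordinate; default is the water
#'   point.
#' @param fix_interval Seconds between fixes (default 50).
#' @param n_candidates Candidate destinations per step (default 15).
#' @param seed Integer seed.
#' @return A tibble (class `gs_track`) with columns `t_s`, `x_m`, `y_m`,
#'   `mode`, and attribute `fix_interval`.
#' @export
simulate_track <- function(landscape, params = true_params(), n_fixes = 1000,
                           start = NULL, fix_interval = 50,
                           n_candidates = 15, seed = 1) {
  stopifnot(n_fixes >= 2)
  g <- landscape$grid
  ext <- grid_extent(g)
  half_extent <- min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"]) / 2
  if (params$forage_step_mean > half_extent || params$travel_step_mean > half_extent) {
    stop("step means exceed half the landscape extent; reduce them or enlarge the grid",
      call. = FALSE
    )
  }
  if (is.null(start)) start <- as.numeric(landscape$water_point)
  if (!in_extent(g, start[1], start[2])) {
    stop("start lies outside the landscape extent", call. = FALSE)
  }

  w_surface <- true_rsf_surface(landscape, params)
  wm <- w_surface$values
  cs <- g$cell_size

  lookup_w <- function(x, y) {
    col <- pmin(pmax(floor((x - g$origin_x) / cs) + 1, 1), g$n_cols)
    rfb <- pmin(pmax(floor((y - g$origin_y) / cs) + 1, 1), g$n_rows)
    wm[cbind(g$n_rows - rfb + 1, col)]
  }

  with_substream(seed, "track", {
    modes <- character(n_fixes)
    xs <- numeric(n_fixes)
    ys <- numeric(n_fixes)
    xs[1] <- start[1]
    ys[1] <- start[2]
    p_stat <- stationary_mode_distribution(params$mode_transition)
    modes[1] <- sample(c("foraging", "non-foraging"), 1, prob = p_stat)
    heading <- stats::runif(1, 0, 2 * pi)

    for (i in 2:n_fixes) {
      prev <- modes[i - 1]
      trans <- params$mode_transition[prev, ]
      modes[i] <- sample(colnames(params$mode_transition), 1, prob = trans)
      foraging <- modes[i] == "foraging"
      step_mean <- if (foraging) params$forage_step_mean else params$travel_step_mean
      turn_sd <- if (foraging) params$forage_turn_sd else params$travel_turn_sd

      turns <- stats::rnorm(n_candidates, 0, turn_sd * pi / 180)
      steps <- stats::rgamma(n_candidates, shape = 2, scale = step_mean / 2)
      hs <- heading + turns
      cx <- reflect_into(xs[i - 1] + steps * cos(hs), ext["xmin"], ext["xmax"])
      cy <- reflect_into(ys[i - 1] + steps * sin(hs), ext["ymin"], ext["ymax"])

      pick <- if (foraging) {
        wv <- lookup_w(cx, cy)
        sample.int(n_candidates, 1, prob = wv)
      } else {
        sample.int(n_candidates, 1)
      }
      xs[i] <- cx[pick]
      ys[i] <- cy[pick]
      dx <- xs[i] - xs[i - 1]
      dy <- ys[i] - ys[i - 1]
      if (dx != 0 || dy != 0) heading <- atan2(dy, dx)
    }

    out <- tibble::tibble(
      t_s = (seq_len(n_fixes) - 1) * fix_interval,
      x_m = xs, y_m = ys, mode = modes
    )
    attr(out, "fix_interval") <- fix_interval
    class(out) <- c("gs_track", class(out))
    out
  })
}

#' Stationary distribution of the two-state mode chain
#'
#' @param mode_transition 2x2 row-stochastic matrix.
#' @return Named probabilities over (foraging, non-foraging).
#' @export
stationary_mode_distribution <- function(mode_transition) {
  e <- eigen(t(mode_transition))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), colnames(mode_transition))
}

#' Write / read a track as CSV
#'
#' Columns `t_s,x_m,y_m[,mode]`.
#'
#' @param track A `gs_track` tibble.
#' @param path File path.
#' @return `path` invisibly; `read_track` returns a `gs_track`.
#' @export
write_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @param fix_interval Fix spacing in seconds for the returned track; if
#'   NULL, inferred from the median time difference.
#' @export
read_track <- function(path, fix_interval = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t_s", "x_m", "y_m") %in% names(df)))
  out <- tibble::as_tibble(df)
  if (is.null(fix_interval)) {
    fix_interval <- stats::median(diff(out$t_s))
  }
  attr(out, "fix_interval") <- fix_interval
  class(out) <- c("gs_track", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.gs_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_m, y = .data$y_m)) +
    ggplot2::geom_path(colour = "grey60", linewidth = 0.2) +
    { if ("mode" %in% names(object)) {
        ggplot2::geom_point(ggplot2::aes(colour = .data$mode), size = 0.4)
      } else {
        ggplot2::geom_point(size = 0.4, colour = "steelblue")
      } } +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}
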