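# End-to-end orchestration: simulate -> features -> classify -> design ->
# fit/select -> converge (optional) -> moderation -> predict -> validate,
# driven by a YAML config with one master seed split into named substreams.

#' Default pipeline configuration
#'
#' Mirrors the analysis' standard settings: 50-s fixes, 100-800 s feature
#' lags, 10 CV folds, 100,000 available locations, convergence sizes 100 to
#' 30,000, delta-AICc < 2 support rule, 20 probability intervals, 0.05-SD
#' moderation scan and bias-corrected bootstrap. Synthetic-landscape
#' defaults are a 224 x 448-cell 2-m grid with 60% dune cover of 5-8 m
#' relief. Scaled-down knobs (`n_fixes`, `convergence$reps`, `jn$n_boot`)
#' are exposed so desk runs finish quickly; raise them for full fidelity.
#'
#' @param seed Master seed.
#' @return Nested list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = list(
      n_rows = 224, n_cols = 448, cell_size = 2,
      dune_fraction = 0.6, dune_height = c(5, 8),
      period = "early",
      n_fixes = 5000
    ),
    lags = c(100, 200, 400, 800),
    classifier = list(n_folds = 10, num_trees = 500),
    n_available = 100000,
    terms = c(
      "elevation", "dwp", "slope", "ndvi",
      "ndvi_x_elevation", "ndvi_x_dwp"
    ),
    model_selection = list(enabled = TRUE),
    convergence = list(
      enabled = FALSE,
      sizes = c(100, 1000, 5000, 10000, 30000), reps = 200
    ),
    jn = list(
      alpha = 0.05, step = 0.05, n_boot = 2000,
      pairs = list(
        c(focal = "elevation", moderator = "ndvi"),
        c(focal = "dwp", moderator = "ndvi")
      )
    ),
    n_bins = 20
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values; the config is
#' validated before any stage runs.
#'
#' @param path YAML file with top-level keys matching [default_config()].
#' @return Validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  validate_config(config)
  config
}

validate_config <- function(config) {
  if (is.null(config$synthetic) &&
    (is.null(config$paths$landscape_dir) || is.null(config$paths$track))) {
    stop("config needs either a `synthetic` block or input paths for landscape and track",
      call. = FALSE
    )
  }
  if (!is.null(config$paths$landscape_dir) && is.null(config$synthetic)) {
    needed <- file.path(
      config$paths$landscape_dir,
      paste0(c("elevation", "slope", "aspect", "dwp", "ndvi"), ".asc")
    )
    missing <- needed[!file.exists(needed)]
    if (length(missing) > 0) {
      stop("missing landscape raster(s): ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    if (!file.exists(config$paths$track)) {
      stop("missing track file: ", config$paths$track, call. = FALSE)
    }
  }
  stopifnot(
    is.numeric(config$seed), length(config$seed) == 1,
    config$n_available >= 1, config$n_bins >= 1,
    all(config$lags > 0)
  )
  invisible(config)
}

#' Run the full foraging-distribution pipeline
#'
#' Executes every stage in order and writes all outputs plus a JSON
#' manifest (stage seeds, output paths, settings) under `out_dir`.
#' Rerunning with the same config reproduces identical outputs.
#'
#' @param config Config list from [default_config()] / [read_config()], or
#'   a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; all stage objects in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("grazescape_run_")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  manifest <- list(
    package_version = as.character(utils::packageVersion("grazescape")),
    seed = seed, stages = list(), outputs = list()
  )
  results <- list()
  say <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  # --- landscape ---
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    grid <- grid_spec(sy$n_rows, sy$n_cols, sy$cell_size)
    land <- generate_landscape(
      grid = grid, dune_fraction = sy$dune_fraction,
      dune_height_range = sy$dune_height, period = sy$period,
      seed = substream_seed(seed, "landscape")
    )
    say("simulate", sprintf("synthetic landscape (%s period)", sy$period))
    track <- simulate_track(
      land,
      params = true_params(), n_fixes = sy$n_fixes,
      seed = substream_seed(seed, "track")
    )
    say("simulate", sprintf("%d-fix track", nrow(track)))
    land_files <- write_landscape(land, file.path(out_dir, "landscape"))
    track_path <- file.path(out_dir, "track.csv")
    write_track(track, track_path)
    manifest$outputs$landscape <- land_files$path
    manifest$outputs$track <- track_path
  } else {
    dirp <- config$paths$landscape_dir
    layers <- lapply(
      stats::setNames(nm = c("elevation", "slope", "aspect", "dwp", "ndvi")),
      function(nm) read_ascii_grid(file.path(dirp, paste0(nm, ".asc")), name = nm)
    )
    land <- structure(
      c(list(grid = layers$elevation$grid), layers,
        list(
          water_point = unlist(config$paths$water_point),
          period = config$synthetic$period %||% "early"
        )
      ),
      class = "gs_landscape"
    )
    track <- read_track(config$paths$track)
    say("load", "landscape and track read from disk")
  }
  results$landscape <- land
  results$track <- track

  # --- features + classification ---
  features <- compute_features(track, lags = config$lags)
  say("features", sprintf("%d lags over %d fixes", length(config$lags), nrow(features)))
  if (!"mode" %in% names(track)) {
    stop("track has no behavior labels; supply a `mode` column or use the simulator",
      call. = FALSE
    )
  }
  classifier <- fit_behavior_classifier(
    features, track$mode,
    n_folds = config$classifier$n_folds,
    num_trees = config$classifier$num_trees,
    seed = substream_seed(seed, "classifier")
  )
  say("classify", sprintf("CV accuracy %.3f", classifier$cv$overall_accuracy))
  labels <- classify_track(classifier, features)
  results$features <- features
  results$classifier <- classifier
  results$labels <- labels

  # --- design + fit ---
  used <- track[which(labels$label == "foraging"), c("x_m", "y_m")]
  avail <- sample_available(land, config$n_available,
    seed = substream_seed(seed, "sampling")
  )
  design <- build_design(used, avail, land)
  fit <- fit_rsf(design, config$terms)
  say("fit", sprintf(
    "%d used vs %d available, AICc %.1f", fit$n_used, fit$n_available, fit$aicc
  ))
  results$design <- design
  results$fit <- fit
  fit_path <- file.path(out_dir, "rsf_fit.csv")
  utils::write.csv(tidy(fit), fit_path, row.names = FALSE)
  manifest$outputs$fit <- fit_path

  if (isTRUE(config$model_selection$enabled)) {
    models <- select_models(design, candidate_models())
    results$models <- models
    sel_path <- file.path(out_dir, "model_selection.csv")
    utils::write.csv(
      dplyr::select(tibble::as_tibble(models), -"terms"), sel_path,
      row.names = FALSE
    )
    manifest$outputs$model_selection <- sel_path
    say("select", sprintf("%d candidates, best: %s", nrow(models), models$model[1]))
  }

  # --- convergence study (optional, heavy) ---
  if (isTRUE(config$convergence$enabled)) {
    conv <- convergence_study(
      used, land,
      sizes = config$convergence$sizes,
      reps = config$convergence$reps,
      terms = config$terms,
      seed = substream_seed(seed, "convergence")
    )
    results$convergence <- conv
    conv_path <- file.path(out_dir, "convergence.csv")
    utils::write.csv(tibble::as_tibble(conv), conv_path, row.names = FALSE)
    manifest$outputs$convergence <- conv_path
    say("converge", sprintf("converged_at = %s", format(attr(conv, "converged_at"))))
  }

  # --- moderation ---
  jn_out <- purrr::map(config$jn$pairs, function(pair) {
    focal <- pair[["focal"]]
    moderator <- pair[["moderator"]]
    region <- jn_boundaries(fit, focal, moderator, alpha = config$jn$alpha)
    slopes <- simple_slope(fit, focal, moderator, m = c(-1, 0, 1))
    boot <- bc_bootstrap(
      design,
      statistic = function(d) {
        # rows are already on the fitted standardised scale
        f <- fit_rsf(d, config$terms)
        simple_slope(f, focal, moderator, m = 1)$estimate
      },
      n_boot = config$jn$n_boot,
      seed = substream_seed(seed, paste0("boot-", focal))
    )
    list(
      focal = focal, moderator = moderator,
      boundaries_sd = region$boundaries,
      boundaries_raw = region$boundaries_raw,
      slopes = slopes, bootstrap = boot
    )
  })
  results$jn <- jn_out
  jn_path <- file.path(out_dir, "jn_report.json")
  jsonlite::write_json(
    lapply(jn_out, function(r) {
      list(
        focal = r$focal, moderator = r$moderator,
        boundaries_sd = r$boundaries_sd, boundaries_raw = r$boundaries_raw,
        slopes = r$slopes,
        bootstrap = r$bootstrap[, c("estimate", "low", "high", "n_boot")]
      )
    }),
    jn_path,
    auto_unbox = TRUE, digits = NA
  )
  manifest$outputs$jn <- jn_path
  say("jn", sprintf("%d interactions analysed", length(jn_out)))

  # --- prediction + validation ---
  surface <- predict_surface(fit, land)
  intervals <- bin_surface(surface, config$n_bins)
  freq <- interval_frequencies(used, intervals)
  thresholds <- threshold_summary(freq)
  results$surface <- surface
  results$intervals <- intervals
  results$frequencies <- freq
  results$thresholds <- thresholds
  surf_path <- file.path(out_dir, "rsf_surface.asc")
  write_ascii_grid(surface, surf_path)
  int_path <- file.path(out_dir, "rsf_intervals.asc")
  write_ascii_grid(intervals, int_path, digits = 2)
  freq_path <- file.path(out_dir, "interval_frequencies.csv")
  utils::write.csv(tibble::as_tibble(freq), freq_path, row.names = FALSE)
  manifest$outputs$surface <- surf_path
  manifest$outputs$intervals <- int_path
  manifest$outputs$frequencies <- freq_path
  say("validate", sprintf(
    ">50%% RSF: %.1f%%, >75%% RSF: %.1f%%",
    thresholds$percentage[1], thresholds$percentage[2]
  ))

  manifest$stages <- list(
    landscape = substream_seed(seed, "landscape"),
    track = substream_seed(seed, "track"),
    classifier = substream_seed(seed, "classifier"),
    sampling = substream_seed(seed, "sampling")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
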