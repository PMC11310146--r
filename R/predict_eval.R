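# Projection of a fitted RSF over the landscape, 20-interval segmentation,
# and validation by the frequency distribution of observed foraging
# locations across the intervals.

#' Project a fitted RSF over the landscape
#'
#' Standardises every cell's covariates with the fit's stored
#' standardisation parameters and evaluates the selection function, giving
#' a per-cell relative probability of use.
#'
#' @param fit An `rsf_fit` with stored standardisation.
#' @param landscape A `gs_landscape` providing every covariate the fit's
#'   terms need.
#' @return A `gs_raster` of values in (0, 1) named `"rsf"`, carrying the
#'   landscape period as attribute `period`.
#' @export
predict_surface <- function(fit, landscape) {
  if (is.null(fit$standardization)) {
    stop("fit carries no standardisation parameters; refit from a standardised design",
      call. = FALSE
    )
  }
  df <- as_tibble(landscape)
  std <- fit$standardization
  for (i in seq_len(nrow(std))) {
    v <- std$covariate[i]
    if (!v %in% names(df)) {
      stop("landscape lacks covariate required by the fit: ", v, call. = FALSE)
    }
    df[[v]] <- (df[[v]] - std$mean[i]) / std$sd[i]
  }
  for (term in grep("_x_", fit$terms, value = TRUE)) {
    parents <- strsplit(term, "_x_")[[1]]
    if (!all(parents %in% names(df))) {
      stop("landscape lacks covariates for interaction term: ", term, call. = FALSE)
    }
    df[[term]] <- df[[parents[1]]] * df[[parents[2]]]
  }
  missing_terms <- setdiff(fit$terms, names(df))
  if (length(missing_terms) > 0) {
    stop(
      "landscape lacks covariates required by the fit: ",
      paste(missing_terms, collapse = ", "),
      call. = FALSE
    )
  }
  w <- rsf_value(df[fit$terms], fit)
  g <- landscape$grid
  out <- new_raster(matrix(w, g$n_rows, g$n_cols), g, "rsf")
  attr(out, "period") <- landscape$period
  out
}

interval_labels <- function(n_bins = 20) {
  edges <- seq(0, 100, length.out = n_bins + 1)
  sprintf("%g-%g%%", edges[-(n_bins + 1)], edges[-1])
}

#' Segment a probability surface into equal intervals
#'
#' Interval `b` covers `[(b-1)/n, b/n)` (the last interval is closed at 1),
#' so `bin = floor(w * n_bins) + 1` with `w = 1` mapped to the top bin.
#'
#' @param surface A `gs_raster` of probabilities from [predict_surface()].
#' @param n_bins Number of intervals (default 20, i.e. 5% steps).
#' @return A `gs_raster` of integer bin indices 1..n_bins.
#' @export
bin_surface <- function(surface, n_bins = 20) {
  stopifnot(n_bins >= 1)
  b <- pmin(floor(surface$values * n_bins) + 1, n_bins)
  out <- new_raster(b, surface$grid, "rsf_interval")
  attr(out, "n_bins") <- n_bins
  out
}

#' Build an interval-frequency table from per-interval counts
#'
#' Percentages are computed against the sum of the counts, which keeps
#' count and percentage columns internally consistent.
#'
#' @param counts Non-negative integer vector, one entry per interval, in
#'   increasing probability order.
#' @param n_bins Number of intervals (defaults to `length(counts)`).
#' @return A `gs_interval_table` tibble: `interval`, `count`,
#'   `percentage`; total count in `attr(, "total")`.
#' @export
interval_table <- function(counts, n_bins = length(counts)) {
  stopifnot(length(counts) == n_bins, all(counts >= 0))
  total <- sum(counts)
  out <- tibble::tibble(
    interval = interval_labels(n_bins),
    count = as.numeric(counts),
    percentage = if (total > 0) counts / total * 100 else rep(0, n_bins)
  )
  attr(out, "total") <- total
  attr(out, "n_bins") <- n_bins
  class(out) <- c("gs_interval_table", class(out))
  out
}

#' Tabulate observed locations across RSF intervals
#'
#' Assigns each observed (used) point the interval of its containing cell
#' and tabulates counts and percentages per interval — the validation table
#' for a predicted foraging-probability map.
#'
#' @param used_points Tibble with `x_m`, `y_m`, all inside the extent.
#' @param intervals Interval raster from [bin_surface()].
#' @return A `gs_interval_table` (see [interval_table()]).
#' @export
interval_frequencies <- function(used_points, intervals) {
  outside <- !in_extent(intervals$grid, used_points$x_m, used_points$y_m)
  if (any(outside)) {
    stop(
      "used points outside the extent at indices: ",
      paste(utils::head(which(outside), 10), collapse = ", "),
      call. = FALSE
    )
  }
  n_bins <- attr(intervals, "n_bins")
  if (is.null(n_bins)) n_bins <- max(intervals$values)
  b <- raster_extract(intervals, used_points$x_m, used_points$y_m)
  counts <- tabulate(b, nbins = n_bins)
  interval_table(counts, n_bins)
}

#' Share of locations above RSF thresholds
#'
#' Sums the counts of all intervals lying entirely above each threshold and
#' reports them as a percentage of all locations. Thresholds must fall on
#' interval edges.
#'
#' @param table A `gs_interval_table`.
#' @param thresholds Probabilities on bin edges (default 0.50 and 0.75).
#' @return Tibble `threshold`, `count`, `percentage`.
#' @export
threshold_summary <- function(table, thresholds = c(0.50, 0.75)) {
  n_bins <- attr(table, "n_bins")
  if (is.null(n_bins)) n_bins <- nrow(table)
  on_edge <- abs(thresholds * n_bins - round(thresholds * n_bins)) < 1e-9
  if (!all(on_edge)) {
    stop(
      "thresholds must be multiples of 1/", n_bins, ": ",
      paste(thresholds[!on_edge], collapse = ", "),
      call. = FALSE
    )
  }
  total <- sum(table$count)
  purrr::map_dfr(thresholds, function(th) {
    first_bin <- round(th * n_bins) + 1
    cnt <- if (first_bin > n_bins) 0 else sum(table$count[first_bin:n_bins])
    tibble::tibble(
      threshold = th, count = cnt,
      percentage = if (total > 0) cnt / total * 100 else 0
    )
  })
}

#' Published cattle-location counts per RSF interval
#'
#' Field counts of observed cattle GPS locations in twenty 5% RSF
#' intervals on a dune-lowland ranch, for the early (July) and late
#' (September) grazing periods, as published for the study system this
#' package models. Note: the early column was published with a total of
#' 10220, which is inconsistent with the column's sum (10488); the
#' published percentages follow the column sum, which is the denominator
#' this package uses throughout.
#'
#' @return Tibble `interval`, `count_early`, `count_late`.
#' @export
cattle_interval_counts <- function() {
  path <- system.file("extdata", "cattle_interval_counts.csv",
    package = "grazescape", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' @exportS3Method ggplot2::autoplot
autoplot.gs_interval_table <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    interval = factor(.data$interval, levels = .data$interval)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "RSF interval", y = "Locations (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
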