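# How many available points are enough? Refit the RSF with fresh available
# samples of increasing size and watch the coefficient simulation envelopes
# tighten.

#' Available-sample coefficient-convergence study
#'
#' For each available-sample size, draws `reps` independent available
#' samples, rebuilds and refits the full RSF against the same used points,
#' and summarises each monitored coefficient's replicate draws as a mean and
#' 95% simulation envelope (2.5th/97.5th percentiles, order statistics).
#' `converged_at` is the smallest size whose envelope width is within
#' `tolerance_ratio` of the largest size's width for every monitored
#' coefficient.
#'
#' @param used Tibble of used points (`x_m`, `y_m`).
#' @param landscape A `gs_landscape`.
#' @param sizes Strictly increasing available-sample sizes.
#' @param reps Replicates per size (>= 2); default 200.
#' @param terms Model terms passed to [fit_rsf()].
#' @param monitor Coefficients to track (default the four mains).
#' @param tolerance_ratio Envelope width at a size may exceed the
#'   largest-size width by at most this factor (default 1.15).
#' @param seed Integer seed.
#' @return A `gs_convergence`: summary tibble (`size`, `term`, `mean`,
#'   `lo`, `hi`, `width`, `n_ok`), all replicate draws in
#'   `attr(, "draws")`, and `converged_at`.
#' @export
convergence_study <- function(used, landscape,
                              sizes = c(100, 1000, 5000, 10000, 30000),
                              reps = 200,
                              terms = c(
                                "elevation", "dwp", "slope", "ndvi",
                                "ndvi_x_elevation", "ndvi_x_dwp"
                              ),
                              monitor = c("dwp", "elevation", "ndvi", "slope"),
                              tolerance_ratio = 1.15,
                              seed = 1) {
  stopifnot(reps >= 2, !is.unsorted(sizes, strictly = TRUE))
  draws <- purrr::map_dfr(seq_along(sizes), function(si) {
    n_avail <- sizes[si]
    purrr::map_dfr(seq_len(reps), function(r) {
      rep_seed <- substream_seed(seed, sprintf("conv-%d-%d", n_avail, r))
      avail <- sample_available(landscape, n_avail, seed = rep_seed)
      fit <- tryCatch(
        {
          design <- build_design(used, avail, landscape)
          fit_rsf(design, terms)
        },
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        return(tibble::tibble(
          size = n_avail, rep = r, term = monitor,
          beta = NA_real_
        ))
      }
      tibble::tibble(
        size = n_avail, rep = r, term = monitor,
        beta = unname(fit$beta[monitor])
      )
    })
  })

  fail_rate <- draws |>
    dplyr::group_by(.data$size, .data$rep) |>
    dplyr::summarise(failed = any(is.na(.data$beta)), .groups = "drop") |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(rate = mean(.data$failed), .groups = "drop")
  if (any(fail_rate$rate > 0.2)) {
    stop(
      "more than 20% of replicate fits failed at size(s): ",
      paste(fail_rate$size[fail_rate$rate > 0.2], collapse = ", "),
      call. = FALSE
    )
  }

  summary <- draws |>
    dplyr::filter(!is.na(.data$beta)) |>
    dplyr::group_by(.data$size, .data$term) |>
    dplyr::summarise(
      mean = mean(.data$beta),
      lo = stats::quantile(.data$beta, 0.025, names = FALSE, type = 1),
      hi = stats::quantile(.data$beta, 0.975, names = FALSE, type = 1),
      n_ok = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(width = .data$hi - .data$lo)

  widest <- summary |>
    dplyr::filter(.data$size == max(sizes)) |>
    dplyr::select("term", ref_width = "width")
  ok_sizes <- summary |>
    dplyr::left_join(widest, by = "term") |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      ok = all(.data$width <= tolerance_ratio * .data$ref_width),
      .groups = "drop"
    )
  converged_at <- suppressWarnings(min(ok_sizes$size[ok_sizes$ok]))
  if (!is.finite(converged_at)) converged_at <- NA_real_

  structure(
    summary,
    draws = draws,
    converged_at = converged_at,
    reps = reps,
    tolerance_ratio = tolerance_ratio,
    class = c("gs_convergence", class(summary))
  )
}

#' @export
print.gs_convergence <- function(x, ...) {
  ca <- attr(x, "converged_at")
  cat(sprintf(
    "<gs_convergence> %d reps per size; converged_at = %s\n",
    attr(x, "reps"), if (is.na(ca)) "none" else format(ca)
  ))
  NextMethod()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gs_convergence <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(
      x = "Available-sample size (log scale)",
      y = "Coefficient (standardised)",
      title = "Coefficient means and 95% simulation envelopes"
    )
}
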