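# Moderation analysis: simple slopes, closed-form Johnson-Neyman regions of
# significance, and the 0.05-SD scan for the last significant moderator
# value.

interaction_term <- function(fit, focal, moderator) {
  cand <- c(
    paste(focal, moderator, sep = "_x_"),
    paste(moderator, focal, sep = "_x_")
  )
  hit <- cand[cand %in% names(fit$beta)]
  if (length(hit) == 0) {
    stop(
      "fit has no ", focal, " x ", moderator, " interaction term",
      call. = FALSE
    )
  }
  hit[1]
}

slope_components <- function(fit, focal, moderator) {
  int <- interaction_term(fit, focal, moderator)
  list(
    b_f = unname(fit$beta[focal]),
    b_i = unname(fit$beta[int]),
    v_ff = fit$vcov[focal, focal],
    v_ii = fit$vcov[int, int],
    v_fi = fit$vcov[focal, int]
  )
}

#' Simple slope of a focal covariate at fixed moderator values
#'
#' In a model with a focal x moderator interaction, the conditional effect
#' of the focal covariate at moderator value `m` (standardised units) is
#' `beta_focal + m * beta_int`, with standard error
#' `sqrt(v_ff + m^2 v_ii + 2 m v_fi)`; significance uses the normal
#' reference.
#'
#' @param fit An `rsf_fit` containing both terms and their interaction.
#' @param focal,moderator Term names.
#' @param m Standardised moderator value(s).
#' @return Tibble with one row per `m`: `moderator_value`, `estimate`,
#'   `se`, `z`, `p`.
#' @export
simple_slope <- function(fit, focal, moderator, m = c(-1, 0, 1)) {
  cmp <- slope_components(fit, focal, moderator)
  est <- cmp$b_f + m * cmp$b_i
  se <- sqrt(cmp$v_ff + m^2 * cmp$v_ii + 2 * m * cmp$v_fi)
  z <- est / se
  tibble::tibble(
    moderator_value = m, estimate = est, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
}

#' Johnson-Neyman boundaries of a conditional effect
#'
#' Solves `(b_f + b_i m)^2 = z_crit^2 (v_ff + 2 m v_fi + m^2 v_ii)` as a
#' quadratic in the standardised moderator `m`: its real roots are the
#' moderator values at which the simple slope's p-value equals `alpha`. The
#' significance pattern of the intervals delimited by the roots is
#' established by probing |z| between and outside them. When the fit
#' carries standardisation parameters, boundaries are also reported on the
#' moderator's raw scale.
#'
#' @inheritParams simple_slope
#' @param alpha Significance level (default 0.05).
#' @return A `gs_jn_region`: `focal`, `moderator`, `alpha`, sorted
#'   `boundaries` (0, 1 or 2 values), `boundaries_raw` (if available), and
#'   a `pattern` tibble (`lo`, `hi`, `significant`) covering the real line.
#' @export
jn_boundaries <- function(fit, focal, moderator, alpha = 0.05) {
  cmp <- slope_components(fit, focal, moderator)
  zc2 <- stats::qnorm(1 - alpha / 2)^2
  A <- cmp$b_i^2 - zc2 * cmp$v_ii
  B <- 2 * (cmp$b_f * cmp$b_i - zc2 * cmp$v_fi)
  C <- cmp$b_f^2 - zc2 * cmp$v_ff

  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  roots <- roots[is.finite(roots)]

  # probe each interval delimited by the roots
  probes <- if (length(roots) == 0) {
    0
  } else {
    edges <- c(min(roots) - 1, roots, max(roots) + 1)
    (edges[-length(edges)] + edges[-1]) / 2
  }
  sig <- simple_slope(fit, focal, moderator, m = probes)$p < alpha
  lo <- c(-Inf, roots)
  hi <- c(roots, Inf)
  pattern <- tibble::tibble(lo = lo, hi = hi, significant = sig)

  boundaries_raw <- NULL
  std <- fit$standardization
  if (!is.null(std) && moderator %in% std$covariate) {
    i <- match(moderator, std$covariate)
    boundaries_raw <- std$mean[i] + std$sd[i] * roots
  }

  structure(
    list(
      focal = focal, moderator = moderator, alpha = alpha,
      boundaries = roots, boundaries_raw = boundaries_raw,
      pattern = pattern
    ),
    class = "gs_jn_region"
  )
}

#' @export
print.gs_jn_region <- function(x, ...) {
  cat(sprintf(
    "<gs_jn_region> effect of %s moderated by %s (alpha = %g)\n",
    x$focal, x$moderator, x$alpha
  ))
  if (length(x$boundaries) == 0) {
    cat(sprintf(
      "  no boundaries: slope %s everywhere\n",
      if (x$pattern$significant[1]) "significant" else "nonsignificant"
    ))
  } else {
    cat(
      "  boundaries (SD):", paste(sprintf("%.4f", x$boundaries), collapse = ", ")
    )
    if (!is.null(x$boundaries_raw)) {
      cat(
        "  | raw:", paste(sprintf("%.4f", x$boundaries_raw), collapse = ", ")
      )
    }
    cat("\n")
    print(x$pattern)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gs_jn_region <- function(x, ...) {
  x$pattern |>
    dplyr::mutate(focal = x$focal, moderator = x$moderator, alpha = x$alpha)
}

round_to_grid <- function(x, step) round(x / step) * step

#' Scan the moderator in 0.05-SD steps for the last significant value
#'
#' Starting from `start_sd` (snapped to the step grid), walks the
#' standardised moderator in `step`-SD increments in the given direction
#' until the simple slope of the focal covariate is significant at `alpha`,
#' and returns that moderator value (on the step grid). Returns `NA` if the
#' scan leaves [-5, 5] SD without reaching significance.
#'
#' @inheritParams simple_slope
#' @param start_sd Starting moderator value (standardised).
#' @param step Scan increment in SD units (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @param direction `"decreasing"` or `"increasing"`.
#' @return Length-1 numeric: the first significant moderator value on the
#'   grid, or `NA_real_`.
#' @export
jn_sd_scan <- function(fit, focal, moderator, start_sd, step = 0.05,
                       alpha = 0.05,
                       direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(start_sd))
  sgn <- if (direction == "decreasing") -1 else 1
  m <- round_to_grid(start_sd, step)
  while (m >= -5 && m <= 5) {
    if (simple_slope(fit, focal, moderator, m)$p < alpha) {
      return(round_to_grid(m, step))
    }
    m <- m + sgn * step
  }
  NA_real_
}

#' Simple-slope curve across the moderator range
#'
#' Convenience table for plotting the conditional effect with pointwise
#' normal confidence bands.
#'
#' @inheritParams simple_slope
#' @param range Standardised moderator range (default [-3, 3]).
#' @param n Grid points.
#' @param alpha Level for the confidence band.
#' @return Tibble `moderator_value`, `estimate`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
slope_curve <- function(fit, focal, moderator, range = c(-3, 3), n = 121,
                        alpha = 0.05) {
  m <- seq(range[1], range[2], length.out = n)
  zc <- stats::qnorm(1 - alpha / 2)
  simple_slope(fit, focal, moderator, m) |>
    dplyr::mutate(
      ci_low = .data$estimate - zc * .data$se,
      ci_high = .data$estimate + zc * .data$se,
      significant = .data$p < alpha
    )
}

#' Plot a Johnson-Neyman conditional-effect curve
#'
#' @param fit An `rsf_fit`.
#' @param focal,moderator Term names.
#' @param ... Passed to [slope_curve()].
#' @return A ggplot.
#' @export
plot_jn <- function(fit, focal, moderator, ...) {
  curve <- slope_curve(fit, focal, moderator, ...)
  region <- jn_boundaries(fit, focal, moderator)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$moderator_value, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("%s (standardised)", moderator),
      y = sprintf("Conditional effect of %s", focal)
    )
  if (length(region$boundaries) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = region$boundaries,
      linetype = 3, colour = "firebrick"
    )
  }
  p
}
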