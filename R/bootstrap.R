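# Bias-corrected (BC) percentile bootstrap for statistics of a
# used-available design (or any data frame).

#' Bias-corrected bootstrap confidence interval
#'
#' Case-resampling bootstrap with a median-bias correction: the correction
#' `z0` is the normal quantile of the fraction of bootstrap statistics
#' below the point estimate, and the interval endpoints are the bootstrap
#' order statistics at the BC-adjusted levels (quantile type 1 — no
#' interpolation). When a `role` column is present (used-available
#' designs), used and available rows are resampled independently so both
#' strata keep their sizes.
#'
#' @param data A data frame; rows are the resampling units.
#' @param statistic Function `data -> numeric scalar`.
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000, use
#'   50000 for full fidelity).
#' @param alpha Two-sided level (default 0.05 for a 95% interval).
#' @param seed Integer seed.
#' @return A `gs_boot_ci` tibble row: `estimate`, `low`, `high`, `n_boot`,
#'   `z0`, `method`, `seed`; bootstrap draws in `attr(, "draws")`.
#' @export
bc_bootstrap <- function(data, statistic, n_boot = 2000, alpha = 0.05,
                         seed = 1) {
  stopifnot(n_boot >= 100)
  theta_hat <- statistic(data)
  stopifnot(length(theta_hat) == 1, is.finite(theta_hat))

  strata <- if ("role" %in% names(data)) {
    split(seq_len(nrow(data)), data$role)
  } else {
    list(seq_len(nrow(data)))
  }

  with_substream(seed, "bootstrap", {
    draws <- numeric(n_boot)
    n_fail <- 0L
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE
      )
      val <- tryCatch(statistic(data[idx, , drop = FALSE]), error = function(e) NA_real_)
      if (!is.finite(val)) n_fail <- n_fail + 1L
      draws[b] <- val
    }
    if (n_fail > 0.01 * n_boot) {
      stop(
        "statistic failed on ", n_fail, " of ", n_boot,
        " resamples (> 1%); bootstrap aborted",
        call. = FALSE
      )
    }
    draws_ok <- draws[is.finite(draws)]
    nb <- length(draws_ok)

    if (max(draws_ok) - min(draws_ok) < .Machine$double.eps * 100) {
      low <- high <- theta_hat
      z0 <- 0
    } else {
      prop_below <- mean(draws_ok < theta_hat)
      # clamp away from 0/1 so z0 stays finite when theta_hat is extreme
      prop_below <- min(max(prop_below, 1 / (2 * nb)), 1 - 1 / (2 * nb))
      z0 <- stats::qnorm(prop_below)
      zl <- stats::qnorm(alpha / 2)
      zu <- stats::qnorm(1 - alpha / 2)
      a_low <- stats::pnorm(2 * z0 + zl)
      a_high <- stats::pnorm(2 * z0 + zu)
      sorted <- sort(draws_ok)
      pick <- function(p) sorted[min(max(ceiling(p * nb), 1L), nb)]
      low <- pick(a_low)
      high <- pick(a_high)
    }

    out <- tibble::tibble(
      estimate = theta_hat, low = low, high = high,
      n_boot = nb, z0 = z0, method = "bias-corrected percentile",
      seed = seed
    )
    attr(out, "draws") <- draws_ok
    class(out) <- c("gs_boot_ci", class(out))
    out
  })
}
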