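# Shared fixtures, built once per test run. Small grids keep the suite fast;
# the acceptance tests use the full-size default grid where the check
# demands it.

small_grid <- function() grid_spec(n_rows = 60, n_cols = 120, cell_size = 2)

# memoised small landscape (early period)
.fixture_env <- new.env(parent = emptyenv())

small_landscape <- function(period = "early", seed = 42) {
  key <- paste0("land-", period, "-", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_landscape(
      grid = small_grid(), period = period, seed = seed
    )
  }
  .fixture_env[[key]]
}

small_track <- function(n_fixes = 2000, seed = 7, params = true_params()) {
  key <- paste0("track-", n_fixes, "-", seed, "-", digest_params(params))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_track(
      small_landscape(), params, n_fixes = n_fixes, seed = seed
    )
  }
  .fixture_env[[key]]
}

digest_params <- function(params) {
  paste(signif(c(params$beta, params$forage_step_mean, params$travel_step_mean), 6),
    collapse = "|"
  )
}

# hand-built track tibble from coordinates at a 50-s interval
toy_track <- function(x, y, dt = 50) {
  tr <- tibble::tibble(t_s = (seq_along(x) - 1) * dt, x_m = x, y_m = y)
  attr(tr, "fix_interval") <- dt
  tr
}

# minimal rsf_fit stand-in for moderation algebra tests
fake_fit <- function(beta, vcov, standardization = NULL) {
  stopifnot(length(beta) == nrow(vcov))
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(
    list(
      beta = beta, vcov = vcov, loglik = NA_real_, aicc = NA_real_,
      n = NA_integer_, k = length(beta), converged = TRUE,
      terms = setdiff(names(beta), "intercept"),
      standardization = standardization
    ),
    class = "rsf_fit"
  )
}

# toy two-column used-available design (plain tibble works with fit_rsf)
toy_design <- function(z_used, z_available) {
  tibble::tibble(
    role = rep(c("used", "available"), c(length(z_used), length(z_available))),
    z = c(z_used, z_available)
  )
}
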