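# Moderation algebra checked against closed forms and a dense grid-scan
# oracle, on hand-built coefficient/covariance fits.

worked_fit <- function() {
  # focal f, moderator m with known components
  fake_fit(
    beta = c(intercept = 0, f = 0.2, m = 0.1, f_x_m = 0.5),
    vcov = diag(c(0.01, 0.04, 0.02, 0.01))
  )
}

# oracle: scan |z(m)| >= z_crit on a dense grid and report sign-change points
grid_scan_roots <- function(fit, focal, moderator, alpha = 0.05,
                            lo = -5, hi = 5, step = 1e-4) {
  m <- seq(lo, hi, by = step)
  sig <- simple_slope(fit, focal, moderator, m)$p < alpha
  flips <- which(diff(sig) != 0)
  (m[flips] + m[flips + 1]) / 2
}

test_that("simple slopes reduce to their closed forms", {
  fit <- worked_fit()
  s0 <- simple_slope(fit, "f", "m", 0)
  expect_equal(s0$estimate, 0.2)
  expect_equal(s0$se, sqrt(0.04))
  expect_equal(s0$z, s0$estimate / s0$se, tolerance = 1e-10)

  # early-season field estimates: DWP effect at +1 SD NDVI
  field <- fake_fit(
    beta = c(intercept = -0.67, dwp = -0.14, ndvi = 0.22, ndvi_x_dwp = 0.31),
    vcov = diag(c(0.01, 0.002, 0.002, 0.002))
  )
  s1 <- simple_slope(field, "dwp", "ndvi", 1)
  expect_equal(s1$estimate, 0.17)

  # diagonal vcov at m = 2
  s2 <- simple_slope(fit, "f", "m", 2)
  expect_equal(s2$se, sqrt(0.04 + 4 * 0.01))
})

test_that("analytic JN boundaries match the dense grid scan", {
  fit <- worked_fit()
  region <- jn_boundaries(fit, "f", "m")
  expect_equal(region$boundaries, c(-1.3448, 0.3995), tolerance = 1e-3)
  oracle <- grid_scan_roots(fit, "f", "m")
  expect_equal(length(region$boundaries), length(oracle))
  expect_lt(max(abs(region$boundaries - oracle)), 1e-3)
  # significant outside the roots, not between them
  expect_equal(region$pattern$significant, c(TRUE, FALSE, TRUE))
})

test_that("the slope's p-value at a JN boundary equals alpha", {
  fit <- worked_fit()
  region <- jn_boundaries(fit, "f", "m", alpha = 0.05)
  for (root in region$boundaries) {
    expect_equal(simple_slope(fit, "f", "m", root)$p, 0.05, tolerance = 1e-6)
  }
})

test_that("boundaries are invariant to a common rescaling of beta and vcov^1/2", {
  fit <- worked_fit()
  c0 <- 3.7
  scaled <- fake_fit(fit$beta * c0, fit$vcov * c0^2)
  expect_equal(
    jn_boundaries(scaled, "f", "m")$boundaries,
    jn_boundaries(fit, "f", "m")$boundaries,
    tolerance = 1e-10
  )
})

test_that("degenerate interaction variance falls back to the main effect", {
  # no interaction uncertainty and b_i = 0: significance set by the main z
  sig_main <- fake_fit(
    beta = c(intercept = 0, f = 1, m = 0, f_x_m = 0),
    vcov = matrix(c(
      0.01, 0, 0, 0,
      0, 0.01, 0, 0,
      0, 0, 0.01, 0,
      0, 0, 0, 0
    ), 4, byrow = TRUE)
  )
  region <- jn_boundaries(sig_main, "f", "m")
  expect_equal(length(region$boundaries), 0)
  expect_true(all(region$pattern$significant))

  ns_main <- fake_fit(
    beta = c(intercept = 0, f = 0.01, m = 0, f_x_m = 0),
    vcov = sig_main$vcov
  )
  region <- jn_boundaries(ns_main, "f", "m")
  expect_equal(length(region$boundaries), 0)
  expect_false(any(region$pattern$significant))
})

test_that("raw-scale boundaries use the stored standardisation", {
  std <- tibble::tibble(covariate = "m", mean = 0.35, sd = 0.1)
  fit <- fake_fit(
    beta = c(intercept = 0, f = 0.2, m = 0.1, f_x_m = 0.5),
    vcov = diag(c(0.01, 0.04, 0.02, 0.01)),
    standardization = std
  )
  region <- jn_boundaries(fit, "f", "m")
  expect_equal(region$boundaries_raw, 0.35 + 0.1 * region$boundaries)
})

test_that("the 0.05-SD scan lands on the grid and matches the boundaries", {
  fit <- worked_fit()
  # start just inside the nonsignificant band, walking up: first grid value
  # past the upper root 0.3995 is 0.40
  expect_equal(jn_sd_scan(fit, "f", "m", start_sd = 0.35, direction = "increasing"), 0.40)
  # already-significant start is returned unchanged
  expect_equal(jn_sd_scan(fit, "f", "m", start_sd = 2, direction = "increasing"), 2)
  # scan outputs always sit on the 0.05 grid
  for (s in c(-1.62, 0.07, 1.111)) {
    out <- jn_sd_scan(fit, "f", "m", start_sd = s, direction = "decreasing")
    if (!is.na(out)) expect_lt(abs(out / 0.05 - round(out / 0.05)), 1e-9)
  }
  # an everywhere-nonsignificant fit returns NA
  flat <- fake_fit(
    beta = c(intercept = 0, f = 0.001, m = 0, f_x_m = 0.0001),
    vcov = diag(c(0.01, 1, 1, 1))
  )
  expect_true(is.na(jn_sd_scan(flat, "f", "m", 0, direction = "increasing")))
})

test_that("a missing interaction term is a specification error", {
  fit <- fake_fit(
    beta = c(intercept = 0, f = 0.2, m = 0.1),
    vcov = diag(3) * 0.01
  )
  expect_error(simple_slope(fit, "f", "m", 0), "interaction")
})

test_that("randomised instances: analytic roots equal the grid scan", {
  set.seed(1234)
  n_checked <- 0
  for (i in 1:25) {
    b_f <- runif(1, -0.5, 0.5)
    b_i <- runif(1, -0.6, 0.6)
    A <- matrix(runif(4, -0.05, 0.05), 2)
    V <- crossprod(A) + diag(2) * 1e-4
    fit <- fake_fit(
      beta = c(intercept = 0, f = b_f, m = 0, f_x_m = b_i),
      vcov = rbind(
        c(1e-4, 0, 0, 0),
        c(0, V[1, 1], 0, V[1, 2]),
        c(0, 0, 1e-4, 0),
        c(0, V[2, 1], 0, V[2, 2])
      )
    )
    region <- jn_boundaries(fit, "f", "m")
    oracle <- grid_scan_roots(fit, "f", "m")
    roots_in_window <- region$boundaries[abs(region$boundaries) < 5]
    expect_equal(length(roots_in_window), length(oracle))
    if (length(oracle) > 0) {
      expect_lt(max(abs(sort(roots_in_window) - sort(oracle))), 1e-3)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5) # the draw ranges must actually exercise roots
})
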