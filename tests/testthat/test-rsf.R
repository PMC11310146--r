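test_that("intercept-only fit equals the used:available log-ratio", {
  d <- toy_design(rnorm(40), rnorm(80))
  fit <- fit_rsf(d, terms = character(0))
  expect_equal(unname(fit$beta["intercept"]), log(40 / 80), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS matches a brute-force likelihood grid search on a toy design", {
  set.seed(42)
  z_used <- rnorm(10, mean = 0.8)
  z_avail <- rnorm(10, mean = -0.2)
  d <- toy_design(z_used, z_avail)
  fit <- fit_rsf(d, terms = "z")

  # independent oracle: dense two-stage grid over (b0, b1)
  y <- as.numeric(d$role == "used")
  z <- d$z
  ll <- function(b0, b1) {
    eta <- b0 + b1 * z
    sum(y * eta - log1p(exp(eta)))
  }
  grid_best <- function(b0s, b1s) {
    best <- c(NA, NA, -Inf)
    for (b0 in b0s) {
      for (b1 in b1s) {
        v <- ll(b0, b1)
        if (v > best[3]) best <- c(b0, b1, v)
      }
    }
    best
  }
  coarse <- grid_best(seq(-3, 3, by = 0.02), seq(-3, 3, by = 0.02))
  fine <- grid_best(
    seq(coarse[1] - 0.04, coarse[1] + 0.04, by = 5e-4),
    seq(coarse[2] - 0.04, coarse[2] + 0.04, by = 5e-4)
  )
  expect_lt(abs(unname(fit$beta["intercept"]) - fine[1]), 1e-3)
  expect_lt(abs(unname(fit$beta["z"]) - fine[2]), 1e-3)
  expect_gte(fit$loglik, fine[3] - 1e-9)
})

test_that("IRLS agrees with the reference GLM fitter", {
  set.seed(7)
  n <- 300
  d <- tibble::tibble(
    role = rep(c("used", "available"), c(100, 200)),
    a = rnorm(n), b = rnorm(n)
  )
  d$a_x_b <- d$a * d$b
  fit <- fit_rsf(d, terms = c("a", "b", "a_x_b"))
  ref <- glm(I(role == "used") ~ a + b + a_x_b, family = binomial(), data = d)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov))),
    unname(sqrt(diag(vcov(ref)))),
    tolerance = 1e-4
  )
})

test_that("the log-likelihood trace never decreases", {
  set.seed(3)
  d <- toy_design(rnorm(200, 1), rnorm(400, 0))
  fit <- fit_rsf(d, terms = "z")
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
  # vcov symmetric and AICc self-consistent
  expect_lt(max(abs(fit$vcov - t(fit$vcov))), 1e-10)
  expect_equal(fit$aicc, aicc(fit$loglik, fit$k, fit$n), tolerance = 1e-10)
})

test_that("perfect separation raises an error instead of runaway coefficients", {
  d <- toy_design(seq(2, 3, length.out = 20), seq(-3, -2, length.out = 20))
  expect_error(fit_rsf(d, terms = "z"), "separation")
})

test_that("a duplicated covariate is reported as rank deficiency", {
  set.seed(8)
  d <- toy_design(rnorm(30), rnorm(30))
  d$z2 <- d$z
  expect_error(fit_rsf(d, terms = c("z", "z2")), "singular|rank")
})

test_that("rsf_value implements a numerically stable inverse logit", {
  fit <- fake_fit(
    beta = c(intercept = 0, z = 1),
    vcov = diag(c(0.1, 0.1))
  )
  expect_equal(rsf_value(c(z = 0), fit), 0.5)
  expect_equal(rsf_value(c(z = log(3)), fit), 0.75)
  lo <- rsf_value(c(z = -50), fit)
  expect_gt(lo, 0)
  expect_lte(lo, 1e-20)
  hi <- rsf_value(c(z = 700), fit)
  expect_true(is.finite(hi) && hi <= 1)
  # monotone in a positively weighted covariate
  vals <- rsf_value(data.frame(z = seq(-5, 5, by = 0.5)), fit)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  expect_equal(aicc(-100, 0, 50), 200)
  # approaches plain AIC for huge n
  expect_lt(abs(aicc(-100, 3, 1e9) - (206)), 1e-6)
  expect_error(aicc(-100, 10, 11), "n > k \\+ 1")
})

test_that("standardisation centres, scales, and is idempotent in effect", {
  land <- small_landscape()
  u <- sample_used(land, n = 300, seed = 1)
  a <- sample_available(land, 600, seed = 2)
  d <- build_design(u, a, land)
  std <- attr(d, "standardization")
  for (v in std$covariate) {
    expect_lt(abs(mean(d[[v]])), 1e-10)
    expect_lt(abs(sd(d[[v]]) - 1), 1e-10)
  }
  # interactions are exact products of standardised mains
  expect_lt(max(abs(d$ndvi_x_dwp - d$ndvi * d$dwp)), 1e-12)
  # re-applying the stored parameters to the raw design changes nothing
  raw <- build_design(u, a, land, standardize = FALSE)
  d2 <- standardize_design(raw, params = std)
  expect_equal(d2$elevation, d$elevation, tolerance = 1e-12)

  # zero-variance covariate is named in the error
  raw_bad <- raw
  raw_bad$slope <- 1
  expect_error(standardize_design(raw_bad), "slope")
})

test_that("standardised and raw fits describe the same model", {
  land <- small_landscape()
  u <- sample_used(land, n = 400, seed = 5)
  a <- sample_available(land, 800, seed = 6)
  d_std <- build_design(u, a, land)
  d_raw <- build_design(u, a, land, standardize = FALSE)
  d_raw$ndvi_x_elevation <- d_raw$ndvi * d_raw$elevation
  d_raw$ndvi_x_dwp <- d_raw$ndvi * d_raw$dwp
  terms <- c("elevation", "dwp", "slope", "ndvi")
  f_std <- fit_rsf(d_std, terms)
  f_raw <- fit_rsf(d_raw, terms)
  # identical fitted probabilities on 100 points despite different scales
  idx <- as.integer(seq(1, nrow(d_std), length.out = 100))
  p_std <- rsf_value(d_std[idx, terms], f_std)
  p_raw <- rsf_value(d_raw[idx, terms], f_raw)
  expect_equal(p_std, p_raw, tolerance = 1e-8)
})
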