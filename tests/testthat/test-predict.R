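# Probability surfaces, interval segmentation and the observed-frequency
# validation table.

surface_fixture <- function() {
  if (is.null(.fixture_env$surf)) {
    land <- small_landscape()
    u <- sample_used(land, n = 1000, seed = 51)
    a <- sample_available(land, 2000, seed = 52)
    d <- build_design(u, a, land)
    fit <- fit_rsf(d)
    .fixture_env$surf <- list(land = land, used = u, fit = fit,
                              surface = predict_surface(fit, land))
  }
  .fixture_env$surf
}

test_that("a null model predicts a flat 0.5 surface", {
  land <- small_landscape()
  fit <- fake_fit(
    beta = c(intercept = 0, elevation = 0, dwp = 0, slope = 0, ndvi = 0),
    vcov = diag(5) * 0.01,
    standardization = landscape_standardization(land)
  )
  s <- predict_surface(fit, land)
  expect_equal(max(abs(s$values - 0.5)), 0)
})

test_that("the surface agrees with pointwise rsf_value at cell centres", {
  fx <- surface_fixture()
  df <- as_tibble(fx$land)
  idx <- seq(1, nrow(df), length.out = 50)
  pts <- tibble::tibble(x_m = df$x[idx], y_m = df$y[idx])
  ann <- annotate_points(pts, fx$land)
  std_ann <- standardize_design(
    structure(dplyr::mutate(ann, role = "used"), class = c("gs_design", class(ann))),
    params = fx$fit$standardization
  )
  expect_equal(
    raster_extract(fx$surface, pts$x_m, pts$y_m),
    unname(rsf_value(std_ann[fx$fit$terms], fx$fit)),
    tolerance = 1e-12
  )
  expect_true(all(fx$surface$values > 0 & fx$surface$values < 1))
})

test_that("with a single positive NDVI effect the surface sorts like NDVI", {
  land <- small_landscape()
  fit <- fake_fit(
    beta = c(intercept = 0, ndvi = 0.8),
    vcov = diag(2) * 0.01,
    standardization = landscape_standardization(land)
  )
  s <- predict_surface(fit, land)
  o <- order(as.vector(land$ndvi$values))
  expect_true(!is.unsorted(as.vector(s$values)[o]))
})

test_that("interval binning follows the half-open convention with a closed top", {
  g <- grid_spec(1, 5, cell_size = 1)
  s <- new_raster(matrix(c(0, 0.05, 0.999, 1, 0.049999), 1, 5), g)
  b <- bin_surface(s, 20)
  expect_equal(as.vector(b$values), c(1, 2, 20, 20, 1))
  # partition: every cell lands in exactly one bin
  fx <- surface_fixture()
  bins <- bin_surface(fx$surface)
  expect_true(all(bins$values >= 1 & bins$values <= 20))
  expect_equal(length(bins$values), n_cells(fx$land$grid))
})

test_that("frequency tables match the published interval arithmetic", {
  counts <- cattle_interval_counts()
  early <- interval_table(counts$count_early)
  expect_equal(attr(early, "total"), 10488)
  expect_equal(early$percentage[early$interval == "95-100%"], 43.030, tolerance = 5e-4)
  expect_equal(sum(early$percentage), 100, tolerance = 0.01)

  late <- interval_table(counts$count_late)
  expect_equal(attr(late, "total"), 10414)
  expect_equal(late$percentage[late$interval == "95-100%"], 17.33, tolerance = 5e-3)

  # late-period share above the 75% threshold, from the printed counts
  th <- threshold_summary(late, 0.75)
  expect_equal(th$count, 691 + 794 + 774 + 894 + 1805)
  expect_equal(th$percentage, 47.6, tolerance = 0.05)
})

test_that("observed points are tabulated into their cells' intervals", {
  fx <- surface_fixture()
  bins <- bin_surface(fx$surface)
  tab <- interval_frequencies(fx$used, bins)
  expect_equal(sum(tab$count), nrow(fx$used))
  expect_equal(sum(tab$percentage), 100, tolerance = 0.01)
  # all points forced into one bin
  one_cell <- fx$used[rep(1, 7), ]
  tab1 <- interval_frequencies(one_cell, bins)
  expect_equal(sum(tab1$count > 0), 1)
  expect_equal(max(tab1$percentage), 100)
  # outside points rejected with indices
  bad <- tibble::tibble(x_m = -1e5, y_m = 0)
  expect_error(interval_frequencies(bad, bins), "outside the extent")
})

test_that("threshold summaries respect bin edges", {
  tab <- interval_table(rep(5, 20))
  expect_equal(threshold_summary(tab, 0)$percentage, 100)
  expect_equal(threshold_summary(tab, 0.5)$percentage, 50)
  expect_error(threshold_summary(tab, 0.33), "multiples")
  single <- interval_table(c(rep(0, 19), 11))
  expect_equal(threshold_summary(single, 0.5)$percentage, 100)
})

test_that("points sampled from a known surface calibrate across bins", {
  fx <- surface_fixture()
  land <- fx$land
  # draw points with weight equal to the surface itself, then the expected
  # per-cell density rises with the bin index
  w <- as.vector(land$ndvi$values) # any smooth positive field works
  w <- (w - min(w) + 0.01)
  g <- land$grid
  set.seed(77)
  cell <- sample.int(n_cells(g), 50000, replace = TRUE, prob = w)
  # column-major linear index back to row/col
  row <- ((cell - 1) %% g$n_rows) + 1
  col <- ((cell - 1) %/% g$n_rows) + 1
  ctr <- cell_center(g, row, col)
  pts <- tibble::tibble(x_m = ctr$x, y_m = ctr$y)
  wr <- new_raster(matrix(w / max(w) * 0.999, g$n_rows, g$n_cols), g)
  bins <- bin_surface(wr, 20)
  tab <- interval_frequencies(pts, bins)
  cells_per_bin <- tabulate(bins$values, 20)
  density <- ifelse(cells_per_bin > 0, tab$count / cells_per_bin, NA)
  ok <- !is.na(density)
  expect_gt(cor(seq_len(20)[ok], density[ok], method = "spearman"), 0.9)
})
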