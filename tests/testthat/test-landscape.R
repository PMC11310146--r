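test_that("generated landscapes satisfy their type invariants", {
  for (period in c("early", "late")) {
    land <- small_landscape(period)
    df <- as_tibble(land)
    expect_true(all(df$ndvi >= -1 & df$ndvi <= 1))
    expect_true(all(df$slope >= 0 & df$slope <= 90))
    expect_true(all(df$dwp >= 0))
    expect_true(all(df$aspect %in% c(0, 1)))
    expect_true(all(is.finite(df$elevation)))
    # dwp at the cell containing the water point is below one cell diagonal
    wp <- land$water_point
    expect_lt(
      raster_extract(land$dwp, wp["x"], wp["y"]),
      sqrt(2) * land$grid$cell_size
    )
  }
})

test_that("dune cover hits the requested fraction at 5-8 m relief", {
  land <- small_landscape()
  relief <- as_tibble(land)$elevation - 100 # baseline datum is 100 m
  covered <- mean(relief > 2.5)
  expect_gt(covered, 0.5)
  expect_lt(covered, 0.7)
  # crests stay within the requested height band (plus baseline undulation)
  expect_lt(max(relief), 8 + 1.5)
})

test_that("NDVI-elevation coupling flips sign between grazing periods", {
  early <- as_tibble(small_landscape("early"))
  late <- as_tibble(small_landscape("late"))
  expect_lt(cor(early$ndvi, early$elevation), 0)
  expect_gt(cor(late$ndvi, late$elevation), 0)
  # early season is greener overall
  expect_gt(mean(early$ndvi), mean(late$ndvi))
})

test_that("identical seeds reproduce the landscape exactly", {
  a <- generate_landscape(grid_spec(20, 30), seed = 9)
  b <- generate_landscape(grid_spec(20, 30), seed = 9)
  expect_identical(a, b)
  c <- generate_landscape(grid_spec(20, 30), seed = 10)
  expect_false(identical(a$elevation$values, c$elevation$values))
})

test_that("terrain derivation matches closed-form cases", {
  g <- grid_spec(5, 5, cell_size = 2)
  # flat surface: zero slope everywhere, dwp by plain geometry
  flat <- new_raster(matrix(7, 5, 5), g)
  terr <- derive_terrain_covariates(flat, water_point = c(5, 5))
  expect_equal(max(abs(terr$slope$values)), 0)
  ctr <- cell_center(g, 1, 1)
  expect_equal(
    raster_extract(terr$dwp, ctr$x, ctr$y),
    sqrt((ctr$x - 5)^2 + (ctr$y - 5)^2)
  )

  # plane rising 2 m per 2-m cell eastward: 45 degrees on interior cells
  plane <- new_raster(
    matrix(rep(seq(0, 8, by = 2), each = 5), 5, 5), g
  )
  terr <- derive_terrain_covariates(plane, water_point = c(5, 5))
  expect_equal(terr$slope$values[, 2:4], matrix(45, 5, 3))

  # 3-4-5 triangle distance
  gq <- grid_spec(10, 10, cell_size = 2)
  elev <- new_raster(matrix(0, 10, 10), gq)
  terr <- derive_terrain_covariates(elev, water_point = c(3, 3))
  expect_equal(raster_extract(terr$dwp, 3 + 6, 3 + 8), 10)
})

test_that("aspect separates north- from south-facing slopes", {
  g <- grid_spec(6, 4, cell_size = 2)
  # elevation increasing northwards (row 1 highest): surface drops to south
  south_tilt <- new_raster(matrix(rev(seq_len(6)), 6, 4), g)
  terr <- derive_terrain_covariates(south_tilt, water_point = c(1, 1))
  expect_true(all(terr$aspect$values[2:5, ] == 0))
  north_tilt <- new_raster(matrix(seq_len(6), 6, 4), g)
  terr <- derive_terrain_covariates(north_tilt, water_point = c(1, 1))
  expect_true(all(terr$aspect$values[2:5, ] == 1))
})

test_that("degenerate inputs are rejected", {
  g1 <- grid_spec(1, 1, cell_size = 2)
  expect_error(
    derive_terrain_covariates(new_raster(matrix(1), g1), c(1, 1)),
    "at least 2 x 2"
  )
  expect_error(
    generate_landscape(grid_spec(20, 20), water_point = c(1e6, 1e6)),
    "outside the landscape extent"
  )
})

test_that("landscape layers survive an ASCII-grid round trip", {
  land <- small_landscape()
  dir <- withr::local_tempdir()
  files <- write_landscape(land, dir)
  expect_equal(nrow(files), 5)
  ndvi <- read_ascii_grid(file.path(dir, "ndvi.asc"), "ndvi")
  expect_equal(ndvi$values, land$ndvi$values, tolerance = 1e-5)
  expect_equal(ndvi$grid$cell_size, land$grid$cell_size)
})
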