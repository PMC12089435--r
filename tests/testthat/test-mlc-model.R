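test_that("pair boundaries are the prefix sums of the leaf widths", {
  pb <- pair_boundaries(millennium_120(), 0)
  expect_equal(nrow(pb), 60L)
  # first 5 mm pair (index 11, after ten 10 mm pairs from -200)
  expect_equal(pb$y_low[11], -100)
  expect_equal(pb$y_high[11], -95)
  # central 5 mm pairs span -100 to +100
  expect_equal(pb$y_low[51], 100)
  # contiguous partition of [y_min, y_min + sum(w))
  expect_equal(pb$y_low[-1], pb$y_high[-60])
  expect_equal(pb$y_high[60], -200 + sum(millennium_120()$pair_widths))
})

test_that("a bank offset shifts every boundary rigidly", {
  g <- toy_geometry()
  pb0 <- pair_boundaries(g, 0)
  pb <- pair_boundaries(g, 2.5)
  expect_equal(pb$y_low, pb0$y_low + 2.5)
  expect_equal(pb$y_high, pb0$y_high + 2.5)
})

test_that("row aggregation honors both modes on hand geometries", {
  g <- toy_geometry()
  # uniform field: every overlapped pair sees the constant
  uni <- fluence_grid(matrix(7, 20, 4), grid_spec(0, -10, 1, 1, 4, 20))
  for (mode in c("max", "coverage_weighted_mean")) {
    prof <- aggregate_pair_profiles(uni, g, 0, mode)
    touched <- apply(prof, 1, max) > 0
    expect_true(all(prof[touched, ] == 7))
  }
  # one 1 mm row of 10 inside a 5 mm pair
  one <- fluence_grid(matrix(10, 1, 3), grid_spec(0, 1, 1, 1, 3, 1))
  expect_equal(unname(aggregate_pair_profiles(one, g, 0, "max")[7, ]),
               rep(10, 3))
  expect_equal(unname(aggregate_pair_profiles(one, g, 0, "coverage_weighted_mean")[7, ]),
               rep(2, 3))
})

test_that("open pair count tracks the offset for a misaligned rectangle", {
  g <- toy_geometry()
  rect <- rect_grid(0, 40, 2.5, 27.5)  # spans y in [2.5, 27.5)
  n_open <- function(offset) {
    prof <- aggregate_pair_profiles(scale_to_mu(rect, 100), g, offset, "max")
    sum(apply(prof, 1, max) > 0)
  }
  expect_equal(n_open(0), 6L)
  expect_equal(n_open(2.5), 5L)
})

test_that("coverage-weighted aggregation conserves fluence column-wise", {
  g <- toy_geometry()
  for (seed in 1:5) {
    f <- random_grid(seed, nx = 5, ny = 30)
    f <- fluence_grid(f$values, grid_spec(0, -20, 1, 1, 5, 30))
    prof <- aggregate_pair_profiles(f, g, 0.75, "coverage_weighted_mean")
    lhs <- as.vector(g$pair_widths %*% prof)
    rhs <- colSums(f$values) * f$spec$dy
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("aggregation is equivariant under matched y shifts", {
  g <- toy_geometry()
  f <- random_grid(11, nx = 4, ny = 12)
  f <- fluence_grid(f$values, grid_spec(0, -10, 1, 1, 4, 12))
  for (mode in c("max", "coverage_weighted_mean")) {
    a <- aggregate_pair_profiles(shift_y(f, 2), g, 1.5, mode)
    b <- aggregate_pair_profiles(f, g, -0.5, mode)
    expect_equal(unclass(a)[, ], unclass(b)[, ], ignore_attr = TRUE)
  }
})

test_that("too-coarse rows are rejected with a pointer to upsample_rows", {
  g <- toy_geometry(width = 5)
  coarse <- fluence_grid(matrix(1, 2, 2), grid_spec(0, 0, 1, 6, 2, 2))
  expect_error(aggregate_pair_profiles(coarse, g),
               regexp = "upsample_rows", class = "dmlc2d_resolution_error")
})

test_that("machine setup loads from YAML with defaults and overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("machine:", "  dose_rate: 300", "geometry:",
               "  pair_widths: [10, 10, 10]", "  y_min: -15"), path)
  setup <- read_machine_setup(path)
  expect_equal(setup$machine$dose_rate, 300)
  expect_equal(setup$machine$max_leaf_speed, 25)
  expect_equal(setup$geometry$pair_widths, c(10, 10, 10))
  expect_equal(mu_speed(setup$machine), 25 * 60 / 300)
})
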