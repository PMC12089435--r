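test_that("the sliding-window recurrence reproduces the hand example", {
  phi <- c(2, 4, 4, 1, 1)
  # unconstrained leaf speed: tau = 0
  tr <- sequence_pair_profile(phi, dx = 1, v_mu = Inf)
  expect_equal(tr$arrival_right, c(0, 0, 0, 3, 3))
  expect_equal(tr$arrival_left, c(2, 4, 4, 4, 4))
  expect_equal(trajectory_gap(tr), phi)
  # speed-limited leaf: tau = dx / v_mu = 2 MU per beamlet
  tr2 <- sequence_pair_profile(phi, dx = 1, v_mu = 0.5)
  expect_equal(tr2$arrival_right, c(0, 2, 4, 9, 11))
  expect_equal(tr2$arrival_left, c(2, 6, 8, 10, 12))
  expect_equal(max(tr2$arrival_left), 12)
  expect_equal(trajectory_gap(tr2), phi)
})

test_that("zero profiles give a closed pair and negatives are rejected", {
  tr <- sequence_pair_profile(rep(0, 6), dx = 1, v_mu = 2)
  expect_equal(trajectory_gap(tr), rep(0, 6))
  expect_error(sequence_pair_profile(c(1, -0.1), dx = 1, v_mu = 2),
               class = "dmlc2d_value_error")
})

test_that("the recurrence is exact and feasible for random profiles", {
  machine <- machine_config()  # v_mu = 2.5 mm/MU, tau = 0.4 at 1 mm
  v <- mu_speed(machine)
  for (seed in 1:25) {
    phi <- withr::with_seed(seed, {
      n <- sample(5:40, 1)
      pmax(0, stats::runif(n, -0.3, 1) * 30)  # sparse, non-negative
    })
    tr <- sequence_pair_profile(phi, dx = 1, v_mu = v)
    expect_lt(max(abs(trajectory_gap(tr) - phi)), 1e-9)
    expect_true(all(diff(tr$arrival_right) >= 1 / v - 1e-9))
    expect_true(all(diff(tr$arrival_left) >= 1 / v - 1e-9))
  }
})

test_that("synchronization shares one MU clock and closes early finishers", {
  g <- toy_geometry(npairs = 2, y_min = 0)
  m <- fast_machine()
  xc <- seq(0.5, 4.5, by = 1)
  tr_a <- sequence_pair_profile(c(2, 4, 4, 1, 1), 1, v_mu = 0.5)  # total 12
  tr_b <- sequence_pair_profile(c(2, 2, 2, 0, 0), 1, v_mu = 0.5)  # total 10
  seq1 <- synchronize_pairs(list(tr_a, NULL), xc, g, m, bank_offset = 0)
  expect_equal(seq1$total_mu, 12)

  seq2 <- synchronize_pairs(list(tr_a, tr_b), xc, g, m)
  expect_equal(seq2$total_mu, 12)
  late <- seq2$mu > 10
  expect_true(any(late))
  expect_equal(seq2$left[late, 2], seq2$right[late, 2])
  # identical trajectories give identical position columns
  seq3 <- synchronize_pairs(list(tr_a, tr_a), xc, g, m)
  expect_equal(seq3$left[, 1], seq3$left[, 2])
  expect_equal(seq3$right[, 1], seq3$right[, 2])
  expect_error(synchronize_pairs(list(NULL, NULL), xc, g, m),
               class = "dmlc2d_argument_error")
})

test_that("control-point MU is non-decreasing and leaves sweep monotonically", {
  rect <- scale_to_mu(rect_grid(0, 40, 2.5, 27.5), 100)
  g <- toy_geometry()
  m <- fast_machine()
  sq <- sequence_field(rect, g, m, zero_sector_plan(rect, 8))
  expect_true(all(diff(sq$mu) >= 0))
  expect_true(all(diff(sq$left) >= -1e-9 | abs(diff(sq$mu)) < 1e-12))
  expect_true(all(sq$right - sq$left >= -1e-9))
  # leaf-speed feasibility between control points with positive MU width
  v <- mu_speed(m)
  dmu <- diff(sq$mu)
  ok <- dmu > 1e-9
  expect_true(all(abs(diff(sq$left)[ok, ]) <= v * dmu[ok] + 1e-9))
  expect_true(all(abs(diff(sq$right)[ok, ]) <= v * dmu[ok] + 1e-9))
})

test_that("a leaf-aligned uniform rectangle is delivered exactly", {
  rect <- scale_to_mu(rect_grid(0, 40, 5, 25), 100)  # aligned to 5 mm pairs
  g <- toy_geometry()
  m <- fast_machine()
  sq <- sequence_field(rect, g, m, zero_sector_plan(rect, 1))
  fine <- delivery_grid_spec(rect$spec, 0.25)
  actual <- reconstruct_fluence(sq, g, fine)
  planned <- upsample_rows(rect, 2)
  expect_equal(actual$values, planned$values, tolerance = 1e-9)
  expect_equal(conformity_index(actual, planned, 0.1), 1)
})

test_that("eight equal-offset sectors deliver the same fluence as one", {
  f <- random_grid(5, nx = 16, ny = 20)
  f <- fluence_grid(f$values, grid_spec(0, 0, 1, 1, 16, 20))
  f <- scale_to_mu(f, 50)
  g <- toy_geometry()
  m <- fast_machine()
  fine <- delivery_grid_spec(f$spec, 0.25)
  for (s in c(0, 1.25)) {
    sq8 <- sequence_field(f, g, m, sector_plan(seq(0, 16, by = 2), rep(s, 8)))
    sq1 <- sequence_field(f, g, m, sector_plan(c(0, 16), s))
    expect_equal(reconstruct_fluence(sq8, g, fine)$values,
                 reconstruct_fluence(sq1, g, fine)$values,
                 tolerance = 1e-9)
  }
})

test_that("sector transitions hold the beam while the bank moves", {
  rect <- scale_to_mu(rect_grid(0, 40, 2.5, 27.5), 100)
  g <- toy_geometry()
  m <- fast_machine()
  plan <- sector_plan(c(0, 20, 40), c(0, 2.5))
  sq <- sequence_field(rect, g, m, plan)
  jump <- which(diff(sq$offset) != 0)
  expect_length(jump, 1L)
  expect_equal(sq$mu[jump + 1], sq$mu[jump])  # zero-MU beam hold
})

test_that("sequences round-trip through the control-point table files", {
  rect <- scale_to_mu(rect_grid(0, 20, 2.5, 27.5, nx = 20), 50)
  g <- toy_geometry()
  m <- fast_machine()
  sq <- sequence_field(rect, g, m, sector_plan(c(0, 10, 20), c(0, 2.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence(sq, path)
  back <- read_sequence(path)
  expect_equal(back$mu, sq$mu, tolerance = 1e-12)
  expect_equal(back$left, sq$left, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$offset, sq$offset)
  fine <- delivery_grid_spec(rect$spec, 0.25)
  expect_equal(reconstruct_fluence(back, back$geometry, fine)$values,
               reconstruct_fluence(sq, g, fine)$values, tolerance = 1e-9)
})
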