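test_that("a static open rectangle accumulates the full beam-on MU", {
  g <- toy_geometry(npairs = 4, y_min = 0)  # pairs at [0,5)..[15,20)
  m <- fast_machine()
  # hand-built sequence: pairs 2-3 held open over x in [5, 15] for 400 MU
  left <- matrix(c(-100, -100, 5, 5, 5, 5, -100, -100), nrow = 2)
  right <- matrix(c(-100, -100, 15, 15, 15, 15, -100, -100), nrow = 2)
  sq <- dmlc2d:::new_mlc_sequence(mu = c(0, 400), offset = c(0, 0),
                                  left = left, right = right,
                                  geometry = g, machine = m)
  spec <- grid_spec(0, 0, 1, 0.25, 20, 80)
  fl <- reconstruct_fluence(sq, g, spec)
  inside <- fl$values[dmlc2d:::rows_in_band(spec, 5, 15), 6:15]
  expect_true(all(inside == 400))
  expect_equal(sum(fl$values) * 1 * 0.25, 400 * 10 * 10)
  # the oracle agrees exactly for a static aperture
  or <- simulate_delivery_oracle(sq, g, spec, mu_step = 7)
  expect_equal(or$values, fl$values, tolerance = 1e-12)
})

test_that("reconstruction reproduces the sequenced profile beamlet by beamlet", {
  g <- toy_geometry(npairs = 2, y_min = 0)
  m <- fast_machine()
  phi <- c(2, 4, 4, 1, 1)
  tr <- sequence_pair_profile(phi, 1, v_mu = 0.5)
  sq <- synchronize_pairs(list(tr, NULL), seq(0.5, 4.5), g, m)
  spec <- grid_spec(0, 0, 1, 0.25, 5, 20)
  fl <- reconstruct_fluence(sq, g, spec)
  expect_equal(fl$values[1, ], phi, tolerance = 1e-9)   # row inside pair 1
  expect_true(all(fl$values[dmlc2d:::rows_in_band(spec, 5, 20), ] == 0))
})

test_that("reconstruction is linear in total MU", {
  f <- scale_to_mu(random_grid(3, nx = 10, ny = 15), 40)
  g <- toy_geometry()
  m <- fast_machine()
  sq <- sequence_field(f, g, m, zero_sector_plan(f, 2))
  spec <- delivery_grid_spec(f$spec, 0.25)
  base <- reconstruct_fluence(sq, g, spec)
  sq2 <- sq
  sq2$mu <- sq$mu * 3
  sq2$total_mu <- sq$total_mu * 3
  expect_equal(reconstruct_fluence(sq2, g, spec)$values, 3 * base$values,
               tolerance = 1e-9)
  expect_true(all(base$values >= 0))
  expect_true(all(base$values <= sq$total_mu + 1e-9))
})

test_that("the time-stepped oracle converges to the analytic reconstruction", {
  g <- toy_geometry()
  m <- fast_machine()
  devs <- purrr::map_dbl(1:3, function(seed) {
    f <- scale_to_mu(random_grid(seed, nx = 12, ny = 18), 30)
    plan <- sector_plan(c(0, 6, 12), c(0.5, -0.75))
    sq <- sequence_field(f, g, m, plan)
    spec <- delivery_grid_spec(f$spec, 0.25)
    ana <- reconstruct_fluence(sq, g, spec)
    for (h in c(0.05, 0.01)) {
      or <- simulate_delivery_oracle(sq, g, spec, mu_step = h)
      expect_lt(max(abs(or$values - ana$values)), 2 * h)
    }
    d1 <- max(abs(simulate_delivery_oracle(sq, g, spec, 0.02)$values - ana$values))
    d2 <- max(abs(simulate_delivery_oracle(sq, g, spec, 0.01)$values - ana$values))
    # first-order convergence: each step stays within its 2*mu_step envelope
    # (so the certified deviation halves with the step) and the realized
    # worst case strictly decreases
    expect_lt(d1, 2 * 0.02)
    expect_lt(d2, 2 * 0.01)
    d2 / d1
  })
  expect_true(all(devs < 1))
})

test_that("oracle argument checks reject absurd steps", {
  f <- scale_to_mu(random_grid(1, nx = 6, ny = 10), 10)
  g <- toy_geometry()
  sq <- sequence_field(f, g, fast_machine(), zero_sector_plan(f, 1))
  spec <- delivery_grid_spec(f$spec, 0.25)
  expect_error(simulate_delivery_oracle(sq, g, spec, mu_step = sq$total_mu + 1),
               class = "dmlc2d_argument_error")
  expect_error(simulate_delivery_oracle(sq, g, spec, mu_step = 0),
               class = "dmlc2d_argument_error")
})
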