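test_that("grid read-back places values in the documented frame", {
  txt <- c("x0 0", "y0 0", "dx 1", "dy 1", "nx 3", "ny 2", "units relative",
           "0 1 0", "2 3 4")
  g <- read_fluence(textConnection(txt))
  # 0-based cell (i = 2, j = 1) covers x in [2,3), y in [1,2)
  expect_equal(g$values[2, 3], 4)
  expect_equal(g$spec$nx, 3L)
  expect_equal(g$spec$x0 + (3 - 0.5) * g$spec$dx, 2.5)
})

test_that("malformed input is rejected with informative errors", {
  expect_error(read_fluence(textConnection(character(0))),
               class = "dmlc2d_parse_error")
  expect_error(
    read_fluence(textConnection(c("x0 0", "y0 0", "dx 1", "dy 1", "nx 2",
                                  "units relative", "1 2"))),
    regexp = "ny", class = "dmlc2d_parse_error"
  )
  expect_error(
    read_fluence(textConnection(c("x0 0", "y0 0", "dx 1", "dy 1", "nx 2",
                                  "ny 2", "units relative", "1 2"))),
    class = "dmlc2d_dim_error"
  )
  expect_error(
    read_fluence(textConnection(c("x0 0", "y0 0", "dx 1", "dy 1", "nx 2",
                                  "ny 1", "units relative", "1 -2"))),
    regexp = "i = 1", class = "dmlc2d_value_error"
  )
})

test_that("write/read round trip is lossless, including in batches", {
  path <- withr::local_tempfile(fileext = ".txt")
  for (seed in 1:5) {
    g <- random_grid(seed, nx = 7, ny = 5)
    write_fluence(g, path)
    g2 <- read_fluence(path)
    expect_equal(g2$values, g$values)
    expect_equal(g2$spec, g$spec)
    expect_equal(g2$units, g$units)
  }
  # larger batch: specs and counts preserved
  dir <- withr::local_tempdir()
  n <- 25
  specs <- list()
  for (k in seq_len(n)) {
    g <- random_grid(100 + k, nx = 3 + k %% 4, ny = 2 + k %% 3)
    write_fluence(g, file.path(dir, sprintf("map%03d.txt", k)))
    specs[[k]] <- g$spec
  }
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, n)
  back <- lapply(files, read_fluence)
  expect_equal(lapply(back, `[[`, "spec"), specs)
})

test_that("degenerate writes stay readable", {
  path <- withr::local_tempfile()
  g <- fluence_grid(matrix(0, 1, 1), grid_spec(nx = 1, ny = 1))
  write_fluence(g, path)
  lines <- readLines(path)
  expect_equal(lines[length(lines)], "0")
  expect_equal(read_fluence(path)$values, matrix(0, 1, 1))
})

test_that("read clamps numerical dust below 1e-9 of the maximum", {
  txt <- c("x0 0", "y0 0", "dx 1", "dy 1", "nx 2", "ny 1", "units relative",
           "1 1e-12")
  g <- read_fluence(textConnection(txt))
  expect_equal(g$values[1, 2], 0)
})

test_that("row upsampling replicates rows and conserves integrated fluence", {
  g1 <- random_grid(42, nx = 6, ny = 4)
  expect_identical(upsample_rows(g1, 1), g1)

  one <- fluence_grid(matrix(5, 1, 2), grid_spec(nx = 2, ny = 1))
  up <- upsample_rows(one, 4)
  expect_equal(up$spec$dy, 0.25)
  expect_equal(up$values, matrix(5, 4, 2))

  up1 <- upsample_rows(g1, 4)
  expect_identical(sum(up1$values) * up1$spec$dx * up1$spec$dy,
                   sum(g1$values) * g1$spec$dx * g1$spec$dy)
  expect_error(upsample_rows(g1, 0), class = "dmlc2d_argument_error")
})

test_that("MU scaling anchors the map maximum at the prescribed MU", {
  g <- fluence_grid(matrix(c(1, 0.5), 1, 2), grid_spec(nx = 2, ny = 1))
  mu <- scale_to_mu(g, 500)
  expect_equal(mu$values, matrix(c(500, 250), 1, 2))
  expect_equal(mu$units, "MU")
  # renormalizing and rescaling is the identity
  renorm <- fluence_grid(mu$values / max(mu$values), mu$spec)
  expect_equal(scale_to_mu(renorm, 500)$values, mu$values)
  zero <- fluence_grid(matrix(0, 1, 1), grid_spec(nx = 1, ny = 1))
  expect_error(scale_to_mu(zero, 500), class = "dmlc2d_degenerate_error")
  expect_error(scale_to_mu(mu, 500), class = "dmlc2d_argument_error")
})

test_that("y shifts move the frame rigidly", {
  g <- random_grid(7)
  s <- shift_y(g, 2.5)
  expect_equal(s$spec$y0, g$spec$y0 + 2.5)
  expect_equal(s$values, g$values)
})
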