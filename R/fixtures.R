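#' Specification of a synthetic optimal fluence map
#'
#' Deterministic description of a synthetic target emulating clinical
#' sliding-window fluence maps: a binary support shape, optionally textured
#' with smooth multiplicative modulation. The key randomized parameter of
#' the suites is `y_offset`, the placement of the target's lower edge
#' relative to the leaf boundaries: the bank translation's whole effect
#' lives within one leaf width of the target border, so edges must occur at
#' all phases.
#'
#' @param shape `"rectangle"`, `"ellipse"`, `"two_lobe"` or `"modulated"`
#'   (a modulated rectangle).
#' @param x_extent,y_extent Target extents in mm (> 0).
#' @param y_offset Lower-edge placement (mm) relative to the nearest leaf
#'   boundary below the grid's vertical center.
#' @param modulation_depth Fraction in `[0, 1)`; 0 gives a binary map,
#'   otherwise the support is multiplied by smoothed seeded noise rescaled
#'   to `[1 - depth, 1]`.
#' @param seed Integer seed; the same spec and seed always reproduce the
#'   identical map.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(shape = c("rectangle", "ellipse", "two_lobe", "modulated"),
                         x_extent, y_extent, y_offset = 0,
                         modulation_depth = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (x_extent <= 0 || y_extent <= 0) {
    rlang::abort("Extents must be positive.", class = "dmlc2d_argument_error")
  }
  if (modulation_depth < 0 || modulation_depth >= 1) {
    rlang::abort("`modulation_depth` must be in [0, 1).", class = "dmlc2d_argument_error")
  }
  structure(
    list(shape = shape, x_extent = x_extent, y_extent = y_extent,
         y_offset = y_offset, modulation_depth = modulation_depth,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# separable moving-average smoothing with edge renormalization
smooth_noise <- function(m, k = 5L) {
  kern <- rep(1, k)
  sm <- function(v) {
    num <- stats::filter(v, kern, sides = 2)
    den <- stats::filter(rep(1, length(v)), kern, sides = 2)
    out <- as.numeric(num / den)
    # partial windows at the edges
    na <- is.na(out)
    if (any(na)) {
      half <- (k - 1L) %/% 2L
      for (i in which(na)) {
        lo <- max(1L, i - half); hi <- min(length(v), i + half)
        out[i] <- mean(v[lo:hi])
      }
    }
    out
  }
  m <- apply(m, 2L, sm)
  t(apply(m, 1L, sm))
}

#' Generate one synthetic optimal fluence map
#'
#' The shape is centered in x, and its lower edge is placed at the leaf
#' boundary (5 mm period) nearest below the grid's vertical center, plus
#' `y_offset`. Support membership is decided by cell-center containment;
#' values are relative units with maximum 1.
#'
#' @param fspec A [fixture_spec()].
#' @param grid A [grid_spec()] the shape must fit into.
#' @return A [fluence_grid()] in relative units.
#' @export
generate_fixture <- function(fspec, grid) {
  stopifnot(inherits(fspec, "fixture_spec"), inherits(grid, "grid_spec"))
  xc <- x_centers(grid)
  yc <- y_centers(grid)
  cx <- grid$x0 + grid$nx * grid$dx / 2
  gy_mid <- grid$y0 + grid$ny * grid$dy / 2
  y_lo <- 5 * floor((gy_mid - fspec$y_extent / 2) / 5) + fspec$y_offset
  y_hi <- y_lo + fspec$y_extent
  x_lo <- cx - fspec$x_extent / 2
  x_hi <- cx + fspec$x_extent / 2
  if (x_lo < grid$x0 || x_hi > grid$x0 + grid$nx * grid$dx ||
      y_lo < grid$y0 || y_hi > grid$y0 + grid$ny * grid$dy) {
    rlang::abort("Shape does not fit inside the grid.", class = "dmlc2d_argument_error")
  }
  X <- matrix(rep(xc, each = grid$ny), nrow = grid$ny)
  Y <- matrix(rep(yc, times = grid$nx), nrow = grid$ny)
  inside <- switch(
    fspec$shape,
    rectangle = ,
    modulated = X >= x_lo & X < x_hi & Y >= y_lo & Y < y_hi,
    ellipse = {
      a <- fspec$x_extent / 2; b <- fspec$y_extent / 2
      ((X - cx) / a)^2 + ((Y - (y_lo + b)) / b)^2 <= 1
    },
    two_lobe = {
      a <- fspec$x_extent * 0.225; b <- fspec$y_extent / 2
      c1 <- cx - fspec$x_extent * 0.275
      c2 <- cx + fspec$x_extent * 0.275
      cyy <- y_lo + b
      (((X - c1) / a)^2 + ((Y - cyy) / b)^2 <= 1) |
        (((X - c2) / a)^2 + ((Y - cyy) / b)^2 <= 1)
    }
  )
  vals <- matrix(0, nrow = grid$ny, ncol = grid$nx)
  vals[inside] <- 1
  if (fspec$modulation_depth > 0 && any(inside)) {
    noise <- withr::with_seed(fspec$seed, {
      smooth_noise(matrix(stats::runif(grid$ny * grid$nx), nrow = grid$ny))
    })
    rng <- range(noise[inside])
    tex <- if (diff(rng) > 0) {
      (1 - fspec$modulation_depth) +
        fspec$modulation_depth * (noise - rng[1]) / diff(rng)
    } else {
      matrix(1, nrow = grid$ny, ncol = grid$nx)
    }
    vals[inside] <- vals[inside] * tex[inside]
  }
  if (max(vals) > 0) vals <- vals / max(vals)
  fluence_grid(vals, grid, units = "relative")
}

#' Generate a seeded suite of synthetic fluence maps
#'
#' Draws `n` targets from a regime: `"small"` targets have vertical extents
#' of 20-30 mm (the head-and-neck / lung scale, where the bank translation
#' matters most) and `"large"` ones 60-80 mm (the liver scale, where the
#' half-leaf-width translation is small against the target). Shapes are
#' drawn uniformly from rectangle / ellipse / two-lobe with modulation depth
#' 0.3, x-extents from 30-60 mm (small) or 50-90 mm (large), and lower-edge
#' placements uniform over [0, 5) mm so the target border visits every phase
#' of the 5 mm leaf period. Grids are 1 mm beamlets with a 10 mm margin.
#'
#' @param n Number of maps.
#' @param regime `"small"` or `"large"`.
#' @param seed Integer seed; the suite is reproduced identically from the
#'   same seed.
#' @param modulation_depth Texture depth applied to every map.
#' @param margin Grid margin around the target, mm.
#' @return A list with `grids` (list of [fluence_grid()]) and `specs`
#'   (tibble of the drawn parameters, for provenance).
#' @export
generate_suite <- function(n, regime = c("small", "large"), seed = 1L,
                           modulation_depth = 0.3, margin = 10) {
  regime <- match.arg(regime)
  if (n < 1L) rlang::abort("`n` must be >= 1.", class = "dmlc2d_argument_error")
  y_range <- switch(regime, small = c(20, 30), large = c(60, 80))
  x_range <- switch(regime, small = c(30, 60), large = c(50, 90))
  draws <- withr::with_seed(seed, {
    tibble::tibble(
      case = seq_len(n),
      shape = sample(c("rectangle", "ellipse", "two_lobe"), n, replace = TRUE),
      x_extent = stats::runif(n, x_range[1], x_range[2]),
      y_extent = stats::runif(n, y_range[1], y_range[2]),
      y_offset = stats::runif(n, 0, 5),
      map_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  grids <- purrr::pmap(
    draws[, c("shape", "x_extent", "y_extent", "y_offset", "map_seed")],
    function(shape, x_extent, y_extent, y_offset, map_seed) {
      nx <- ceiling(x_extent) + 2 * margin
      ny <- ceiling(y_extent) + 2 * margin + 5   # room for the offset shift
      generate_fixture(
        fixture_spec(shape, x_extent, y_extent, y_offset,
                     modulation_depth = modulation_depth, seed = map_seed),
        grid_spec(x0 = 0, y0 = 0, dx = 1, dy = 1, nx = nx, ny = ny)
      )
    }
  )
  list(grids = grids, specs = draws)
}
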