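#' Multileaf collimator geometry
#'
#' Leaf-pair widths (ordered bottom to top along y), the bottom boundary of
#' the first pair at zero bank offset, and the leaf travel limits along x.
#' Pair `k` (1-based) at bank offset `s` covers
#' `y in [Y_k + s, Y_k + w_k + s)` with `Y_k = y_min + sum(w_m, m < k)`.
#'
#' @param pair_widths Numeric vector of leaf widths in mm, bottom to top.
#' @param y_min Bottom boundary (mm) of pair 1 at zero offset.
#' @param x_travel_min,x_travel_max Leaf position limits (mm).
#' @return An object of class `mlc_geometry`.
#' @export
mlc_geometry <- function(pair_widths, y_min,
                         x_travel_min = -200, x_travel_max = 200) {
  pair_widths <- as.numeric(pair_widths)
  if (!length(pair_widths) || any(!is.finite(pair_widths) | pair_widths <= 0)) {
    rlang::abort("All leaf-pair widths must be positive.", class = "dmlc2d_spec_error")
  }
  if (x_travel_min >= x_travel_max) {
    rlang::abort("`x_travel_min` must be below `x_travel_max`.", class = "dmlc2d_spec_error")
  }
  structure(
    list(pair_widths = pair_widths, y_min = as.numeric(y_min),
         x_travel_min = as.numeric(x_travel_min),
         x_travel_max = as.numeric(x_travel_max)),
    class = "mlc_geometry"
  )
}

#' Varian Millennium 120 leaf layout
#'
#' 60 leaf pairs: 10 outer pairs of 10 mm, 40 central pairs of 5 mm, 10 outer
#' pairs of 10 mm, centered so the 5 mm pairs span -100 to +100 mm.
#'
#' @inheritParams mlc_geometry
#' @export
millennium_120 <- function(x_travel_min = -200, x_travel_max = 200) {
  mlc_geometry(c(rep(10, 10), rep(5, 40), rep(10, 10)), y_min = -200,
               x_travel_min = x_travel_min, x_travel_max = x_travel_max)
}

#' @export
print.mlc_geometry <- function(x, ...) {
  cat(sprintf("<mlc_geometry> %d pairs, widths %g-%g mm, y in [%g, %g) mm at zero offset\n",
              length(x$pair_widths), min(x$pair_widths), max(x$pair_widths),
              x$y_min, x$y_min + sum(x$pair_widths)))
  invisible(x)
}

#' Machine delivery configuration
#'
#' @param dose_rate Dose rate in MU/min.
#' @param max_leaf_speed Maximum leaf speed in mm/s.
#' @param total_mu Total MU assigned to the maximum of a relative fluence map
#'   (see [scale_to_mu()]).
#' @return An object of class `machine_config`.
#' @export
machine_config <- function(dose_rate = 600, max_leaf_speed = 25, total_mu = 500) {
  if (!is.finite(dose_rate) || dose_rate <= 0) {
    rlang::abort("`dose_rate` must be positive.", class = "dmlc2d_spec_error")
  }
  if (!is.finite(max_leaf_speed) || max_leaf_speed <= 0) {
    rlang::abort("`max_leaf_speed` must be positive and finite.", class = "dmlc2d_spec_error")
  }
  structure(
    list(dose_rate = dose_rate, max_leaf_speed = max_leaf_speed, total_mu = total_mu),
    class = "machine_config"
  )
}

#' MU-domain leaf speed
#'
#' Converts the mechanical leaf speed to mm per MU:
#' `v_MU = max_leaf_speed * 60 / dose_rate`. Its reciprocal times the beamlet
#' width is the minimum MU a leaf needs to cross one beamlet.
#'
#' @param machine A [machine_config()].
#' @export
mu_speed <- function(machine) {
  stopifnot(inherits(machine, "machine_config"))
  machine$max_leaf_speed * 60 / machine$dose_rate
}

#' Leaf-pair apertures along y at a bank offset
#'
#' @param geometry An [mlc_geometry()].
#' @param offset Rigid bank translation along y, in mm.
#' @return A tibble with columns `pair`, `width`, `y_low`, `y_high`
#'   (contiguous half-open intervals `[y_low, y_high)`).
#' @export
pair_boundaries <- function(geometry, offset = 0) {
  stopifnot(inherits(geometry, "mlc_geometry"))
  w <- geometry$pair_widths
  lo <- geometry$y_min + c(0, cumsum(w)[-length(w)]) + offset
  tibble::tibble(pair = seq_along(w), width = w, y_low = lo, y_high = lo + w)
}

#' Reduce fluence rows to per-pair 1-D profiles
#'
#' Each leaf pair can realize only one intensity profile along x, so the
#' (finer) fluence rows its aperture overlaps must be reduced to a single
#' target profile per pair. In `"max"` mode any row overlapping the pair by
#' at least 10 % of the row height counts fully and the profile is the
#' row-wise maximum: the pair opens whenever any covered row demands fluence,
#' which over-covers the target at its superior/inferior borders exactly as a
#' rigid-bank MLC does. In `"coverage_weighted_mean"` mode rows are weighted
#' by their overlap fraction, which conserves integrated fluence across the
#' reduction.
#'
#' @param fluence A [fluence_grid()] with `dy` at most the smallest leaf width.
#' @param geometry An [mlc_geometry()].
#' @param offset Bank y-offset in mm.
#' @param mode `"max"` (default) or `"coverage_weighted_mean"`.
#' @return A matrix with one row per leaf pair and `nx` columns, with
#'   attributes `offset` and `mode`. Pairs overlapping no nonzero row are all
#'   zero.
#' @export
aggregate_pair_profiles <- function(fluence, geometry, offset = 0,
                                    mode = c("max", "coverage_weighted_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fluence, "fluence_grid"), inherits(geometry, "mlc_geometry"))
  s <- fluence$spec
  if (s$dy > min(geometry$pair_widths) + 1e-9) {
    rlang::abort(
      sprintf("Fluence row height dy = %g mm exceeds the smallest leaf width (%g mm); upsample_rows() the map first.",
              s$dy, min(geometry$pair_widths)),
      class = "dmlc2d_resolution_error"
    )
  }
  pb <- pair_boundaries(geometry, offset)
  row_lo <- s$y0 + (seq_len(s$ny) - 1) * s$dy
  row_hi <- row_lo + s$dy
  npairs <- nrow(pb)
  out <- matrix(0, nrow = npairs, ncol = s$nx)
  for (k in seq_len(npairs)) {
    ovl <- pmin(pb$y_high[k], row_hi) - pmax(pb$y_low[k], row_lo)
    ovl[ovl < 0] <- 0
    if (mode == "max") {
      sel <- ovl >= 0.1 * s$dy - 1e-12
      if (any(sel)) {
        block <- fluence$values[sel, , drop = FALSE]
        out[k, ] <- do.call(pmax, c(asplit(block, 1), list(0)))
      }
    } else {
      out[k, ] <- as.vector(ovl %*% fluence$values) / pb$width[k]
    }
  }
  structure(out, offset = offset, mode = mode)
}

#' Read MLC geometry and machine configuration from a YAML file
#'
#' The file may contain a `geometry` block (`preset: millennium_120` or
#' explicit `pair_widths`, `y_min`, `x_travel_min`, `x_travel_max`) and a
#' `machine` block (`dose_rate`, `max_leaf_speed`, `total_mu`). Missing
#' fields fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `geometry` and `machine`.
#' @export
read_machine_setup <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry %||% list()
  geometry <- if (!is.null(g$pair_widths)) {
    mlc_geometry(g$pair_widths,
                 y_min = g$y_min %||% -sum(g$pair_widths) / 2,
                 x_travel_min = g$x_travel_min %||% -200,
                 x_travel_max = g$x_travel_max %||% 200)
  } else {
    millennium_120(x_travel_min = g$x_travel_min %||% -200,
                   x_travel_max = g$x_travel_max %||% 200)
  }
  m <- cfg$machine %||% list()
  machine <- machine_config(dose_rate = m$dose_rate %||% 600,
                            max_leaf_speed = m$max_leaf_speed %||% 25,
                            total_mu = m$total_mu %||% 500)
  list(geometry = geometry, machine = machine)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
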