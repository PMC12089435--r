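#' Candidate bank offsets for the sector search
#'
#' The bank translation is bounded by half the leaf width (so the same beam
#' field is never repeated during the search) and discretized; the defaults
#' (5 mm leaves, 0.25 mm step) give 21 symmetric candidates spanning
#' -2.5 to +2.5 mm.
#'
#' @param leaf_width Engaged leaf width in mm.
#' @param step Search step in mm; must divide `leaf_width / 2` exactly.
#' @return Ascending numeric vector of candidate offsets (mm), always
#'   including 0.
#' @export
candidate_offsets <- function(leaf_width = 5, step = 0.25) {
  if (!is.finite(step) || step <= 0) {
    rlang::abort("`step` must be positive.", class = "dmlc2d_argument_error")
  }
  half <- leaf_width / 2
  k <- half / step
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort(
      sprintf("`step` (%g mm) must divide half the leaf width (%g mm) exactly.",
              step, half),
      class = "dmlc2d_argument_error"
    )
  }
  (-round(k):round(k)) * step
}

# smallest leaf width among pairs overlapping the map's nonzero rows at zero
# offset: sets the admissible offset range
engaged_leaf_width <- function(fluence, geometry) {
  s <- fluence$spec
  nz <- which(apply(fluence$values, 1L, function(r) any(r > 0)))
  if (!length(nz)) return(min(geometry$pair_widths))
  lo <- s$y0 + (min(nz) - 1L) * s$dy
  hi <- s$y0 + max(nz) * s$dy
  pb <- pair_boundaries(geometry, 0)
  hit <- pb$y_high > lo & pb$y_low < hi
  if (!any(hit)) return(min(geometry$pair_widths))
  min(pb$width[hit])
}

# expand per-pair profiles onto fine y rows (centers) at a bank offset:
# row j takes the profile of the pair containing its center, else zero
profiles_to_rows <- function(prof, geometry, offset, y_cent, nx) {
  pb <- pair_boundaries(geometry, offset)
  idx <- findInterval(y_cent, pb$y_low)
  idx[idx < 1L | y_cent >= max(pb$y_high)] <- NA_integer_
  out <- matrix(0, nrow = length(y_cent), ncol = nx)
  ok <- which(!is.na(idx))
  out[ok, ] <- prof[idx[ok], , drop = FALSE]
  out
}

#' Score one candidate bank offset on one sector
#'
#' Sequences the sector's columns at the given offset and compares the
#' resulting deliverable fluence with the optimal fluence on a fine
#' (`candidate_step`) y grid: the objective is the mean absolute difference
#' over the sector, normalized by the mean optimal intensity over the
#' sector's nonzero region. The comparison band extends one leaf width above
#' and below the sector's nonzero rows, because the over-coverage the bank
#' offset removes lives just outside the target. The deliverable fluence of
#' a sector equals its aggregated per-pair profiles exactly (the sequencer
#' recurrence reproduces any non-negative profile), which this function
#' exploits instead of re-running the full sequence/reconstruct pipeline for
#' each of the candidates.
#'
#' @param fluence A [fluence_grid()] in MU units.
#' @param cols Integer vector of the sector's column indices.
#' @param geometry An [mlc_geometry()].
#' @param machine A [machine_config()].
#' @param offset Candidate bank offset (mm).
#' @param mode Aggregation mode, see [aggregate_pair_profiles()].
#' @param y_step Fine comparison grid step (mm).
#' @return Unitless non-negative objective; 0 for an all-zero sector.
#' @export
score_offset <- function(fluence, cols, geometry, machine, offset,
                         mode = c("max", "coverage_weighted_mean"),
                         y_step = 0.25) {
  mode <- match.arg(mode)
  s <- fluence$spec
  sub_vals <- fluence$values[, cols, drop = FALSE]
  nz <- which(apply(sub_vals, 1L, function(r) any(r > 0)))
  if (!length(nz)) {
    rlang::inform("All-zero sector: bank offset is irrelevant, objective 0.",
                  .frequency = "once", .frequency_id = "dmlc2d_zero_sector")
    return(0)
  }
  sub <- fluence_grid(sub_vals,
                      grid_spec(s$x0 + (cols[1] - 1L) * s$dx, s$y0,
                                s$dx, s$dy, length(cols), s$ny),
                      units = fluence$units)
  guard <- min(geometry$pair_widths[
    pair_boundaries(geometry, 0)$y_high > s$y0 + (min(nz) - 1L) * s$dy &
      pair_boundaries(geometry, 0)$y_low < s$y0 + max(nz) * s$dy
  ])
  band_lo <- s$y0 + (min(nz) - 1L) * s$dy - guard
  band_hi <- s$y0 + max(nz) * s$dy + guard
  n_fine <- round((band_hi - band_lo) / y_step)
  y_fine <- band_lo + (seq_len(n_fine) - 0.5) * y_step

  prof <- aggregate_pair_profiles(sub, geometry, offset, mode)
  actual <- profiles_to_rows(prof, geometry, offset, y_fine, length(cols))

  # replicate the optimal rows onto the fine centers (0 outside the grid)
  src <- floor((y_fine - s$y0) / s$dy) + 1L
  planned <- matrix(0, nrow = n_fine, ncol = length(cols))
  ok <- which(src >= 1L & src <= s$ny)
  planned[ok, ] <- sub_vals[src[ok], , drop = FALSE]

  norm <- mean(planned[planned > 0])
  mean(abs(actual - planned)) / norm
}

#' Optimize the bank offset for every sector of a fluence map
#'
#' Divides the map into `n_sectors` equal-width x sectors and, independently
#' for each, evaluates every candidate offset (always including 0) with
#' [score_offset()], selecting the minimizer. Ties (within 1e-9 relative)
#' are broken by the smallest |offset|, then by the positive sign, so an
#' already-aligned sector keeps the bank still and the selection is fully
#' deterministic.
#'
#' @inheritParams score_offset
#' @param fluence A [fluence_grid()] in MU units.
#' @param n_sectors Number of sectors (default 8).
#' @param candidate_step Offset search step in mm (default 0.25).
#' @return A [sector_plan()] with extra columns `objective` (at the chosen
#'   offset) and `objective_zero` (at offset 0).
#' @export
optimize_sectors <- function(fluence, geometry, machine, n_sectors = 8,
                             candidate_step = 0.25,
                             mode = c("max", "coverage_weighted_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fluence, "fluence_grid"))
  if (fluence$units != "MU") {
    rlang::abort("`fluence` must be in MU units; apply scale_to_mu() first.",
                 class = "dmlc2d_argument_error")
  }
  spec <- fluence$spec
  edges <- default_sector_edges(spec, n_sectors)
  width <- engaged_leaf_width(fluence, geometry)
  cand <- candidate_offsets(width, candidate_step)

  res <- purrr::map(seq_len(length(edges) - 1L), function(sct) {
    cols <- sector_columns(spec, edges[sct], edges[sct + 1L])
    scores <- vapply(cand, function(o) {
      score_offset(fluence, cols, geometry, machine, o, mode = mode,
                   y_step = candidate_step)
    }, numeric(1))
    best <- min(scores)
    tied <- which(scores <= best + 1e-9 * max(best, 1e-12) + 1e-15)
    pick <- tied[order(abs(cand[tied]), -cand[tied])][1]
    list(offset = cand[pick], objective = scores[pick],
         objective_zero = scores[cand == 0])
  })

  plan <- sector_plan(edges, purrr::map_dbl(res, "offset"),
                      candidate_step = candidate_step, max_offset = width / 2)
  plan$objective <- purrr::map_dbl(res, "objective")
  plan$objective_zero <- purrr::map_dbl(res, "objective_zero")
  attr(plan, "mode") <- mode
  plan
}

#' Serialize a sector plan to JSON
#'
#' @param plan A [sector_plan()].
#' @param path Output path.
#' @export
write_sector_plan <- function(plan, path) {
  jsonlite::write_json(
    list(sector_edges = c(plan$x_min, plan$x_max[nrow(plan)]),
         offsets = plan$offset,
         candidate_step = attr(plan, "candidate_step"),
         max_offset = attr(plan, "max_offset")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(plan)
}

#' Read a sector plan from JSON
#'
#' @param path Path written by [write_sector_plan()].
#' @export
read_sector_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sector_plan(x$sector_edges, x$offsets,
              candidate_step = x$candidate_step %||% 0.25,
              max_offset = x$max_offset)
}
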