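#' Sliding-window leaf trajectory for one pair
#'
#' Converts a non-negative 1-D MU profile sampled at the beamlet centers into
#' arrival MUs for the leading (right) and trailing (left) leaf of a pair
#' sweeping left to right. The arrival MU at a beamlet is the cumulative MU
#' (beam-on time at fixed dose rate) at which the leaf edge reaches that
#' beamlet center. With profile increment `D = phi[i+1] - phi[i]` and the
#' minimum crossing MU `tau = dx / v_MU`:
#'
#' * `D >= 0`: the leading leaf steps first,
#'   `r[i+1] = r[i] + tau`, `l[i+1] = r[i+1] + phi[i+1]`;
#' * `D < 0`: the trailing leaf steps first,
#'   `l[i+1] = l[i] + tau`, `r[i+1] = l[i+1] - phi[i+1]`;
#'
#' starting from `r[1] = 0`, `l[1] = phi[1]`. The gap `l - r` then equals
#' `phi` at every beamlet exactly, both sequences are non-decreasing, and no
#' leaf crosses a beamlet in less than `tau` MU. Equivalently, in closed
#' form, `r[i] = (i-1)*tau + sum(max(0, -diff(phi))[1:(i-1)])`.
#'
#' @param profile Non-negative numeric vector, MU per beamlet.
#' @param dx Beamlet width in mm.
#' @param machine A [machine_config()]; ignored when `v_mu` is given.
#' @param v_mu MU-domain leaf speed in mm/MU; `Inf` models an idealized,
#'   speed-unconstrained leaf (`tau = 0`).
#' @return An object of class `pair_trajectory`: list with `arrival_right`,
#'   `arrival_left` (MU at each beamlet center) and `tau`.
#' @export
sequence_pair_profile <- function(profile, dx, machine = NULL,
                                  v_mu = mu_speed(machine)) {
  profile <- as.numeric(profile)
  if (any(!is.finite(profile) | profile < 0)) {
    rlang::abort("Profile values must be finite and >= 0.", class = "dmlc2d_value_error")
  }
  if (!(v_mu > 0)) {
    rlang::abort("`v_mu` must be positive.", class = "dmlc2d_argument_error")
  }
  tau <- if (is.finite(v_mu)) dx / v_mu else 0
  n <- length(profile)
  if (n == 1L) {
    ar <- 0
  } else {
    ar <- c(0, cumsum(tau + pmax(0, -diff(profile))))
  }
  structure(list(arrival_right = ar, arrival_left = ar + profile, tau = tau),
            class = "pair_trajectory")
}

merge_times <- function(times, tol = 1e-6) {
  times <- sort(times)
  keep <- c(TRUE, diff(times) > tol)
  times[keep]
}

#' Synchronize pair trajectories on one MU clock
#'
#' All pairs share the global beam-on clock: the sequence total is the
#' largest final trailing-leaf arrival, pairs finishing early hold closed at
#' their final position, and a control point is emitted at every distinct
#' arrival MU (merged within 1e-6 MU) recording interpolated leaf positions
#' for every pair.
#'
#' @param trajectories List of [sequence_pair_profile()] results, one per
#'   leaf pair (in geometry order); `NULL` entries are parked pairs.
#' @param x_centers Beamlet center x-coordinates (mm) the trajectories were
#'   computed on.
#' @param geometry An [mlc_geometry()] (parked pairs sit closed at
#'   `x_travel_min`).
#' @param machine A [machine_config()].
#' @param bank_offset Bank y-offset (mm) recorded on every control point.
#' @param mu0 MU value of the first control point (used when concatenating
#'   sectors).
#' @return An object of class `mlc_sequence`; see [sequence_field()].
#' @export
synchronize_pairs <- function(trajectories, x_centers, geometry, machine,
                              bank_offset = 0, mu0 = 0) {
  if (!length(trajectories) || all(vapply(trajectories, is.null, logical(1)))) {
    rlang::abort("Need at least one non-parked pair trajectory.",
                 class = "dmlc2d_argument_error")
  }
  active <- which(!vapply(trajectories, is.null, logical(1)))
  times <- merge_times(c(0, unlist(lapply(trajectories[active], function(tr) {
    c(tr$arrival_right, tr$arrival_left)
  }))))
  npairs <- length(trajectories)
  ncp <- length(times)
  left <- matrix(geometry$x_travel_min, nrow = ncp, ncol = npairs)
  right <- matrix(geometry$x_travel_min, nrow = ncp, ncol = npairs)
  for (p in active) {
    tr <- trajectories[[p]]
    right[, p] <- leaf_position(tr$arrival_right, x_centers, times)
    left[, p] <- leaf_position(tr$arrival_left, x_centers, times)
  }
  new_mlc_sequence(mu = times + mu0, offset = rep(bank_offset, ncp),
                   left = left, right = right,
                   geometry = geometry, machine = machine)
}

# piecewise-linear position (mm) vs MU through the (arrival, node) points,
# clamped to the end positions outside the sweep
leaf_position <- function(arrivals, nodes, at) {
  if (length(nodes) == 1L) {
    return(rep(nodes, length(at)))
  }
  stats::approx(x = arrivals, y = nodes, xout = at, method = "linear",
                rule = 2, ties = "ordered")$y
}

new_mlc_sequence <- function(mu, offset, left, right, geometry, machine,
                             plan = NULL) {
  structure(
    list(mu = mu, offset = offset, left = left, right = right,
         total_mu = max(mu), geometry = geometry, machine = machine,
         plan = plan),
    class = "mlc_sequence"
  )
}

#' @export
print.mlc_sequence <- function(x, ...) {
  cat(sprintf("<mlc_sequence> %d control points, %d pairs, total %.4g MU, bank offsets [%g, %g] mm\n",
              length(x$mu), ncol(x$left), x$total_mu, min(x$offset), max(x$offset)))
  invisible(x)
}

#' Control-point table of an MLC sequence
#'
#' @param x An `mlc_sequence`.
#' @param ... Unused.
#' @return A tibble with one row per control point and pair: `mu`,
#'   `bank_offset`, `pair`, `left`, `right`.
#' @method as_tibble mlc_sequence
#' @export
as_tibble.mlc_sequence <- function(x, ...) {
  ncp <- length(x$mu)
  npairs <- ncol(x$left)
  tibble::tibble(
    mu = rep(x$mu, times = npairs),
    bank_offset = rep(x$offset, times = npairs),
    pair = rep(seq_len(npairs), each = ncp),
    left = as.vector(x$left),
    right = as.vector(x$right)
  )
}

#' Partition of a fluence map into bank-offset sectors
#'
#' A sector plan partitions the map's x-range into contiguous sectors, each
#' holding one rigid bank y-offset during the sweep. The conventional
#' (x-only) technique is the all-zero plan.
#'
#' @param sector_edges Increasing numeric vector of x boundaries (mm),
#'   covering the fluence map.
#' @param offsets Bank y-offset (mm) per sector; length
#'   `length(sector_edges) - 1`.
#' @param candidate_step Offset search step (mm); metadata.
#' @param max_offset Offset bound (mm); metadata.
#' @return A tibble of class `sector_plan` with columns `sector`, `x_min`,
#'   `x_max`, `offset`.
#' @export
sector_plan <- function(sector_edges, offsets, candidate_step = 0.25,
                        max_offset = NULL) {
  sector_edges <- as.numeric(sector_edges)
  n <- length(sector_edges) - 1L
  if (n < 1L || any(diff(sector_edges) <= 0)) {
    rlang::abort("`sector_edges` must be increasing with at least two values.",
                 class = "dmlc2d_plan_error")
  }
  if (length(offsets) != n) {
    rlang::abort("Need one offset per sector.", class = "dmlc2d_plan_error")
  }
  if (!is.null(max_offset) && any(abs(offsets) > max_offset + 1e-9)) {
    rlang::abort("Offsets exceed `max_offset`.", class = "dmlc2d_plan_error")
  }
  out <- tibble::tibble(
    sector = seq_len(n),
    x_min = sector_edges[-(n + 1L)],
    x_max = sector_edges[-1L],
    offset = as.numeric(offsets)
  )
  attr(out, "candidate_step") <- candidate_step
  attr(out, "max_offset") <- max_offset
  class(out) <- c("sector_plan", class(out))
  out
}

#' All-zero (conventional) sector plan for a fluence map
#'
#' @param fluence A [fluence_grid()] (or a [grid_spec()]).
#' @param n_sectors Number of equal-width sectors.
#' @export
zero_sector_plan <- function(fluence, n_sectors = 1) {
  spec <- if (inherits(fluence, "fluence_grid")) fluence$spec else fluence
  sector_plan(default_sector_edges(spec, n_sectors), rep(0, n_sectors))
}

# equal-count column splits, expressed as x boundaries in mm
default_sector_edges <- function(spec, n_sectors) {
  n_sectors <- as.integer(n_sectors)
  if (n_sectors < 1L || n_sectors > spec$nx) {
    rlang::abort(sprintf("`n_sectors` must be in 1..nx (= %d).", spec$nx),
                 class = "dmlc2d_plan_error")
  }
  cuts <- round(seq(0, spec$nx, length.out = n_sectors + 1L))
  spec$x0 + cuts * spec$dx
}

# map sector x-interval to fluence column indices; edges must sit on column
# boundaries
sector_columns <- function(spec, x_min, x_max) {
  i0 <- (x_min - spec$x0) / spec$dx
  i1 <- (x_max - spec$x0) / spec$dx
  if (abs(i0 - round(i0)) > 1e-6 || abs(i1 - round(i1)) > 1e-6) {
    rlang::abort("Sector edges must lie on beamlet column boundaries.",
                 class = "dmlc2d_plan_error")
  }
  seq.int(round(i0) + 1L, round(i1))
}

#' Sequence a full fluence map under a sector plan
#'
#' Runs the sliding-window sequencer sector by sector: within each sector the
#' per-pair profiles are aggregated at that sector's bank offset
#' ([aggregate_pair_profiles()]), sequenced ([sequence_pair_profile()]) and
#' synchronized on a shared MU clock; sectors are concatenated in sweep order
#' (left to right). The bank moves between sectors during a beam hold,
#' modeled as a pair of control points at the same cumulative MU (the only
#' places where MU does not strictly increase). Pairs with zero profile
#' everywhere are parked closed at `x_travel_min`; pairs zero only within a
#' sector sweep through it closed.
#'
#' @param fluence A [fluence_grid()] in MU units (see [scale_to_mu()]).
#' @param geometry An [mlc_geometry()].
#' @param machine A [machine_config()].
#' @param plan A [sector_plan()]; default is the conventional single-sector
#'   zero plan.
#' @param mode Row-to-pair aggregation mode, see [aggregate_pair_profiles()].
#' @return An object of class `mlc_sequence` with fields `mu`, `offset`
#'   (per control point), `left`, `right` (control points x pairs position
#'   matrices, mm), `total_mu`, `geometry`, `machine`, `plan`.
#' @export
sequence_field <- function(fluence, geometry, machine, plan = NULL,
                           mode = c("max", "coverage_weighted_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fluence, "fluence_grid"))
  if (fluence$units != "MU") {
    rlang::abort("`fluence` must be in MU units; apply scale_to_mu() first.",
                 class = "dmlc2d_argument_error")
  }
  spec <- fluence$spec
  if (is.null(plan)) plan <- zero_sector_plan(fluence, 1)
  x_lo <- spec$x0
  x_hi <- spec$x0 + spec$nx * spec$dx
  if (abs(plan$x_min[1] - x_lo) > 1e-6 ||
      abs(plan$x_max[nrow(plan)] - x_hi) > 1e-6) {
    rlang::abort("Sector plan does not cover the fluence map's x-range.",
                 class = "dmlc2d_plan_error")
  }
  xc <- x_centers(spec)
  npairs <- length(geometry$pair_widths)
  v <- mu_speed(machine)

  # aggregate every sector first so globally-parked pairs are known
  sectors <- purrr::pmap(
    list(plan$x_min, plan$x_max, plan$offset),
    function(x_min, x_max, offset) {
      cols <- sector_columns(spec, x_min, x_max)
      sub <- fluence_grid(fluence$values[, cols, drop = FALSE],
                          grid_spec(spec$x0 + (cols[1] - 1L) * spec$dx, spec$y0,
                                    spec$dx, spec$dy, length(cols), spec$ny),
                          units = "MU")
      list(cols = cols, prof = aggregate_pair_profiles(sub, geometry, offset, mode))
    }
  )
  engaged <- Reduce(`|`, lapply(sectors, function(s) {
    apply(s$prof, 1L, function(r) any(r > 0))
  }))
  if (!any(engaged)) {
    rlang::abort("Fluence map is all zero; nothing to sequence.",
                 class = "dmlc2d_degenerate_error")
  }

  cursor <- 0
  pieces <- vector("list", nrow(plan))
  for (s in seq_len(nrow(plan))) {
    sec <- sectors[[s]]
    trajs <- lapply(seq_len(npairs), function(p) {
      if (!engaged[p]) return(NULL)
      sequence_pair_profile(sec$prof[p, ], spec$dx, v_mu = v)
    })
    piece <- synchronize_pairs(trajs, xc[sec$cols], geometry, machine,
                               bank_offset = plan$offset[s], mu0 = cursor)
    cursor <- piece$total_mu
    pieces[[s]] <- piece
  }
  new_mlc_sequence(
    mu = unlist(lapply(pieces, `[[`, "mu")),
    offset = unlist(lapply(pieces, `[[`, "offset")),
    left = do.call(rbind, lapply(pieces, `[[`, "left")),
    right = do.call(rbind, lapply(pieces, `[[`, "right")),
    geometry = geometry, machine = machine, plan = plan
  )
}
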