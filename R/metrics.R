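#' Irradiated area of a fluence map
#'
#' Area (mm^2) of cells whose intensity exceeds `tau` times a reference
#' maximum; 10 % of the planned map maximum is the conventional field-edge
#' surrogate.
#'
#' @param grid A [fluence_grid()].
#' @param tau Threshold fraction in (0, 1).
#' @param reference_max Positive reference intensity (usually the planned
#'   map's maximum).
#' @return Area in mm^2.
#' @export
irradiated_area <- function(grid, tau = 0.1, reference_max = max(grid$values)) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (!is.finite(tau) || tau <= 0 || tau >= 1) {
    rlang::abort("`tau` must be in (0, 1).", class = "dmlc2d_argument_error")
  }
  if (!is.finite(reference_max) || reference_max <= 0) {
    rlang::abort("`reference_max` must be positive.", class = "dmlc2d_argument_error")
  }
  sum(grid$values > tau * reference_max) * grid$spec$dx * grid$spec$dy
}

#' Conformity index of an actual fluence map
#'
#' `CI = actual irradiation area / planned irradiation area`, both
#' thresholded at `tau` times the planned map's maximum. A value of 1 is
#' ideal; values above 1 indicate over-coverage outside the planned field.
#'
#' @param actual,planned Co-registered [fluence_grid()]s (same frame).
#' @param tau Threshold fraction.
#' @export
conformity_index <- function(actual, planned, tau = 0.1) {
  check_registered(actual, planned)
  ref <- max(planned$values)
  if (ref <= 0) {
    rlang::abort("Planned map is all zero; conformity index undefined.",
                 class = "dmlc2d_degenerate_error")
  }
  pa <- irradiated_area(planned, tau, ref)
  if (pa <= 0) {
    rlang::abort("Planned irradiation area is zero at this threshold.",
                 class = "dmlc2d_degenerate_error")
  }
  irradiated_area(actual, tau, ref) / pa
}

check_registered <- function(a, b) {
  if (!same_frame(a$spec, b$spec)) {
    rlang::abort("Grids are not co-registered (different frames); replicate rows first.",
                 class = "dmlc2d_argument_error")
  }
  invisible(TRUE)
}

#' Mean intensity over a support
#'
#' Arithmetic mean of the grid values over a support mask (by default the
#' grid's own nonzero cells; technique comparisons use the union of planned
#' and actual nonzero cells, which is symmetric between techniques).
#'
#' @param grid A [fluence_grid()].
#' @param support Logical matrix of the grid's shape, or `NULL` for
#'   `values > 0`.
#' @return Mean intensity in the grid's units; 0 (with a warning) for an
#'   empty support.
#' @export
mean_intensity <- function(grid, support = NULL) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (is.null(support)) support <- grid$values > 0
  if (!any(support)) {
    rlang::warn("Empty support; mean intensity reported as 0.")
    return(0)
  }
  mean(grid$values[support])
}

#' Mean absolute difference between actual and planned fluence, in percent
#'
#' `100 * mean(|actual - planned|)` over the union of the two nonzero
#' supports, divided by the mean planned intensity over the planned support.
#'
#' @inheritParams conformity_index
#' @export
mean_abs_diff_pct <- function(actual, planned) {
  check_registered(actual, planned)
  psup <- planned$values > 0
  if (!any(psup)) {
    rlang::abort("Planned map has zero mean; cannot normalize.",
                 class = "dmlc2d_degenerate_error")
  }
  union_sup <- psup | actual$values > 0
  100 * mean(abs(actual$values - planned$values)[union_sup]) /
    mean(planned$values[psup])
}

#' Irradiated area outside the planned field
#'
#' Area of cells exposed above threshold whose planned fluence is at or
#' below threshold - the unwanted irradiation the bank translation is meant
#' to remove.
#'
#' @inheritParams conformity_index
#' @export
out_of_field_area <- function(actual, planned, tau = 0.1) {
  check_registered(actual, planned)
  ref <- max(planned$values)
  thr <- tau * ref
  sum(actual$values > thr & planned$values <= thr) *
    actual$spec$dx * actual$spec$dy
}

#' Paired two-sided t-test
#'
#' Standard paired t-test with the degenerate branches made explicit: all
#' differences exactly zero gives `(t = 0, p = 1)`; a constant nonzero
#' difference gives `(t = +/-Inf, p = 0)`.
#'
#' @param a,b Equal-length numeric vectors, n >= 2.
#' @return One-row tibble with `statistic`, `p.value`, `df`, `estimate`
#'   (mean difference a - b) and `method`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    rlang::abort("`a` and `b` must have equal length >= 2.",
                 class = "dmlc2d_argument_error")
  }
  d <- a - b
  scale <- max(abs(d), 1)
  if (stats::sd(d) < 1e-12 * scale) {
    if (abs(mean(d)) < 1e-12 * scale) {
      rlang::inform("All paired differences are zero; p = 1.",
                    .frequency = "once", .frequency_id = "dmlc2d_t_zero")
      stat <- 0; p <- 1
    } else {
      rlang::inform("Constant nonzero paired difference; p = 0.",
                    .frequency = "once", .frequency_id = "dmlc2d_t_const")
      stat <- sign(mean(d)) * Inf; p <- 0
    }
    return(tibble::tibble(statistic = stat, p.value = p,
                          df = length(d) - 1, estimate = mean(d),
                          method = "paired t-test (degenerate)"))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 df = unname(ht$parameter), estimate = unname(ht$estimate),
                 method = "paired t-test")
}

#' Compare conventional and 2DDMLC delivery of one fluence map
#'
#' Runs the full pipeline twice on one optimal fluence map: once with the
#' bank held at zero offset (conventional, leaf travel only) and once with
#' the per-sector bank offsets chosen by [optimize_sectors()] (the 2DDMLC
#' technique). Both arms are sequenced with [sequence_field()] and
#' reconstructed with [reconstruct_fluence()] on a fine
#' (`candidate_step` in y) delivery grid, and evaluated with the conformity
#' index, mean intensity over the union support, mean absolute difference
#' and out-of-field area.
#'
#' @param fluence A [fluence_grid()]; relative maps are scaled to
#'   `machine$total_mu` first.
#' @param geometry An [mlc_geometry()].
#' @param machine A [machine_config()].
#' @param n_sectors Number of bank-offset sectors (default 8).
#' @param candidate_step Offset search step and fine-grid y resolution (mm).
#' @param tau Irradiation threshold fraction (default 0.1).
#' @param mode Aggregation mode, see [aggregate_pair_profiles()].
#' @return An object of class `mlc_comparison`; use [generics::tidy()] for
#'   the one-row metric table, `glance()` for the headline numbers, and
#'   `autoplot()` for a planned/conventional/2DDMLC panel.
#' @export
compare_techniques <- function(fluence, geometry = millennium_120(),
                               machine = machine_config(), n_sectors = 8,
                               candidate_step = 0.25, tau = 0.1,
                               mode = c("max", "coverage_weighted_mean")) {
  mode <- match.arg(mode)
  if (fluence$units == "relative") {
    fluence <- scale_to_mu(fluence, machine$total_mu)
  }
  fine <- delivery_grid_spec(fluence$spec, candidate_step)
  planned_fine <- upsample_rows(fluence, round(fluence$spec$dy / candidate_step))

  plan_conv <- zero_sector_plan(fluence, n_sectors)
  seq_conv <- sequence_field(fluence, geometry, machine, plan_conv, mode)
  actual_conv <- reconstruct_fluence(seq_conv, geometry, fine)

  plan_2d <- optimize_sectors(fluence, geometry, machine, n_sectors,
                              candidate_step, mode)
  seq_2d <- sequence_field(fluence, geometry, machine, plan_2d, mode)
  actual_2d <- reconstruct_fluence(seq_2d, geometry, fine)

  psup <- planned_fine$values > 0
  oof_c <- out_of_field_area(actual_conv, planned_fine, tau)
  oof_o <- out_of_field_area(actual_2d, planned_fine, tau)
  report <- tibble::tibble(
    ci_conventional = conformity_index(actual_conv, planned_fine, tau),
    ci_2ddmlc = conformity_index(actual_2d, planned_fine, tau),
    mean_intensity_conventional =
      mean_intensity(actual_conv, psup | actual_conv$values > 0),
    mean_intensity_2ddmlc =
      mean_intensity(actual_2d, psup | actual_2d$values > 0),
    mad_pct_conventional = mean_abs_diff_pct(actual_conv, planned_fine),
    mad_pct_2ddmlc = mean_abs_diff_pct(actual_2d, planned_fine),
    oof_area_conventional = oof_c,
    oof_area_2ddmlc = oof_o,
    oof_reduction_pct = if (oof_c > 0) 100 * (oof_c - oof_o) / oof_c else NA_real_,
    threshold_tau = tau
  )
  if (oof_c <= 0) {
    rlang::inform("Conventional out-of-field area is 0; reduction undefined (reported NA).",
                  .frequency = "once", .frequency_id = "dmlc2d_oof_zero")
  }
  structure(
    list(report = report, plan = plan_2d, planned = planned_fine,
         actual_conventional = actual_conv, actual_2ddmlc = actual_2d,
         tau = tau, mode = mode, n_sectors = n_sectors,
         candidate_step = candidate_step),
    class = "mlc_comparison"
  )
}

#' @export
print.mlc_comparison <- function(x, ...) {
  cat("<mlc_comparison> conventional vs 2DDMLC delivery\n")
  print(x$report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mlc_comparison
#' @export
tidy.mlc_comparison <- function(x, ...) x$report

#' @method glance mlc_comparison
#' @export
glance.mlc_comparison <- function(x, ...) {
  dplyr::select(x$report, "ci_conventional", "ci_2ddmlc",
                "oof_reduction_pct", "threshold_tau")
}

#' @method autoplot mlc_comparison
#' @export
autoplot.mlc_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$planned), panel = "optimal"),
    dplyr::mutate(as_tibble(object$actual_conventional), panel = "conventional"),
    dplyr::mutate(as_tibble(object$actual_2ddmlc), panel = "2DDMLC")
  )
  df$panel <- factor(df$panel, levels = c("optimal", "conventional", "2DDMLC"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::scale_fill_viridis_c(name = "MU") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]")
}

#' Compare techniques over a suite of fluence maps
#'
#' Maps [compare_techniques()] over a list of fluence maps and collects the
#' per-case reports; `glance()` on the result gives suite means and paired
#' t-test p-values per metric, mirroring a per-site summary table.
#'
#' @param fluences List of [fluence_grid()]s, or the result of
#'   [generate_suite()].
#' @inheritParams compare_techniques
#' @return An object of class `mlc_suite_comparison`; `tidy()` returns the
#'   per-case table, `glance()` the suite summary.
#' @export
compare_suite <- function(fluences, geometry = millennium_120(),
                          machine = machine_config(), n_sectors = 8,
                          candidate_step = 0.25, tau = 0.1,
                          mode = c("max", "coverage_weighted_mean")) {
  mode <- match.arg(mode)
  if (is.list(fluences) && !is.null(fluences$grids)) fluences <- fluences$grids
  rows <- purrr::imap(fluences, function(g, i) {
    rep <- compare_techniques(g, geometry, machine, n_sectors,
                              candidate_step, tau, mode)$report
    dplyr::mutate(rep, case = i, .before = 1)
  })
  structure(list(cases = dplyr::bind_rows(rows), tau = tau, mode = mode),
            class = "mlc_suite_comparison")
}

#' @method tidy mlc_suite_comparison
#' @export
tidy.mlc_suite_comparison <- function(x, ...) x$cases

#' @method glance mlc_suite_comparison
#' @export
glance.mlc_suite_comparison <- function(x, ...) {
  cc <- x$cases
  mi_rel <- abs(cc$mean_intensity_conventional - cc$mean_intensity_2ddmlc) /
    cc$mean_intensity_conventional
  tibble::tibble(
    n = nrow(cc),
    ci_conventional_mean = mean(cc$ci_conventional),
    ci_conventional_sd = stats::sd(cc$ci_conventional),
    ci_2ddmlc_mean = mean(cc$ci_2ddmlc),
    ci_2ddmlc_sd = stats::sd(cc$ci_2ddmlc),
    ci_p = paired_t_test(cc$ci_conventional, cc$ci_2ddmlc)$p.value,
    mad_pct_conventional_mean = mean(cc$mad_pct_conventional),
    mad_pct_2ddmlc_mean = mean(cc$mad_pct_2ddmlc),
    mad_p = paired_t_test(cc$mad_pct_conventional, cc$mad_pct_2ddmlc)$p.value,
    mean_intensity_max_rel_diff = max(mi_rel),
    oof_reduction_pct_mean = mean(cc$oof_reduction_pct, na.rm = TRUE)
  )
}

#' @export
print.mlc_suite_comparison <- function(x, ...) {
  cat(sprintf("<mlc_suite_comparison> %d cases\n", nrow(x$cases)))
  print(glance(x))
  invisible(x)
}

#' Write a suite comparison as per-case CSV plus a summary row
#'
#' @param suite An `mlc_suite_comparison`.
#' @param cases_path,summary_path Output CSV paths.
#' @export
write_suite_csv <- function(suite, cases_path, summary_path = NULL) {
  utils::write.csv(tidy(suite), cases_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(glance(suite), summary_path, row.names = FALSE)
  }
  invisible(suite)
}
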