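#' Write an MLC sequence as a control-point table
#'
#' Tab-separated table with one row per control point (`mu`, `bank_offset`,
#' then the left and right leaf positions of every pair), plus a JSON
#' sidecar (`<path>.json`) carrying the geometry, machine configuration and
#' sector plan so the sequence can be reloaded losslessly.
#'
#' @param sequence An `mlc_sequence`.
#' @param path Output path for the TSV; the sidecar is written next to it.
#' @export
write_sequence <- function(sequence, path) {
  stopifnot(inherits(sequence, "mlc_sequence"))
  npairs <- ncol(sequence$left)
  tab <- data.frame(
    mu = sequence$mu,
    bank_offset = sequence$offset,
    sequence$left, sequence$right,
    check.names = FALSE
  )
  names(tab) <- c("mu", "bank_offset",
                  paste0("left_", seq_len(npairs)),
                  paste0("right_", seq_len(npairs)))
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- sequence$geometry
  m <- sequence$machine
  meta <- list(
    total_mu = sequence$total_mu,
    geometry = list(pair_widths = g$pair_widths, y_min = g$y_min,
                    x_travel_min = g$x_travel_min, x_travel_max = g$x_travel_max),
    machine = list(dose_rate = m$dose_rate, max_leaf_speed = m$max_leaf_speed,
                   total_mu = m$total_mu)
  )
  if (!is.null(sequence$plan)) {
    meta$plan <- list(
      sector_edges = c(sequence$plan$x_min, sequence$plan$x_max[nrow(sequence$plan)]),
      offsets = sequence$plan$offset
    )
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(sequence)
}

#' Read an MLC sequence written by [write_sequence()]
#'
#' @param path Path to the TSV control-point table (sidecar expected at
#'   `<path>.json`).
#' @return An `mlc_sequence`.
#' @export
read_sequence <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- meta$geometry
  geometry <- mlc_geometry(g$pair_widths, g$y_min, g$x_travel_min, g$x_travel_max)
  m <- meta$machine
  machine <- machine_config(m$dose_rate, m$max_leaf_speed, m$total_mu)
  npairs <- length(g$pair_widths)
  plan <- if (!is.null(meta$plan)) {
    sector_plan(meta$plan$sector_edges, meta$plan$offsets)
  }
  new_mlc_sequence(
    mu = tab$mu, offset = tab$bank_offset,
    left = as.matrix(tab[, paste0("left_", seq_len(npairs))]),
    right = as.matrix(tab[, paste0("right_", seq_len(npairs))]),
    geometry = geometry, machine = machine, plan = plan
  )
}
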