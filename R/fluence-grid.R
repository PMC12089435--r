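#' Beamlet grid specification
#'
#' Describes the spatial frame of a fluence map at the isocenter plane.
#' Cell `(i, j)` (0-based, `i` along leaf travel in x, `j` along the bank
#' translation axis y) covers the half-open rectangle
#' `[x0 + i*dx, x0 + (i+1)*dx) x [y0 + j*dy, y0 + (j+1)*dy)`.
#'
#' @param x0,y0 Position of the lower-left grid corner, in mm at isocenter.
#' @param dx,dy Beamlet width (x, leaf travel) and height (y), in mm. The
#'   conventional planning resolution is 1 mm.
#' @param nx,ny Number of beamlets along x and y.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(nx = 40, ny = 30)
grid_spec <- function(x0 = 0, y0 = 0, dx = 1, dy = 1, nx, ny) {
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0) {
    rlang::abort("`dx` and `dy` must be positive and finite.", class = "dmlc2d_spec_error")
  }
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L) {
    rlang::abort("`nx` and `ny` must be at least 1.", class = "dmlc2d_spec_error")
  }
  structure(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0),
         dx = as.numeric(dx), dy = as.numeric(dy), nx = nx, ny = ny),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d beamlets of %g x %g mm, x in [%g, %g), y in [%g, %g) mm\n",
    x$nx, x$ny, x$dx, x$dy, x$x0, x$x0 + x$nx * x$dx, x$y0, x$y0 + x$ny * x$dy
  ))
  invisible(x)
}

# cell-center coordinate helpers (mm)
x_centers <- function(spec) spec$x0 + (seq_len(spec$nx) - 0.5) * spec$dx
y_centers <- function(spec) spec$y0 + (seq_len(spec$ny) - 0.5) * spec$dy

same_frame <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol
}

#' Two-dimensional fluence map
#'
#' A fluence map is a non-negative intensity on a beamlet grid: either the
#' optimal fluence prescribed by the treatment planning system (usually in
#' relative units) or the actual fluence deliverable by an MLC sequence (in
#' monitor units, MU).
#'
#' @param values Numeric matrix with `ny` rows and `nx` columns; row 1 is the
#'   lowest y row. All values must be finite and non-negative.
#' @param spec A [grid_spec()].
#' @param units `"relative"` or `"MU"`.
#' @return An object of class `fluence_grid`.
#' @export
fluence_grid <- function(values, spec, units = c("relative", "MU")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (!inherits(spec, "grid_spec")) {
    rlang::abort("`spec` must be a grid_spec.", class = "dmlc2d_spec_error")
  }
  if (nrow(values) != spec$ny || ncol(values) != spec$nx) {
    rlang::abort(
      sprintf("`values` must be %d x %d (ny x nx); got %d x %d.",
              spec$ny, spec$nx, nrow(values), ncol(values)),
      class = "dmlc2d_dim_error"
    )
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    j <- ((bad[1] - 1) %% nrow(values))      # 0-based row
    i <- ((bad[1] - 1) %/% nrow(values))     # 0-based col
    rlang::abort(
      sprintf("Fluence values must be finite and >= 0; first offending cell (i = %d, j = %d) has value %g.",
              i, j, values[bad[1]]),
      class = "dmlc2d_value_error"
    )
  }
  dimnames(values) <- NULL
  structure(list(values = values, spec = spec, units = units),
            class = "fluence_grid")
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat(sprintf("<fluence_grid> [%s] max %g, total %g mm^2*value\n",
              x$units, max(x$values), sum(x$values) * x$spec$dx * x$spec$dy))
  print(x$spec)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble fluence_grid
#' @export
as_tibble.fluence_grid <- function(x, ...) {
  xs <- rep(x_centers(x$spec), each = x$spec$ny)
  ys <- rep(y_centers(x$spec), times = x$spec$nx)
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vals)
}

fluence_header_fields <- c("x0", "y0", "dx", "dy", "nx", "ny", "units")

#' Read a fluence map from the plain-text grid format
#'
#' The format is a self-describing ASCII dialect: header lines `key value`
#' for `x0 y0 dx dy nx ny units`, then `ny` data rows of `nx` whitespace- or
#' comma-separated numbers, bottom row (lowest y) first. Lines starting with
#' `#` are comments. On read, intensities below `1e-9` of the map maximum are
#' clamped to zero so numerical dust never reaches the sequencer.
#'
#' @param source File path or connection.
#' @return A [fluence_grid()].
#' @export
read_fluence <- function(source) {
  lines <- readLines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    rlang::abort("Empty fluence stream: no header found.", class = "dmlc2d_parse_error")
  }
  header <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(lines[[i]], "[[:space:]=]+")[[1]]
    if (length(parts) == 2L && parts[1] %in% fluence_header_fields) {
      header[[parts[1]]] <- parts[2]
      i <- i + 1L
    } else {
      break
    }
  }
  missing_fields <- setdiff(fluence_header_fields, names(header))
  if (length(missing_fields)) {
    rlang::abort(
      sprintf("Malformed fluence header: missing field(s) %s.",
              paste(missing_fields, collapse = ", ")),
      class = "dmlc2d_parse_error"
    )
  }
  spec <- grid_spec(
    x0 = as.numeric(header$x0), y0 = as.numeric(header$y0),
    dx = as.numeric(header$dx), dy = as.numeric(header$dy),
    nx = as.integer(header$nx), ny = as.integer(header$ny)
  )
  rows <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(rows) != spec$ny) {
    rlang::abort(
      sprintf("Expected %d data rows, found %d.", spec$ny, length(rows)),
      class = "dmlc2d_dim_error"
    )
  }
  parse_row <- function(r) as.numeric(strsplit(trimws(gsub(",", " ", r)), "[[:space:]]+")[[1]])
  vals <- lapply(rows, parse_row)
  nvals <- lengths(vals)
  if (any(nvals != spec$nx)) {
    bad <- which(nvals != spec$nx)[1]
    rlang::abort(
      sprintf("Data row %d has %d values; expected nx = %d.", bad, nvals[bad], spec$nx),
      class = "dmlc2d_dim_error"
    )
  }
  m <- do.call(rbind, vals)
  if (anyNA(m)) {
    rlang::abort("Non-numeric value in fluence data.", class = "dmlc2d_parse_error")
  }
  g <- fluence_grid(m, spec, units = header$units)
  # clamp numerical dust
  top <- max(g$values)
  if (top > 0) {
    g$values[g$values < 1e-9 * top] <- 0
  }
  g
}

#' Write a fluence map in the plain-text grid format
#'
#' Emits the exact dialect [read_fluence()] accepts. Values are printed with
#' full precision (17 significant digits) so a write/read round trip is
#' lossless.
#'
#' @param grid A [fluence_grid()].
#' @param sink File path or connection.
#' @return `grid`, invisibly.
#' @export
write_fluence <- function(grid, sink) {
  stopifnot(inherits(grid, "fluence_grid"))
  s <- grid$spec
  header <- c(
    "# dmlc2d fluence grid",
    sprintf("x0 %.17g", s$x0), sprintf("y0 %.17g", s$y0),
    sprintf("dx %.17g", s$dx), sprintf("dy %.17g", s$dy),
    sprintf("nx %d", s$nx), sprintf("ny %d", s$ny),
    sprintf("units %s", grid$units)
  )
  body <- apply(grid$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, body), sink)
  invisible(grid)
}

#' Export a fluence map as CSV
#'
#' Long-format CSV (`x`, `y`, `value` columns) for spreadsheet inspection;
#' [write_fluence()] remains the canonical round-trip format.
#'
#' @inheritParams write_fluence
#' @export
write_fluence_csv <- function(grid, sink) {
  utils::write.csv(as_tibble(grid), sink, row.names = FALSE)
  invisible(grid)
}

#' Replicate fluence rows onto a finer y grid
#'
#' Each row is replicated `factor` times and `dy` divided by `factor`; cell
#' values are unchanged, so the integrated fluence (value times cell area) is
#' conserved exactly. Needed because bank offsets move in 0.25 mm steps while
#' planning grids are typically 1 mm.
#'
#' @param grid A [fluence_grid()].
#' @param factor Positive integer replication factor.
#' @export
upsample_rows <- function(grid, factor) {
  stopifnot(inherits(grid, "fluence_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    rlang::abort("`factor` must be a positive integer.", class = "dmlc2d_argument_error")
  }
  if (factor == 1L) return(grid)
  s <- grid$spec
  spec2 <- grid_spec(s$x0, s$y0, s$dx, s$dy / factor, s$nx, s$ny * factor)
  fluence_grid(grid$values[rep(seq_len(s$ny), each = factor), , drop = FALSE],
               spec2, units = grid$units)
}

#' Convert a relative fluence map to monitor units
#'
#' Scales intensities so the map maximum equals `total_mu`; the MU value of a
#' beamlet is the beam-on time (at fixed dose rate) during which it must be
#' exposed.
#'
#' @param grid A relative-units [fluence_grid()] with a positive maximum.
#' @param total_mu Total monitor units assigned to the map maximum.
#' @export
scale_to_mu <- function(grid, total_mu) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (grid$units != "relative") {
    rlang::abort("`grid` is already in MU units.", class = "dmlc2d_argument_error")
  }
  top <- max(grid$values)
  if (top <= 0) {
    rlang::abort("Cannot scale an all-zero fluence map to MU.",
                 class = "dmlc2d_degenerate_error")
  }
  if (!is.finite(total_mu) || total_mu <= 0) {
    rlang::abort("`total_mu` must be positive.", class = "dmlc2d_argument_error")
  }
  fluence_grid(grid$values * (total_mu / top), grid$spec, units = "MU")
}

#' Shift a fluence map rigidly along y
#'
#' Adds `delta` to the grid origin `y0`; the values are untouched.
#'
#' @param grid A [fluence_grid()].
#' @param delta Shift in mm.
#' @export
shift_y <- function(grid, delta) {
  stopifnot(inherits(grid, "fluence_grid"))
  s <- grid$spec
  fluence_grid(grid$values, grid_spec(s$x0, s$y0 + delta, s$dx, s$dy, s$nx, s$ny),
               units = grid$units)
}

#' Heatmap of a fluence map
#'
#' @param object A [fluence_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot fluence_grid
#' @export
autoplot.fluence_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (leaf travel) [mm]", y = "y (bank axis) [mm]")
}
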