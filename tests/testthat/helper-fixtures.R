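# shared test helpers: tiny geometries and deterministic random grids

toy_geometry <- function(npairs = 12, width = 5, y_min = -30) {
  mlc_geometry(rep(width, npairs), y_min = y_min,
               x_travel_min = -100, x_travel_max = 100)
}

# unconstrained-speed machine stand-in for hand examples: use v_mu = Inf
fast_machine <- function(total_mu = 100) {
  machine_config(dose_rate = 600, max_leaf_speed = 25, total_mu = total_mu)
}

random_grid <- function(seed, nx = 8, ny = 6, dx = 1, dy = 1,
                        units = "relative", max_val = 1) {
  withr::with_seed(seed, {
    vals <- matrix(stats::runif(nx * ny, 0.01, max_val), nrow = ny)
    fluence_grid(vals, grid_spec(0, 0, dx, dy, nx, ny), units = units)
  })
}

# uniform rectangle on a 0.5 mm y grid with its support exactly on
# [x_lo, x_hi) x [y_lo, y_hi); edges must be multiples of 0.5
rect_grid <- function(x_lo, x_hi, y_lo, y_hi, nx = 40, ny = 60,
                      dy = 0.5, value = 1, units = "relative") {
  spec <- grid_spec(0, 0, 1, dy, nx, ny)
  vals <- matrix(0, ny, nx)
  xc <- 0 + (seq_len(nx) - 0.5)
  yc <- (seq_len(ny) - 0.5) * dy
  vals[yc >= y_lo & yc < y_hi, xc >= x_lo & xc < x_hi] <- value
  fluence_grid(vals, spec, units = units)
}

# delivered-vs-trajectory gap at each beamlet
trajectory_gap <- function(tr) tr$arrival_left - tr$arrival_right
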