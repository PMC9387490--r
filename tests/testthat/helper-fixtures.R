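# Shared fixtures: a memoised calibrated curve (calibration is the one
# expensive pure computation) and small world builders.

get_calibrated_tr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_thermal_response()
    cache
  }
})

# Independent Euler integrator for the growth ODE: logistic when r > 0,
# plain exponential decline otherwise (density dependence only applies to
# growing populations).
euler_growth <- function(N, r, K, dt, h = 0.001) {
  steps <- round(dt / h)
  for (i in seq_len(steps)) {
    dN <- if (r > 0) r * N * (1 - N / K) else r * N
    N <- N + h * dN
  }
  N
}

# A constant-climate grid built directly (no generator), for oracles that
# need exact control of every timestep.
constant_climate <- function(temp, wilting = 0, rows = 3, cols = 3,
                             times = seq(as.POSIXct("2019-01-01", tz = "UTC"),
                                         by = 3 * 3600, length.out = 8)) {
  climate_grid(
    array(temp, c(rows, cols, length(times))),
    array(wilting, c(rows, cols, length(times))),
    times,
    grid_geometry(x0 = 0, y0 = rows * 9, cell_size = 9)
  )
}
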