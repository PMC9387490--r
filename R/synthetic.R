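# Synthetic climate forcing: self-contained fixtures with the statistical
# structure the model consumes (latitudinal gradient, seasonal sinusoid,
# diurnal cycle, aridity field), so every mechanism is exercisable without
# satellite data.

#' Specification of a synthetic climate world
#'
#' Temperature at a cell and instant is
#' `t_base - lapse * (row - 1) + seasonal_amp * sin(2 pi (doy - seasonal_phase) / 365)
#'  + diurnal_amp * sin(2 pi hour / 24) + noise`,
#' and the wilting fraction analogously (with its own base, per-row
#' gradient, amplitude and phase), clipped to \[0, 1\]. Row 1 is the
#' northernmost and, by default, warmest row (a southern-hemisphere-like
#' world). A 365-day calendar is used for the seasonal term; no leap-day
#' handling.
#'
#' @param rows,cols Grid dimensions.
#' @param cell_size Cell size (km).
#' @param t_base Mean temperature at row 1 (degC).
#' @param lapse Temperature drop per row southward (degC/row).
#' @param seasonal_amp,seasonal_phase Seasonal sinusoid amplitude (degC) and
#'   phase (day of year at which the sinusoid crosses zero rising).
#' @param diurnal_amp Diurnal sinusoid amplitude (degC).
#' @param wilting_base,wilting_gradient Wilting-fraction base at row 1 and
#'   per-row change.
#' @param wilting_amp,wilting_phase Seasonal wilting sinusoid amplitude and
#'   phase (day of year).
#' @param timestep_hours Forcing timestep (hours; default 3).
#' @param start,end Date range (inclusive), coercible to Date.
#' @param noise_sd Gaussian noise s.d. applied to temperature (degC).
#' @param seed RNG seed for the noise; generation is deterministic given
#'   the seed.
#' @return A `synthetic_world_spec` list.
#' @export
synthetic_world_spec <- function(rows = 60, cols = 60, cell_size = 9,
                                 t_base = 27, lapse = 0,
                                 seasonal_amp = 0, seasonal_phase = 0,
                                 diurnal_amp = 0,
                                 wilting_base = 0, wilting_gradient = 0,
                                 wilting_amp = 0, wilting_phase = 0,
                                 timestep_hours = 3,
                                 start = "2019-01-01", end = "2019-12-31",
                                 noise_sd = 0, seed = 1) {
  stopifnot(rows >= 1, cols >= 1, timestep_hours > 0, noise_sd >= 0)
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("synthetic_world_spec: end must be after start")
  structure(as.list(environment()), class = "synthetic_world_spec")
}

# Run code with a private RNG stream, restoring the global state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic climate grid
#'
#' @param spec A [synthetic_world_spec()].
#' @return A [climate_grid()].
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  time <- seq(as.POSIXct(paste(spec$start, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(spec$end, "21:00:00"), tz = "UTC"),
              by = spec$timestep_hours * 3600)
  nt <- length(time)
  doy <- lubridate::yday(time)
  hour <- lubridate::hour(time) + lubridate::minute(time) / 60
  n_cells <- spec$rows * spec$cols

  row_term <- spec$t_base - spec$lapse * (seq_len(spec$rows) - 1)
  time_term <- spec$seasonal_amp * sin(2 * pi * (doy - spec$seasonal_phase) / 365) +
    spec$diurnal_amp * sin(2 * pi * hour / 24)
  temp <- array(row_term, c(spec$rows, spec$cols, nt)) +
    array(rep(time_term, each = n_cells), c(spec$rows, spec$cols, nt))
  if (spec$noise_sd > 0) {
    temp <- temp + with_seed(spec$seed,
      array(stats::rnorm(n_cells * nt, sd = spec$noise_sd),
            c(spec$rows, spec$cols, nt)))
  }

  w_row <- spec$wilting_base + spec$wilting_gradient * (seq_len(spec$rows) - 1)
  w_time <- spec$wilting_amp * sin(2 * pi * (doy - spec$wilting_phase) / 365)
  wilting <- array(w_row, c(spec$rows, spec$cols, nt)) +
    array(rep(w_time, each = n_cells), c(spec$rows, spec$cols, nt))
  wilting <- pmin(pmax(wilting, 0), 1)  # argument order keeps the dim attribute

  climate_grid(temp, wilting, time,
               grid_geometry(x0 = 0, y0 = spec$rows * spec$cell_size,
                             cell_size = spec$cell_size))
}

#' Packaged gradient-world scenarios
#'
#' Three self-contained worlds exercising the model's mechanisms:
#' \describe{
#'   \item{`benign_uniform`}{27 degC everywhere, wet, no variability: every
#'     cell grows at exactly `r_ref`; the control world.}
#'   \item{`tropics_to_temperate`}{north-south gradient from a permanently
#'     suitable tropical edge (30 degC mean) to a winter-lethal temperate
#'     edge (8 degC mean), southern-hemisphere seasonal phase (warm
#'     January), 7 degC seasonal and 4 degC diurnal amplitude.}
#'   \item{`arid_pulse`}{uniform cool 16 degC with a dry season whose
#'     wilting fraction (base 0.3, amplitude 0.5, peak mid-July) crosses
#'     the 0.5 desiccation threshold, flipping the net rate negative in the
#'     dry months.}
#' }
#' Each scenario ships with a founder population (1e6 individuals, well
#' above the Allee threshold) seeded in its suitable zone.
#'
#' @param preset One of `"benign_uniform"`, `"tropics_to_temperate"`,
#'   `"arid_pulse"`.
#' @param rows,cols Grid dimensions (defaults 40 x 20).
#' @param start,end Date range.
#' @param seed RNG seed passed to the world specification.
#' @return A list with elements `climate` (a [climate_grid()]),
#'   `population` (a [population_grid()]), and `spec`.
#' @export
make_gradient_world <- function(preset = c("tropics_to_temperate",
                                           "arid_pulse", "benign_uniform"),
                                rows = 40, cols = 20,
                                start = "2019-01-01", end = "2019-12-31",
                                seed = 1) {
  presets <- c("tropics_to_temperate", "arid_pulse", "benign_uniform")
  if (!is.character(preset) || !preset[1] %in% presets) {
    stop("make_gradient_world: unknown preset; available: ",
         paste(presets, collapse = ", "))
  }
  preset <- match.arg(preset)
  spec <- switch(preset,
    benign_uniform = synthetic_world_spec(
      rows = rows, cols = cols, t_base = 27,
      start = start, end = end, seed = seed),
    tropics_to_temperate = synthetic_world_spec(
      rows = rows, cols = cols, t_base = 30,
      lapse = (30 - 8) / max(rows - 1, 1),
      seasonal_amp = 7, seasonal_phase = 15 - 365 / 4,  # warmest mid-January
      diurnal_amp = 4, wilting_base = 0.05,
      start = start, end = end, seed = seed),
    arid_pulse = synthetic_world_spec(
      rows = rows, cols = cols, t_base = 16,
      wilting_base = 0.3, wilting_amp = 0.5,
      wilting_phase = 196 - 365 / 4,                    # driest mid-July
      start = start, end = end, seed = seed)
  )
  climate <- generate_climate(spec)
  abundance <- matrix(0, rows, cols)
  seed_row <- if (preset == "tropics_to_temperate") 2 else ceiling(rows / 2)
  abundance[seed_row, ceiling(cols / 2)] <- 1e6
  list(climate = climate,
       population = population_grid(abundance, cell_size = spec$cell_size),
       spec = spec)
}
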