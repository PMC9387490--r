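# Weekly-timestep simulation engine: growth -> short-range dispersal ->
# long-range jumps -> Allee extinction, with replicates and mass accounting.

#' Configure a spread simulation
#'
#' Couples monthly growth-rate rasters (or raw climate forcing, from which
#' they are derived) with dispersal and demographic parameters, an initial
#' population, and replicate/seed settings. Each weekly step uses the mean
#' daily rate of the calendar month containing the week's start.
#'
#' @param rates A `faw_rates` object from [monthly_rate_raster()], or
#'   `NULL` to derive it from `climate`.
#' @param climate Optional [climate_grid()] (used when `rates` is `NULL`).
#' @param init Data frame of founder cells with columns `row`, `col`,
#'   `abundance`.
#' @param start,end Simulation date range (coercible to Date); defaults to
#'   the span of the rate raster's months.
#' @param dt Timestep in days (default 7).
#' @param replicates Number of replicate runs (default 1).
#' @param seed Master RNG seed; replicate `k` uses a seed derived
#'   deterministically from it, so any replicate is reproducible in
#'   isolation.
#' @param thermal,stress Parameter objects used when deriving rates from
#'   climate.
#' @param kernel A [dispersal_kernel()] (set `p_disperse = 0` to disable
#'   short-range dispersal).
#' @param jumps A [long_jump_params()] (set `beta = 0` to disable jumps).
#' @param K,theta,cell_size Population grid metadata (see
#'   [population_grid()]).
#' @param land_mask Logical matrix; defaults to cells with non-missing
#'   rates.
#' @param regions Data frame with columns `region`, `row`, `col` defining
#'   reporting regions; defaults to a single region `"global"` covering
#'   all land.
#' @param snapshot_every Store a population snapshot (replicate 1 only)
#'   every this many steps; `NA` disables snapshots. Default 4 (~monthly).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(rates = NULL, climate = NULL, init,
                              start = NULL, end = NULL, dt = 7,
                              replicates = 1, seed = 1,
                              thermal = thermal_response(),
                              stress = stress_params(),
                              kernel = dispersal_kernel(),
                              jumps = long_jump_params(),
                              K = 1e9, theta = 1e4, cell_size = 9,
                              land_mask = NULL, regions = NULL,
                              snapshot_every = 4) {
  if (is.null(rates)) {
    if (is.null(climate)) {
      stop("simulation_config: provide either rates or climate")
    }
    rates <- monthly_rate_raster(climate, thermal, stress)
  }
  stopifnot(inherits(rates, "faw_rates"),
            inherits(kernel, "dispersal_kernel"),
            inherits(jumps, "long_jump_params"),
            replicates >= 1, dt > 0)
  d <- dim(rates$rates)
  if (is.null(land_mask)) land_mask <- !is.na(rates$rates[, , 1])
  stopifnot(all(dim(land_mask) == d[1:2]))
  stopifnot(is.data.frame(init), all(c("row", "col", "abundance") %in% names(init)))
  if (any(init$row < 1 | init$row > d[1] | init$col < 1 | init$col > d[2])) {
    stop("simulation_config: init cells outside the grid")
  }
  if (is.null(start)) start <- min(rates$months)
  if (is.null(end)) end <- lubridate::ceiling_date(max(rates$months), "month") - 1
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("simulation_config: end must be after start")
  if (is.null(regions)) {
    land_idx <- which(land_mask, arr.ind = TRUE)
    regions <- tibble::tibble(region = "global",
                              row = land_idx[, 1], col = land_idx[, 2])
  }
  stopifnot(all(c("region", "row", "col") %in% names(regions)))
  for (rg in unique(regions$region)) {
    sub <- regions[regions$region == rg, ]
    if (nrow(sub) == 0 ||
        any(sub$row < 1 | sub$row > d[1] | sub$col < 1 | sub$col > d[2])) {
      stop("simulation_config: region '", rg, "' is empty or outside the grid")
    }
  }
  structure(list(rates = rates, init = tibble::as_tibble(init),
                 start = start, end = end, dt = dt,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 kernel = kernel, jumps = jumps,
                 K = K, theta = theta, cell_size = cell_size,
                 land_mask = land_mask,
                 regions = tibble::as_tibble(regions),
                 snapshot_every = snapshot_every),
            class = "simulation_config")
}

# Deterministic per-replicate seed from the master seed (counter-based,
# kept below 2^31).
replicate_seed <- function(master, k) {
  as.integer((as.numeric(master) + 104729 * as.numeric(k)) %% 2147483647)
}

#' One weekly simulation step
#'
#' Applies, in order: logistic growth (`dt` days at the cell's monthly mean
#' rate), short-range kernel dispersal, long-range jumps, then the Allee
#' extinction check. The order is a declared convention; only the Allee
#' check's position (end of step) is biologically fixed.
#'
#' @param grid A [population_grid()].
#' @param rate_matrix Per-cell net daily rates for the step's month.
#' @param kernel A [dispersal_kernel()].
#' @param jumps A [long_jump_params()].
#' @param destinations Optional precomputed [jump_destination_table()].
#' @param dt Step length (days).
#' @return A list with `grid` (updated) and `accounting` (one-row tibble:
#'   mass before/after, growth delta, dispersal and Allee losses, and the
#'   accounting residual).
#' @export
step_population <- function(grid, rate_matrix, kernel, jumps,
                            destinations = NULL, dt = 7) {
  stopifnot(inherits(grid, "population_grid"),
            all(dim(rate_matrix) == dim(grid$abundance)))
  before <- sum(grid$abundance)
  grid$abundance <- logistic_step(grid$abundance, rate_matrix, grid$K, dt)
  growth_delta <- sum(grid$abundance) - before
  sd_res <- apply_short_dispersal(grid, kernel)
  grid <- sd_res$grid
  lj_res <- apply_long_jumps(grid, jumps, destinations)
  grid <- lj_res$grid
  pre_allee <- sum(grid$abundance)
  grid <- apply_allee(grid)
  allee_lost <- pre_allee - sum(grid$abundance)
  after <- sum(grid$abundance)
  acct <- tibble::tibble(
    total_before = before, growth_delta = growth_delta,
    short_lost = sd_res$lost, jump_lost = lj_res$lost,
    allee_lost = allee_lost, total_after = after,
    residual = after - (before + growth_delta - sd_res$lost -
                          lj_res$lost - allee_lost)
  )
  list(grid = grid, accounting = acct)
}

#' Run replicate spread simulations
#'
#' Executes `replicates` weekly-timestep runs from the configured founder
#' population, each with a deterministically derived seed, and aggregates
#' per-region abundance series. Identical master seeds give identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return An object of class `faw_simulation` with elements `series`
#'   (tibble: replicate, region, time, total), `accounting` (per-step mass
#'   bookkeeping), `snapshots` (list of abundance matrices from replicate
#'   1), `final` (final [population_grid()] of replicate 1), and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- dim(config$rates$rates)
  week_starts <- seq(config$start, config$end, by = config$dt)
  month_idx <- match(lubridate::floor_date(week_starts, "month"),
                     config$rates$months)
  if (any(is.na(month_idx))) {
    stop("run_simulation: no rate raster for month(s) ",
         paste(unique(format(lubridate::floor_date(
       week_starts[is.na(month_idx)], "month"))), collapse = ", "))
  }
  abundance0 <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(config$init))) {
    abundance0[config$init$row[i], config$init$col[i]] <-
      abundance0[config$init$row[i], config$init$col[i]] +
      config$init$abundance[i]
  }
  destinations <- NULL
  if (config$jumps$beta > 0) {
    destinations <- jump_destination_table(
      config$land_mask, config$jumps$radius_km / config$cell_size)
  }
  region_cells <- split(
    (config$regions$col - 1) * d[1] + config$regions$row,
    config$regions$region)

  series <- vector("list", config$replicates)
  acct <- vector("list", config$replicates)
  snapshots <- list()
  final_grid <- NULL
  for (k in seq_len(config$replicates)) {
    grid <- population_grid(abundance0, cell_size = config$cell_size,
                            K = config$K, theta = config$theta,
                            land_mask = config$land_mask)
    rows <- vector("list", length(week_starts))
    arows <- vector("list", length(week_starts))
    with_seed(replicate_seed(config$seed, k), {
      for (w in seq_along(week_starts)) {
        res <- step_population(grid, config$rates$rates[, , month_idx[w]],
                               config$kernel, config$jumps, destinations,
                               dt = config$dt)
        grid <- res$grid
        arows[[w]] <- res$accounting
        rows[[w]] <- tibble::tibble(
          replicate = k, region = names(region_cells),
          time = week_starts[w],
          total = unname(vapply(region_cells,
                                function(ix) sum(grid$abundance[ix]),
                                numeric(1))))
        if (k == 1 && !is.na(config$snapshot_every) &&
            w %% config$snapshot_every == 0) {
          snapshots[[format(week_starts[w])]] <- grid$abundance
        }
      }
    })
    series[[k]] <- dplyr::bind_rows(rows)
    acct[[k]] <- dplyr::bind_rows(arows) |>
      dplyr::mutate(replicate = k, time = week_starts, .before = 1)
    if (k == 1) final_grid <- grid
  }
  structure(list(series = dplyr::bind_rows(series),
                 accounting = dplyr::bind_rows(acct),
                 snapshots = snapshots, final = final_grid,
                 config = config),
            class = "faw_simulation")
}

#' @export
print.faw_simulation <- function(x, ...) {
  cat(sprintf("<faw_simulation> %d replicate(s), %d step(s), %d region(s)\n",
              x$config$replicates,
              length(unique(x$series$time)),
              length(unique(x$series$region))))
  print(glance(x))
  invisible(x)
}

#' Summarise per-region abundance across replicates
#'
#' For each region and timestep, reports the mean and the min-max envelope
#' of total abundance across replicates, plus two presentation scalings:
#' abundance scaled to unity (per region) and `log10(1 + N)` scaled to
#' unity, which makes both small incoming-migrant populations and large
#' build-ups visible on one axis.
#'
#' @param sim A `faw_simulation` from [run_simulation()].
#' @return A tibble: `region`, `time`, `mean`, `min`, `max`, `scaled`,
#'   `log_scaled`.
#' @export
summarise_regions <- function(sim) {
  stopifnot(inherits(sim, "faw_simulation"))
  sim$series |>
    dplyr::group_by(.data$region, .data$time) |>
    dplyr::summarise(mean = mean(.data$total), min = min(.data$total),
                     max = max(.data$total), .groups = "drop_last") |>
    dplyr::mutate(
      scaled = .data$mean / max(.data$mean, 1e-300),
      log_scaled = log10(1 + .data$mean) / max(log10(1 + .data$mean), 1e-300)
    ) |>
    dplyr::ungroup()
}

#' Tidy a simulation into its abundance series
#'
#' @param x A `faw_simulation`.
#' @param ... Unused.
#' @return The per-replicate series tibble.
#' @method tidy faw_simulation
#' @export
tidy.faw_simulation <- function(x, ...) x$series

#' One-row overview of a simulation run
#'
#' @param x A `faw_simulation`.
#' @param ... Unused.
#' @return A one-row tibble: replicates, steps, final total abundance
#'   (replicate 1), occupied cells, and the largest absolute mass-balance
#'   residual.
#' @method glance faw_simulation
#' @export
glance.faw_simulation <- function(x, ...) {
  tibble::tibble(
    replicates = x$config$replicates,
    steps = length(unique(x$series$time)),
    final_total = sum(x$final$abundance),
    occupied_cells = sum(x$final$abundance > 0),
    max_abs_residual = max(abs(x$accounting$residual))
  )
}

#' Plot per-region abundance with replicate envelopes
#'
#' @param object A `faw_simulation`.
#' @param log10_scale Plot `log10(1 + N)` instead of raw abundance.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot faw_simulation
#' @export
autoplot.faw_simulation <- function(object, log10_scale = TRUE, ...) {
  s <- summarise_regions(object)
  tf <- if (log10_scale) function(v) log10(1 + v) else identity
  ggplot2::ggplot(s, ggplot2::aes(.data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = tf(.data$min), ymax = tf(.data$max)),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = tf(.data$mean))) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = if (log10_scale) "log10(1 + abundance)" else "abundance")
}
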