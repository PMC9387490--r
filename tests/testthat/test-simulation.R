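no_dispersal <- function() dispersal_kernel(p_disperse = 0)
no_jumps <- function() long_jump_params(beta = 0)

benign_config <- function(rows = 6, cols = 5, N0 = 1e5, months = 3, ...) {
  end <- as.character(lubridate::ceiling_date(
    as.Date("2019-01-01") + months * 30, "month") - 1)
  w <- make_gradient_world("benign_uniform", rows = rows, cols = cols,
                           start = "2019-01-01", end = end)
  simulation_config(climate = w$climate,
                    init = tibble::tibble(row = 3, col = 3, abundance = N0),
                    ...)
}

test_that("an empty world stays empty through any number of steps", {
  cfg <- benign_config(N0 = 0, kernel = no_dispersal(), jumps = no_jumps())
  sim <- run_simulation(cfg)
  expect_true(all(sim$series$total == 0))
})

test_that("without dispersal the trajectory is the closed-form logistic", {
  cfg <- benign_config(N0 = 1e5, months = 4, K = 1e9,
                       kernel = no_dispersal(), jumps = no_jumps())
  sim <- run_simulation(cfg)
  s <- sim$series
  weeks <- seq_along(unique(s$time))
  expected <- vapply(weeks, function(w) logistic_step(1e5, 0.16, 1e9, 7 * w),
                     numeric(1))
  expect_equal(s$total, expected, tolerance = 1e-9)
})

test_that("a sub-threshold founder population goes extinct at the first Allee check", {
  # theta = 1e4; 5000 individuals growing at 0.16/day for 7 days reach ~15300,
  # but 3000 reach ~9200 < theta and die out
  cfg <- benign_config(N0 = 3000, kernel = no_dispersal(), jumps = no_jumps())
  sim <- run_simulation(cfg)
  expect_true(all(sim$series$total == 0))
  cfg2 <- benign_config(N0 = 5000, kernel = no_dispersal(), jumps = no_jumps())
  sim2 <- run_simulation(cfg2)
  expect_true(all(sim2$series$total > 0))
})

test_that("identical master seeds give identical stochastic runs", {
  cfg <- benign_config(N0 = 1e6, replicates = 2, seed = 77)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$final$abundance, s2$final$abundance)
  cfg2 <- benign_config(N0 = 1e6, replicates = 2, seed = 78)
  expect_false(identical(run_simulation(cfg2)$series$total, s1$series$total))
})

test_that("the replicate envelope is degenerate when jumps are disabled", {
  cfg <- benign_config(N0 = 1e6, replicates = 3, jumps = no_jumps())
  sm <- summarise_regions(run_simulation(cfg))
  expect_equal(sm$min, sm$max)
  expect_equal(sm$min, sm$mean)
})

test_that("early log-growth recovers the configured net rate within 1%", {
  cfg <- benign_config(N0 = 1e5, months = 2, kernel = no_dispersal(),
                       jumps = no_jumps())
  sim <- run_simulation(cfg)
  s <- head(sim$series, 4)
  days <- as.numeric(s$time - min(s$time)) + 7
  fit <- stats::lm(log(s$total) ~ days)
  expect_equal(unname(stats::coef(fit)[2]), 0.16, tolerance = 0.01)
})

test_that("per-step mass accounting closes to within 1e-6 relative", {
  w <- make_gradient_world("tropics_to_temperate", rows = 16, cols = 6)
  cfg <- simulation_config(climate = w$climate,
                           init = tibble::tibble(row = 2, col = 3,
                                                 abundance = 1e6),
                           replicates = 2, seed = 5)
  sim <- run_simulation(cfg)
  scale <- pmax(sim$accounting$total_before, 1)
  expect_true(all(abs(sim$accounting$residual) / scale < 1e-6))
  expect_equal(glance(sim)$max_abs_residual,
               max(abs(sim$accounting$residual)))
})

test_that("warming a cold-limited world never reduces the next-step total", {
  totals <- vapply(c(5, 8), function(tb) {
    w <- make_gradient_world("benign_uniform", rows = 4, cols = 4,
                             start = "2019-01-01", end = "2019-01-31")
    # rebuild at a uniform cold temperature below CTmin
    cold <- climate_grid(array(tb, dim(w$climate$temp_c)),
                         w$climate$wilting, w$climate$time,
                         w$climate$geometry)
    rates <- monthly_rate_raster(cold)
    g <- population_grid(matrix(1e8, 4, 4), theta = 0)
    step_population(g, rates$rates[, , 1], no_dispersal(), no_jumps())$grid |>
      (\(x) sum(x$abundance))()
  }, numeric(1))
  expect_gte(totals[2], totals[1])
})

test_that("region series partition the global total and name empty regions", {
  regions <- tibble::tibble(
    region = rep(c("west", "east"), times = c(6 * 3, 6 * 2)),
    row = c(rep(1:6, 3), rep(1:6, 2)),
    col = c(rep(1:3, each = 6), rep(4:5, each = 6))
  )
  cfg <- benign_config(N0 = 1e6, regions = regions, seed = 3)
  sim <- run_simulation(cfg)
  both <- tidyr::pivot_wider(sim$series, names_from = "region",
                             values_from = "total")
  cfg_g <- benign_config(N0 = 1e6, seed = 3)
  glob <- run_simulation(cfg_g)$series$total
  expect_equal(both$west + both$east, glob, tolerance = 1e-9)

  bad <- tibble::tibble(region = "nowhere", row = 99, col = 1)
  expect_error(benign_config(regions = bad), "nowhere")
})

test_that("rate/grid shape mismatches are refused", {
  g <- population_grid(matrix(1e6, 4, 4))
  expect_error(step_population(g, matrix(0.1, 3, 3), no_dispersal(),
                               no_jumps()),
               "dim")
})

test_that("the transient south swells in the warm season and collapses in winter", {
  w <- make_gradient_world("tropics_to_temperate", rows = 30, cols = 6)
  rates <- monthly_rate_raster(w$climate)
  ann <- annual_mean_growth(rates)
  # rows 22-30 lie beyond the permanent range of this world
  expect_true(all(ann[22:30, ] < 0))
  south <- tibble::tibble(region = "south",
                          row = rep(22:30, times = 6),
                          col = rep(1:6, each = 9))
  cfg <- simulation_config(climate = w$climate,
                           init = tibble::tibble(row = 2, col = 3,
                                                 abundance = 1e8),
                           replicates = 1, seed = 11, regions = south)
  sim <- run_simulation(cfg)
  s <- sim$series
  mo <- lubridate::month(s$time)
  warm <- mean(s$total[mo %in% c(12, 1, 2, 3)])  # southern-hemisphere summer
  cold <- mean(s$total[mo %in% 6:9])
  expect_gt(warm, 2 * cold)
  # the seasonal sign pattern of the forcing drives this: southern monthly
  # rates are positive only around the warm months
  r_south <- rates$rates[25, 3, ]
  expect_true(all(r_south[6:9] < 0))
  expect_gt(max(r_south[c(1, 2, 12)]), min(r_south) + 0.1)
  # migrants do reach beyond the permanent range at all (dispersal matters)
  expect_gt(max(s$total), 0)
})

test_that("zero-week and snapshot bookkeeping stay consistent", {
  cfg <- benign_config(N0 = 1e6, months = 3, snapshot_every = 2, seed = 9)
  sim <- run_simulation(cfg)
  expect_gt(length(sim$snapshots), 0)
  expect_equal(dim(sim$snapshots[[1]]), c(6, 5))
  g <- glance(sim)
  expect_equal(g$final_total, sum(sim$final$abundance))
})
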