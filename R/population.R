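# Gridded population state: logistic growth, Allee extinction,
# annual-mean rates and establishment classification.

#' Gridded population state
#'
#' Per-cell abundance (individuals, non-negative reals) on a regular grid,
#' with carrying capacity and Allee threshold metadata and a land mask.
#' Abundance is forced to zero off land. Row 1 is the northernmost row.
#'
#' @param abundance Numeric matrix of per-cell abundance.
#' @param cell_size Linear cell dimension (km; default 9).
#' @param K Carrying capacity per cell (individuals; default 1e9,
#'   approximately one individual per square metre at this resolution).
#' @param theta Allee threshold per cell (individuals; default 10 000,
#'   roughly one moth per hectare).
#' @param land_mask Logical matrix, same shape; `TRUE` = land. Defaults to
#'   all-land.
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(abundance, cell_size = 9, K = 1e9, theta = 1e4,
                            land_mask = NULL) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("population_grid: abundance must be >= 0")
  }
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, nrow(abundance), ncol(abundance))
  }
  stopifnot(is.logical(land_mask), dim(land_mask) == dim(abundance),
            K > 0, theta >= 0, cell_size > 0)
  abundance[!land_mask] <- 0
  abundance[is.na(abundance)] <- 0
  structure(list(abundance = abundance, cell_size = cell_size,
                 K = K, theta = theta, land_mask = land_mask),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("<population_grid> %d x %d cells (%g km), K = %g, theta = %g\n",
              nrow(x$abundance), ncol(x$abundance), x$cell_size, x$K, x$theta))
  cat(sprintf("  occupied cells: %d, total abundance: %g\n",
              sum(x$abundance > 0), sum(x$abundance)))
  invisible(x)
}

#' Tidy a population grid into a cell table
#'
#' @param x A `population_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `abundance`, `land`.
#' @method tidy population_grid
#' @export
tidy.population_grid <- function(x, ...) {
  nr <- nrow(x$abundance); nc <- ncol(x$abundance)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    abundance = as.vector(x$abundance),
    land = as.vector(x$land_mask)
  )
}

#' One weekly (or arbitrary-duration) growth update
#'
#' Advances abundance under the logistic model `dN/dt = (1 - N/K) r N`.
#' For `r > 0` the closed-form logistic solution
#' `K N e^{rt} / (K + N (e^{rt} - 1))` is used (unconditionally stable at
#' weekly steps); for `r <= 0` density dependence is dropped and the
#' population declines as pure exponential `N e^{rt}`. Vectorised over all
#' arguments (recycling), so a matrix of abundances against a matrix of
#' rates advances a whole grid.
#'
#' @param N Abundance(s) (>= 0).
#' @param r Net growth rate(s), 1/day; `NA` rates leave `N` at 0.
#' @param K Carrying capacity.
#' @param dt Duration (days).
#' @return Updated abundance(s); never exceeds `K` when starting at or
#'   below it.
#' @examples
#' logistic_step(1000, 0.12, K = 1e9, dt = 28) / 1000  # ~29-fold
#' @export
logistic_step <- function(N, r, K = 1e9, dt = 7) {
  stopifnot(all(N >= 0, na.rm = TRUE), K > 0, dt > 0)
  g <- exp(r * dt)
  out <- ifelse(!is.na(r) & r > 0, K * N * g / (K + N * (g - 1)), N * g)
  out[is.na(r)] <- 0
  dim(out) <- dim(N)
  out
}

#' Allee-threshold extinction
#'
#' Sets to zero every cell whose abundance is strictly below the Allee
#' threshold `theta`; cells at or above `theta` are unchanged. Applied once
#' at the end of each weekly timestep: small founder populations (arriving
#' migrants included) fail to establish. Idempotent.
#'
#' @param grid A [population_grid()].
#' @return The grid with sub-threshold cells extinct.
#' @export
apply_allee <- function(grid) {
  stopifnot(inherits(grid, "population_grid"))
  a <- grid$abundance
  a[a < grid$theta] <- 0
  grid$abundance <- a
  grid
}

#' Annual mean growth rate per cell
#'
#' Arithmetic mean across months of per-cell monthly mean rates. Because
#' growth compounds as `exp((r1 + ... + rn) t)`, the mean rate's sign
#' decides whether a cell gains or loses population over the full year.
#'
#' @param monthly A 3-d array `[rows, cols, months]` of monthly mean rates
#'   (as produced by [monthly_rate_raster()], whose `rates` element can be
#'   passed directly), or a `faw_rates` object.
#' @return A matrix of per-cell annual means. Cells with some (not all)
#'   missing months are averaged over available months with a warning;
#'   all-missing cells are `NA`.
#' @export
annual_mean_growth <- function(monthly) {
  if (inherits(monthly, "faw_rates")) monthly <- monthly$rates
  stopifnot(is.array(monthly), length(dim(monthly)) == 3)
  n_na <- apply(monthly, c(1, 2), function(v) sum(is.na(v)))
  partial <- n_na > 0 & n_na < dim(monthly)[3]
  if (any(partial)) {
    warning(sprintf("annual_mean_growth: %d cell(s) had missing months; %s",
                    sum(partial), "averaged over available months"))
  }
  out <- apply(monthly, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out
}

#' Permanent-range (establishment) classification
#'
#' A cell belongs to the permanent range if and only if its annual mean
#' growth rate is strictly positive; mean-zero and negative cells are
#' transient (reachable by dispersal in favourable seasons but unable to
#' sustain year-round populations). `NA` (sea/missing) propagates.
#'
#' @param annual_mean Matrix of per-cell annual mean rates.
#' @return Logical matrix: `TRUE` = permanent range.
#' @export
establishment_map <- function(annual_mean) {
  stopifnot(is.matrix(annual_mean))
  annual_mean > 0
}
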