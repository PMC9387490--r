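# Dispersal: short-range discretised exponential kernel and long-range
# stochastic jumps.

#' Build the short-range dispersal kernel
#'
#' Discretises the 2-D negative-exponential location kernel
#' `f(d) = exp(-d / alpha)` (distance in cell units, centre-to-centre
#' Euclidean) over the `(2 dS + 1) x (2 dS + 1)` neighbourhood, dropping
#' cells farther than `dS` from the centre. The centre cell keeps
#' `1 - p_disperse` of the mass and the off-centre cells share `p_disperse`
#' in proportion to their raw exponential weights, so `p_disperse` is the
#' fraction of a cell's population undertaking short-range dispersal each
#' step. With the defaults (`alpha = 0.01` cells, `dS = 2` cells = 18 km,
#' `p_disperse = 0.01`) 1% of each cell's population disperses, almost
#' entirely to the four orthogonally adjacent cells.
#'
#' @param alpha Kernel scale (cell units); `2 * alpha` is the mean
#'   displacement of the underlying continuous kernel (see
#'   [mean_dispersal_distance()]).
#' @param dS Truncation step distance (cells, >= 1).
#' @param p_disperse Fraction leaving the centre cell per step, in \[0, 1).
#' @param cell_size Cell size (km), carried as metadata.
#' @return An object of class `dispersal_kernel` with a `weights` matrix
#'   summing to 1.
#' @export
dispersal_kernel <- function(alpha = 0.01, dS = 2, p_disperse = 0.01,
                             cell_size = 9) {
  if (dS < 1) stop("dispersal_kernel: dS must be >= 1 (degenerate kernel)")
  stopifnot(alpha > 0, p_disperse >= 0, p_disperse < 1)
  n <- 2 * dS + 1
  off <- seq(-dS, dS)
  d <- sqrt(outer(off^2, off^2, "+"))
  raw <- exp(-(d - 1) / alpha)  # shifted by the min off-centre distance to avoid underflow
  raw[d > dS] <- 0
  centre <- dS + 1
  raw[centre, centre] <- 0
  w <- matrix(0, n, n)
  if (p_disperse > 0) {
    w <- p_disperse * raw / sum(raw)
  }
  w[centre, centre] <- 1 - p_disperse
  structure(list(weights = w, alpha = alpha, dS = dS,
                 p_disperse = p_disperse, cell_size = cell_size),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf("<dispersal_kernel> %dx%d, alpha = %g cells, p_disperse = %g\n",
              nrow(x$weights), ncol(x$weights), x$alpha, x$p_disperse))
  print(signif(x$weights, 3))
  invisible(x)
}

#' Mean displacement of the continuous exponential kernel
#'
#' For the radially symmetric 2-D kernel with density proportional to
#' `exp(-r / alpha)`, the mean displacement is
#' `int r^2 exp(-r/alpha) dr / int r exp(-r/alpha) dr = 2 alpha`.
#'
#' @param alpha Kernel scale (cell units or km, as interpreted).
#' @return Mean dispersal distance, same units as `alpha`.
#' @export
mean_dispersal_distance <- function(alpha) 2 * alpha

#' Long-range jump dispersal parameters
#'
#' @param beta Proportion of each occupied cell's population undertaking a
#'   long-range jump per weekly step (default 0.05).
#' @param radius_km Maximum jump distance (km; default 540, one week of
#'   nightly long-range flights).
#' @return An object of class `long_jump_params`.
#' @export
long_jump_params <- function(beta = 0.05, radius_km = 540) {
  stopifnot(beta >= 0, beta <= 1, radius_km > 0)
  structure(list(beta = beta, radius_km = radius_km),
            class = "long_jump_params")
}

#' Apply short-range kernel dispersal to a population grid
#'
#' Linear convolution of the abundance field with the kernel. Boundaries are
#' absorbing: mass directed off the grid or onto non-land cells is removed
#' (moths over ocean do not found populations). On an all-land interior the
#' operation conserves total abundance to machine precision.
#'
#' @param grid A [population_grid()].
#' @param kernel A [dispersal_kernel()].
#' @return A list with elements `grid` (the dispersed [population_grid()])
#'   and `lost` (mass absorbed at boundaries/sea).
#' @export
apply_short_dispersal <- function(grid, kernel) {
  stopifnot(inherits(grid, "population_grid"),
            inherits(kernel, "dispersal_kernel"))
  a <- grid$abundance
  nr <- nrow(a); nc <- ncol(a)
  dS <- kernel$dS
  out <- matrix(0, nr, nc)
  w <- kernel$weights
  for (di in -dS:dS) {
    for (dj in -dS:dS) {
      wk <- w[di + dS + 1, dj + dS + 1]
      if (wk == 0) next
      sr <- max(1, 1 - di):min(nr, nr - di)  # source rows whose target stays in-grid
      sc <- max(1, 1 - dj):min(nc, nc - dj)
      out[sr + di, sc + dj] <- out[sr + di, sc + dj] + wk * a[sr, sc]
    }
  }
  out[!grid$land_mask] <- 0
  lost <- sum(a) - sum(out)
  grid$abundance <- out
  list(grid = grid, lost = lost)
}

# Relative integer offsets (dr, dc) with 0 < distance <= radius_cells.
jump_offsets <- function(radius_cells) {
  r <- floor(radius_cells)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(off$dr^2 + off$dc^2)
  keep <- d > 0 & d <= radius_cells
  as.matrix(off[keep, , drop = FALSE])
}

#' Precompute eligible long-jump destinations per cell
#'
#' For each requested cell, lists the linear indices of land cells within
#' the jump radius (origin excluded). Computed once per land mask and
#' reused across timesteps and replicates.
#'
#' @param land_mask Logical matrix.
#' @param radius_cells Jump radius in cell units.
#' @param cells Linear indices of cells to compute (default: all land
#'   cells).
#' @return A list of integer vectors indexed by linear cell index.
#' @export
jump_destination_table <- function(land_mask, radius_cells,
                                   cells = which(land_mask)) {
  nr <- nrow(land_mask); nc <- ncol(land_mask)
  off <- jump_offsets(radius_cells)
  tab <- vector("list", nr * nc)
  for (idx in cells) {
    r0 <- ((idx - 1) %% nr) + 1
    c0 <- ((idx - 1) %/% nr) + 1
    rr <- r0 + off[, 1]
    cc <- c0 + off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    lin <- (cc[ok] - 1) * nr + rr[ok]
    tab[[idx]] <- lin[land_mask[lin]]
  }
  tab
}

#' Apply long-range jump dispersal
#'
#' From every occupied cell, a fraction `beta` of the population leaves as a
#' single packet to one destination drawn uniformly at random from the land
#' cells within `radius_km` of the origin (origin excluded). If a cell has
#' no eligible destination its migrants are lost. Uses R's global RNG:
#' seed it for reproducibility.
#'
#' @param grid A [population_grid()].
#' @param params A [long_jump_params()].
#' @param destinations Optional precomputed [jump_destination_table()];
#'   computed on the fly for occupied cells when `NULL`.
#' @return A list with elements `grid`, `lost` (migrants with no eligible
#'   destination) and `moved` (total mass that jumped).
#' @export
apply_long_jumps <- function(grid, params, destinations = NULL) {
  stopifnot(inherits(grid, "population_grid"),
            inherits(params, "long_jump_params"))
  a <- grid$abundance
  if (params$beta == 0) return(list(grid = grid, lost = 0, moved = 0))
  radius_cells <- params$radius_km / grid$cell_size
  occupied <- which(a > 0 & grid$land_mask)
  if (length(occupied) == 0) return(list(grid = grid, lost = 0, moved = 0))
  if (is.null(destinations)) {
    destinations <- jump_destination_table(grid$land_mask, radius_cells,
                                           cells = occupied)
  }
  migrants <- params$beta * a[occupied]
  a[occupied] <- a[occupied] - migrants
  lost <- 0
  for (k in seq_along(occupied)) {
    dests <- destinations[[occupied[k]]]
    n <- length(dests)
    if (n == 0) {
      lost <- lost + migrants[k]
    } else {
      dest <- dests[sample.int(n, 1L)]
      a[dest] <- a[dest] + migrants[k]
    }
  }
  grid$abundance <- a
  list(grid = grid, lost = lost, moved = sum(migrants))
}

#' Write a kernel's weight matrix as plain text
#'
#' @param kernel A [dispersal_kernel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dispersal_kernel alpha=%.17g dS=%d p_disperse=%.17g cell_size=%.17g",
                     kernel$alpha, kernel$dS, kernel$p_disperse,
                     kernel$cell_size), con)
  utils::write.table(kernel$weights, con, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a kernel written by [write_kernel()]
#'
#' @param path File path.
#' @return A `dispersal_kernel`.
#' @export
read_kernel <- function(path) {
  header <- readLines(path, n = 1)
  get_num <- function(key) {
    as.numeric(sub(sprintf(".*%s=([^ ]+).*", key), "\\1", header))
  }
  w <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
  dimnames(w) <- NULL
  k <- dispersal_kernel(alpha = get_num("alpha"), dS = as.integer(get_num("dS")),
                        p_disperse = get_num("p_disperse"),
                        cell_size = get_num("cell_size"))
  k$weights <- w
  k
}
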