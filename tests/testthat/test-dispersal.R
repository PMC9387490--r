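test_that("the default kernel has 1% off-centre mass, normalised and symmetric", {
  k <- dispersal_kernel()
  w <- k$weights
  expect_equal(dim(w), c(5, 5))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w) - w[3, 3], 0.01, tolerance = 1e-12)
  # symmetry under 90-degree rotation and reflection
  expect_equal(w, t(w))
  expect_equal(w, w[5:1, ])
  expect_equal(w, w[, 5:1])
  # corners lie beyond the dS = 2 truncation distance
  expect_identical(w[1, 1], 0)
  # weights non-increasing with distance from the centre
  off <- -2:2
  d <- sqrt(outer(off^2, off^2, "+"))
  ord <- order(d)
  expect_true(all(diff(w[ord]) <= 1e-12))
})

test_that("degenerate and no-dispersal kernels behave as specified", {
  expect_error(dispersal_kernel(dS = 0), "degenerate")
  k0 <- dispersal_kernel(p_disperse = 0)
  expect_identical(k0$weights[3, 3], 1)
  expect_identical(sum(k0$weights), 1)
})

test_that("mean displacement of the continuous kernel is 2*alpha", {
  for (a in c(0.3, 1, 2.5)) {
    num <- stats::integrate(function(r) r^2 * exp(-r / a), 0, Inf)$value
    den <- stats::integrate(function(r) r * exp(-r / a), 0, Inf)$value
    expect_equal(mean_dispersal_distance(a), num / den, tolerance = 1e-6)
  }
})

test_that("short-range dispersal of an impulse reproduces the kernel pattern", {
  k <- dispersal_kernel()
  a <- matrix(0, 11, 11); a[6, 6] <- 1e6
  res <- apply_short_dispersal(population_grid(a), k)
  expect_equal(res$grid$abundance[4:8, 4:8], 1e6 * k$weights)
  expect_equal(res$lost, 0)
  expect_equal(sum(res$grid$abundance), 1e6, tolerance = 1e-9)
})

test_that("uniform abundance is a fixed point away from boundaries", {
  k <- dispersal_kernel()
  a <- matrix(1e5, 15, 15)
  res <- apply_short_dispersal(population_grid(a), k)
  interior <- res$grid$abundance[3:13, 3:13]
  expect_equal(interior, matrix(1e5, 11, 11), tolerance = 1e-12)
})

test_that("short dispersal commutes with translation away from boundaries", {
  k <- dispersal_kernel()
  a <- matrix(0, 13, 13); a[5, 5] <- 7e5; a[6, 7] <- 3e5
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  d1 <- shift(apply_short_dispersal(population_grid(a), k)$grid$abundance, 2, 1)
  d2 <- apply_short_dispersal(population_grid(shift(a, 2, 1)), k)$grid$abundance
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("mass directed onto sea equals the kernel overlap, and is removed", {
  k <- dispersal_kernel()
  mask <- matrix(TRUE, 9, 9); mask[, 6:9] <- FALSE   # coast east of column 5
  a <- matrix(0, 9, 9); a[5, 5] <- 1e6               # population on the coast
  res <- apply_short_dispersal(population_grid(a, land_mask = mask), k)
  # direct summation oracle: kernel mass whose destination column exceeds 5
  overlap <- sum(k$weights[, 4:5])
  expect_equal(res$lost, 1e6 * overlap, tolerance = 1e-9)
  expect_equal(sum(res$grid$abundance), 1e6 * (1 - overlap), tolerance = 1e-9)
})

test_that("long jumps move exactly beta*N as one packet to a land cell in range", {
  a <- matrix(0, 21, 21); a[11, 11] <- 1e6
  g <- population_grid(a, cell_size = 9)
  set.seed(99)
  res <- apply_long_jumps(g, long_jump_params(beta = 0.05, radius_km = 540))
  expect_equal(res$grid$abundance[11, 11], 0.95e6)
  expect_equal(res$moved, 5e4)
  expect_equal(res$lost, 0)
  expect_equal(sum(res$grid$abundance), 1e6)
  dest <- which(res$grid$abundance == 5e4, arr.ind = TRUE)
  expect_equal(nrow(dest), 1)
  expect_lte(sqrt(sum((dest - c(11, 11))^2)) * 9, 540)

  # beta = 0 leaves the grid untouched
  res0 <- apply_long_jumps(g, long_jump_params(beta = 0))
  expect_identical(res0$grid$abundance, a)

  # an isolated island has no eligible destination: migrants are lost
  mask1 <- matrix(FALSE, 5, 5); mask1[3, 3] <- TRUE
  g1 <- population_grid(matrix(c(rep(0, 12), 1e6, rep(0, 12)), 5, 5),
                        land_mask = mask1)
  set.seed(1)
  res1 <- apply_long_jumps(g1, long_jump_params(beta = 0.05, radius_km = 18))
  expect_equal(res1$lost, 5e4)
  expect_equal(res1$grid$abundance[3, 3], 0.95e6)
})

test_that("long jumps are bit-reproducible under a fixed seed", {
  a <- matrix(runif(15 * 15) * 1e6, 15, 15)
  g <- population_grid(a)
  p <- long_jump_params()
  set.seed(2024); r1 <- apply_long_jumps(g, p)
  set.seed(2024); r2 <- apply_long_jumps(g, p)
  expect_identical(r1$grid$abundance, r2$grid$abundance)
})

test_that("jump destinations are uniform over the eligible disc", {
  # radius 2 cells on a 7x7 all-land grid: 12 eligible destinations
  a <- matrix(0, 7, 7); a[4, 4] <- 1e4
  g <- population_grid(a, cell_size = 9)
  p <- long_jump_params(beta = 0.4, radius_km = 18)
  tab <- jump_destination_table(g$land_mask, 2, cells = (4 - 1) * 7 + 4)
  eligible <- tab[[(4 - 1) * 7 + 4]]
  expect_length(eligible, 12)
  set.seed(5)
  hits <- integer(49)
  for (i in 1:4800) {
    res <- apply_long_jumps(g, p, destinations = tab)
    dest <- which(res$grid$abundance == 4e3)
    hits[dest] <- hits[dest] + 1L
  }
  expect_identical(sum(hits[eligible]), 4800L)
  chi <- stats::chisq.test(hits[eligible])
  expect_gt(chi$p.value, 0.001)
})

test_that("combined weekly dispersal never creates mass or negative cells", {
  set.seed(31)
  for (i in 1:10) {
    nr <- sample(6:12, 1); nc <- sample(6:12, 1)
    mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
    a <- matrix(rpois(nr * nc, 5) * 1e4, nr, nc)
    g <- population_grid(a, land_mask = mask)
    before <- sum(g$abundance)
    s <- apply_short_dispersal(g, dispersal_kernel())
    j <- apply_long_jumps(s$grid, long_jump_params(radius_km = 45))
    after <- sum(j$grid$abundance)
    expect_true(all(j$grid$abundance >= 0))
    expect_lte(after, before * (1 + 1e-9))
    expect_equal(before - after, s$lost + j$lost, tolerance = 1e-6)
  }
})

test_that("kernel text dump and load roundtrip", {
  k <- dispersal_kernel(alpha = 0.02, dS = 2, p_disperse = 0.015)
  f <- tempfile(fileext = ".txt")
  write_kernel(k, f)
  k2 <- read_kernel(f)
  expect_equal(k2$weights, k$weights, tolerance = 1e-12)
  expect_equal(k2$alpha, k$alpha)
  expect_equal(k2$p_disperse, k$p_disperse)
})
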