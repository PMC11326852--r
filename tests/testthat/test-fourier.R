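test_that("F(0,0,0) = V alone synthesizes a uniform unit map", {
  cell <- unit_cell(4, 4, 4)
  fr <- random_structure(3, cell, seed = 5)
  refs <- calc_structure_factors(fr, 1.2)
  refs$F[] <- 0
  refs$F[refs$hkl$h == 0 & refs$hkl$k == 0 & refs$hkl$l == 0] <- cell$V
  den <- density_from_sf(refs, list(dims = c(8L, 8L, 8L)))
  expect_equal(max(abs(den$values - 1)), 0, tolerance = 1e-12)
})

test_that("FFT density synthesis equals the naive direct summation", {
  cell <- unit_cell(4, 4, 4)
  for (seed in 1:5) {
    fr <- random_structure(5, cell, seed = seed)
    refs <- calc_structure_factors(fr, 1.2)
    den <- density_from_sf(refs, list(dims = c(8L, 8L, 8L)))
    oracle <- xtalformer:::density_direct_sum(refs, c(8L, 8L, 8L))
    expect_lt(max(abs(den$values - oracle)), 1e-9)
  }
})

test_that("band-limited density round-trips through structure factors", {
  cell <- unit_cell(5, 4, 6)
  fr <- random_structure(6, cell, seed = 9)
  refs <- calc_structure_factors(fr, 1.5)
  grid <- list(dims = c(10L, 8L, 12L))
  den <- density_from_sf(refs, grid)
  refs2 <- sf_from_map(den, 1.5)
  expect_equal(refs2$hkl[, c("h", "k", "l")], refs$hkl[, c("h", "k", "l")])
  expect_lt(max(Mod(refs2$F - refs$F)), 1e-9 * max(Mod(refs$F)))
  den2 <- density_from_sf(refs2, grid)
  expect_lt(max(abs(den2$values - den$values)), 1e-9)
})

test_that("Friedel-inconsistent coefficients are rejected", {
  cell <- unit_cell(4, 4, 4)
  fr <- random_structure(2, cell, seed = 3)
  refs <- calc_structure_factors(fr, 1.5)
  # an imaginary F(0,0,0) cannot come from any real density
  refs$F[refs$hkl$h == 0 & refs$hkl$k == 0 & refs$hkl$l == 0] <- 5i
  expect_error(density_from_sf(refs, list(dims = c(8L, 8L, 8L))),
               "non-real density")
})

test_that("Patterson via squared amplitudes matches the autocorrelation route", {
  for (seed in 1:5) {
    cell <- unit_cell(runif(1, 4, 8), runif(1, 4, 8), runif(1, 4, 8))
    fr <- random_structure(6, cell, seed = 100 + seed)
    refs <- calc_structure_factors(fr, 1.5)
    dims <- build_grid(cell, 1.5, 2.0)$dims
    p_sf <- patterson_from_sf(refs, list(dims = dims))
    p_ac <- patterson_from_density(density_from_sf(refs, list(dims = dims)))
    expect_lt(max(abs(p_sf$values - p_ac$values)) / max(abs(p_sf$values)),
              1e-6)
  }
})

test_that("Patterson physics: origin peak, centrosymmetry, two-atom vectors", {
  cell <- unit_cell(8, 8, 8)
  # single atom anywhere: global maximum at the origin voxel
  fr1 <- fragment_structure(
    data.frame(element = "C", x = 3.1, y = 5.2, z = 0.7), cell = cell)
  p1 <- patterson_from_sf(calc_structure_factors(fr1, 2.2),
                          list(dims = c(8L, 8L, 8L)))
  expect_identical(which.max(p1$values), 1L)

  # two unit atoms separated by delta: peaks at 0 and +/- delta,
  # origin peak twice the satellite height
  fr2 <- fragment_structure(
    data.frame(element = "X", x = c(1, 3), y = c(1, 1), z = c(1, 1)),
    cell = cell)
  p2 <- patterson_from_sf(calc_structure_factors(fr2, 2.2),
                          list(dims = c(8L, 8L, 8L)))
  v <- p2$values
  # delta = (2, 0, 0) A = 2 voxels at 1 A spacing
  expect_identical(which.max(v), 1L)
  satellites <- c(v[3, 1, 1], v[7, 1, 1]) # +delta and -delta (mod 8)
  expect_equal(satellites[1], satellites[2], tolerance = 1e-9)
  # ideal point vectors give exactly 2; band-limited peaks overlap their
  # truncation ripples, so the ratio is only approximate
  expect_equal(v[1, 1, 1] / satellites[1], 2, tolerance = 0.1)

  # exact centrosymmetry on random maps
  for (seed in 1:3) {
    fr <- random_structure(5, cell, seed = 200 + seed)
    p <- patterson_from_sf(calc_structure_factors(fr, 2.2),
                           list(dims = c(8L, 8L, 8L)))
    idx <- as.matrix(expand.grid(i = 0:7, j = 0:7, k = 0:7))
    mirror <- p$values[cbind((-idx[, 1]) %% 8 + 1, (-idx[, 2]) %% 8 + 1,
                             (-idx[, 3]) %% 8 + 1)]
    expect_lt(max(abs(p$values[idx + 1] - mirror)),
              1e-12 * max(abs(p$values)))
  }
})

test_that("the Patterson map is invariant to translations of the density", {
  cell <- unit_cell(6, 6, 6)
  fr <- random_structure(4, cell, seed = 77)
  dims <- c(12L, 12L, 12L)
  p0 <- patterson_from_sf(calc_structure_factors(fr, 1.5),
                          list(dims = dims))
  for (shift in list(c(1.0, 0, 0), c(0.5, 2.5, 1.0), c(-2, 3, 4))) {
    fr2 <- fr
    fr2$atoms$x <- (fr2$atoms$x + shift[1]) %% cell$a
    fr2$atoms$y <- (fr2$atoms$y + shift[2]) %% cell$b
    fr2$atoms$z <- (fr2$atoms$z + shift[3]) %% cell$c
    p2 <- patterson_from_sf(calc_structure_factors(fr2, 1.5),
                            list(dims = dims))
    expect_lt(max(abs(p2$values - p0$values)) / max(abs(p0$values)), 1e-6)
  }
  # circular voxel shifts of the density leave the autocorrelation fixed
  den <- density_from_sf(calc_structure_factors(fr, 1.5),
                         list(dims = dims))
  pd <- patterson_from_density(den)
  den2 <- den
  den2$values <- den$values[c(4:12, 1:3), c(12, 1:11), ]
  pd2 <- patterson_from_density(den2)
  expect_lt(max(abs(pd2$values - pd$values)), 1e-10 * max(abs(pd$values)))
})

test_that("all-zero maps give all-zero Patterson maps", {
  z <- volume_grid(array(0, c(4, 4, 4)), unit_cell(4, 4, 4))
  expect_true(all(patterson_from_density(z)$values == 0))
})
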