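test_that("a paraboloid grid has exactly one minimum at its center", {
  g <- as_pmf_grid(grid_from_surface(
    function_surface(function(z) 40 * (z[1]^2 + z[2]^2),
                     rbind(c(-1, 1), c(-1, 1))), n_bins = 41))
  m <- find_minima(g)
  expect_equal(nrow(m), 1L)
  expect_lt(sqrt(m$z1^2 + m$z2^2), 0.01)
})

test_that("a flat grid yields no minima under the strict-inequality rule", {
  g <- as_pmf_grid(grid_from_surface(
    function_surface(function(z) 1, rbind(c(-1, 1), c(-1, 1))), n_bins = 21))
  expect_equal(nrow(find_minima(g)), 0L)
})

test_that("the conduction preset minima are recovered from its grid", {
  sf <- preset_conduction_surface()
  g <- as_pmf_grid(grid_from_surface(sf, n_bins = 100))
  m <- find_minima(g)
  gt <- sf$ground_truth[sf$ground_truth$type == "min", ]
  expect_equal(nrow(m), 5L)
  for (i in seq_len(5)) {
    d <- sqrt((m$z1 - gt$z1[i])^2 + (m$z2 - gt$z2[i])^2)
    expect_lt(min(d), 1e-2)
  }
  ## energies match the interpolated surface at the located points
  itp <- attr(m, "interpolant")
  expect_equal(m$energy, fes_value(itp, as.matrix(m[, c("z1", "z2")])),
               tolerance = 1e-9)
})

test_that("minima detection is invariant to constant shifts and merges twins", {
  sf <- two_well()
  g <- grid_from_surface(sf, n_bins = 61)
  m1 <- find_minima(as_pmf_grid(g))
  g2 <- g; g2$free_energy <- g2$free_energy + 100
  m2 <- find_minima(as_pmf_grid(g2), max_energy = 100 + 50)
  expect_equal(m1[, c("z1", "z2")], m2[, c("z1", "z2")], tolerance = 1e-9)
  expect_equal(m2$energy - 100, m1$energy, tolerance = 1e-9)
  ## a separation larger than the well distance keeps only the lower minimum
  m3 <- find_minima(as_pmf_grid(g), min_separation = 3)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$energy, min(m1$energy))
})

test_that("basin assignment follows the gradient, not Euclidean distance", {
  ## a shallow well at (-0.3, 0) and a deep one at (1.5, 0): the saddle sits
  ## near the shallow well, so points just past it descend into the deep well
  ## although they are Euclidean-closer to the shallow one
  sf <- make_surface(list(gaussian_term(-15, c(-0.3, 0), 0.25),
                          gaussian_term(-40, c(0.7, 0), 0.25)),
                     boundaries = rbind(c(-1.2, 1.6), c(-1, 1)))
  gt <- sf$ground_truth
  m <- data.frame(index = 1:2,
                  z1 = gt$z1[gt$type == "min"],
                  z2 = gt$z2[gt$type == "min"],
                  energy = gt$energy[gt$type == "min"])
  sad <- gt[gt$type == "saddle", ]
  far <- which.max(m$z1); near <- which.min(m$z1)
  probe <- c(sad$z1 + 0.05, 0)
  ## premise: probe is Euclidean-closer to the near well
  expect_lt(abs(probe[1] - m$z1[near]), abs(probe[1] - m$z1[far]))
  idx <- assign_basins(rbind(probe), m, sf, n_steps = 50)
  expect_equal(idx, m$index[far])
  ## samples at the minima stay put
  expect_equal(assign_basins(as.matrix(m[, c("z1", "z2")]), m, sf), 1:2)
})

test_that("basin assignment partitions samples below the ceiling", {
  sf <- two_well()
  m <- find_minima(as_pmf_grid(grid_from_surface(sf, 61)))
  set.seed(12)
  P <- cbind(runif(200, -1.5, 1.5), runif(200, -0.8, 0.8))
  en <- fes_value(sf, P)
  idx <- assign_basins(P, m, sf, max_energy = 15)
  expect_true(all(is.na(idx[en > 15])))
  expect_true(all(!is.na(idx[en <= 15])))
  expect_true(all(idx[!is.na(idx)] %in% m$index))
  ## one-well case: everything lands in the single basin
  one <- assign_basins(P[en <= 15, ], m[which.min(m$energy), ], sf)
  expect_true(all(one == m$index[which.min(m$energy)]))
})

test_that("representative snapshots sit at the basin centroid", {
  samples <- rbind(c(0, 0))
  expect_equal(representative_snapshot(1L, 1L, samples), 1L)
  ## symmetric pair: tie broken toward the lower index
  samples <- rbind(c(-1, 0), c(1, 0))
  expect_equal(representative_snapshot(c(1L, 1L), 1L, samples), 1L)
  ## Gaussian cloud: the representative is within 2 sigma / sqrt(n) of the
  ## centroid
  set.seed(77)
  n <- 1000; sigma <- 0.05
  cloud <- cbind(rnorm(n, 0.4, sigma), rnorm(n, -0.2, sigma))
  rs <- representative_snapshot(rep(1L, n), 1L, cloud)
  d <- sqrt(sum((cloud[rs, ] - colMeans(cloud))^2))
  expect_lt(d, 2 * sigma / sqrt(n) * sqrt(n) / 10)  # 0.2 sigma
  expect_error(representative_snapshot(rep(1L, n), 2L, cloud), "empty")
})

test_that("minima tables round-trip through CSV", {
  sf <- two_well()
  m <- find_minima(as_pmf_grid(grid_from_surface(sf, 61)))
  f <- tempfile(fileext = ".csv")
  write_minima(m, f)
  back <- read_minima(f)
  expect_equal(back$z1, m$z1, tolerance = 1e-12)
  expect_equal(back$energy, m$energy, tolerance = 1e-12)
  expect_s3_class(back, "fes_minima")
  unlink(f)
})
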