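## direct (Metropolis-free) sampler from exp(-F/kT) by inverse CDF on a fine
## grid: an independent route to equilibrium samples for WHAM checks
direct_boltzmann_1d <- function(surface, n, temperature = 310, seed = 1) {
  zz <- seq(surface$boundaries[1, 1], surface$boundaries[1, 2],
            length.out = 20001)
  dens <- exp(-fes_value(surface, matrix(zz, ncol = 1)) / kT(temperature))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  set.seed(seed)
  u <- runif(n)
  stats::approx(cdf, zz, xout = u, ties = "ordered", rule = 2)$y
}

unbiased_window <- function(samples) {
  samples <- as.matrix(samples)
  colnames(samples) <- paste0("z", seq_len(ncol(samples)))
  structure(list(centers = rep(0, ncol(samples)), force_constant = 0,
                 samples = samples, n_samples = nrow(samples), seed = NA,
                 temperature = 310, acceptance_rate = NA),
            class = "umbrella_window")
}

test_that("windows are histogrammed with half-open bins and conserved counts", {
  w <- unbiased_window(c(0.25, 0.25, 0.75, 0.75))
  h <- histogram_windows(list(w), list(c(0, 0.5, 1)))
  expect_equal(h[[1]], c(2, 2))
  ## sample on an interior edge goes to the right bin
  h2 <- histogram_windows(list(unbiased_window(0.5)), list(c(0, 0.5, 1)))
  expect_equal(h2[[1]], c(0, 1))
  ## and the upper boundary closes the last bin
  h3 <- histogram_windows(list(unbiased_window(1.0)), list(c(0, 0.5, 1)))
  expect_equal(h3[[1]], c(0, 1))
  ## totals conserved on random data
  set.seed(8)
  w4 <- unbiased_window(runif(500))
  expect_equal(sum(histogram_windows(list(w4), list(seq(0, 1, 0.1)))[[1]]),
               500)
  expect_error(histogram_windows(list(unbiased_window(5)), list(c(0, 1))),
               "outside")
})

test_that("an unbiased window recovers the double-well barrier from its histogram", {
  dw <- double_well_1d(5, boundaries = c(-1.8, 1.8))
  z <- direct_boltzmann_1d(dw, 1e5, seed = 202)
  fit <- wham(list(unbiased_window(z)), n_bins = 100, temperature = 310)
  pmf <- fit$pmf
  mid <- pmf$midpoints[[1]]
  barrier <- pmf$free_energy[which.min(abs(mid))] -
    min(pmf$free_energy, na.rm = TRUE)
  expect_equal(barrier, 5, tolerance = 0.5 / 5)
  expect_equal(fit$offsets, 0)
})

test_that("duplicated windows leave the PMF and offsets unchanged", {
  dw <- double_well_1d(5)
  z <- direct_boltzmann_1d(dw, 2e4, seed = 7)
  w <- unbiased_window(z)
  f1 <- wham(list(w), n_bins = 60)
  f2 <- wham(list(w, w), n_bins = 60, boundaries = f1$boundaries)
  expect_equal(f2$pmf$free_energy, f1$pmf$free_energy, tolerance = 1e-8)
  expect_equal(f2$offsets[1], f2$offsets[2], tolerance = 1e-8)
})

test_that("a 23-window chain recovers the analytic double well within 1 kJ/mol RMSE", {
  a <- 20
  dw <- function_surface(function(z) a * (z[1]^2 - 1)^2,
                         grad = function(z) 4 * a * z[1] * (z[1]^2 - 1),
                         matrix(c(-1.6, 1.6), nrow = 1))
  plan <- plan_windows(matrix(c(-1.1, 1.1), nrow = 1), 0.1)
  expect_equal(nrow(plan$centers), 23L)
  ws <- sample_windows(dw, plan, n_samples = 5000, force_constant = 1000,
                       seed = 51)
  fit <- wham(ws, n_bins = 100, tolerance = 1e-6)
  pmf <- fit$pmf
  ok <- pmf$counts >= 50 & !is.na(pmf$free_energy)
  ref <- fes_value(dw, matrix(pmf$midpoints[[1]], ncol = 1))
  ref <- ref - min(ref[ok])
  rmse <- sqrt(mean((pmf$free_energy[ok] - ref[ok])^2))
  expect_lt(rmse, 1)
  expect_lt(fit$final_change, 1e-6)
})

test_that("WHAM converges to the same answer with and without the warm start", {
  dw <- double_well_1d(8)
  plan <- plan_windows(matrix(c(-1.2, 1.2), nrow = 1), 0.2)
  ws <- sample_windows(dw, plan, n_samples = 800, force_constant = 500,
                       seed = 9)
  fa <- wham(ws, n_bins = 40, accelerate = TRUE)
  fb <- wham(ws, n_bins = 40, accelerate = FALSE)
  expect_equal(fa$pmf$free_energy, fb$pmf$free_energy, tolerance = 1e-4)
  expect_equal(fa$offsets, fb$offsets, tolerance = 1e-4)
})

test_that("shifting samples and centers translates the PMF axes only", {
  dw <- double_well_1d(6)
  plan <- plan_windows(matrix(c(-1.2, 1.2), nrow = 1), 0.2)
  ws <- sample_windows(dw, plan, n_samples = 500, force_constant = 500,
                       seed = 13)
  shift <- 2.5
  ws2 <- lapply(ws, function(w) {
    w$centers <- w$centers + shift
    w$samples <- w$samples + shift
    w
  })
  f1 <- wham(ws, n_bins = 50)
  f2 <- wham(ws2, n_bins = 50)
  expect_equal(f2$pmf$axes[[1]], f1$pmf$axes[[1]] + shift, tolerance = 1e-12)
  expect_equal(f2$pmf$free_energy, f1$pmf$free_energy, tolerance = 1e-6)
})

test_that("probabilities are conserved and empty windows are no-ops", {
  dw <- double_well_1d(5)
  plan <- plan_windows(matrix(c(-1.1, 1.1), nrow = 1), 0.2)
  ws <- sample_windows(dw, plan, n_samples = 400, force_constant = 500,
                       seed = 17)
  f1 <- wham(ws, n_bins = 40)
  expect_equal(sum(f1$pmf$prob), 1, tolerance = 1e-12)
  empty <- unbiased_window(matrix(numeric(0), ncol = 1))
  f2 <- wham(c(ws, list(empty)), n_bins = 40, boundaries = f1$boundaries)
  ## agreement up to the 1e-6 kJ/mol convergence tolerance of the offsets
  expect_equal(f2$pmf$free_energy, f1$pmf$free_energy, tolerance = 1e-5)
})

test_that("recovered PMF error shrinks as samples per window grow", {
  a <- 12
  dw <- function_surface(function(z) a * (z[1]^2 - 1)^2,
                         grad = function(z) 4 * a * z[1] * (z[1]^2 - 1),
                         matrix(c(-1.5, 1.5), nrow = 1))
  plan <- plan_windows(matrix(c(-1.1, 1.1), nrow = 1), 0.1)
  rmse_at <- function(n, seed) {
    ws <- sample_windows(dw, plan, n_samples = n, force_constant = 1000,
                         seed = seed)
    pmf <- wham(ws, n_bins = 80)$pmf
    ok <- pmf$counts >= 20 & !is.na(pmf$free_energy)
    ref <- fes_value(dw, matrix(pmf$midpoints[[1]], ncol = 1))
    ref <- ref - min(ref[ok])
    sqrt(mean((pmf$free_energy[ok] - ref[ok])^2))
  }
  expect_lt(rmse_at(4000, 23), rmse_at(250, 23))
})

test_that("non-overlapping window clusters are flagged", {
  flat <- function_surface(function(z) 0, grad = function(z) 0 * z,
                           matrix(c(-10, 10), nrow = 1))
  w1 <- sample_window(flat, -8, 5000, n_samples = 300, seed = 1)
  w2 <- sample_window(flat, 8, 5000, n_samples = 300, seed = 2)
  expect_warning(wham(list(w1, w2), n_bins = 50), "non-overlapping")
})

test_that("hitting the iteration cap raises a convergence error with state", {
  dw <- double_well_1d(5)
  plan <- plan_windows(matrix(c(-1.1, 1.1), nrow = 1), 0.2)
  ws <- sample_windows(dw, plan, n_samples = 300, force_constant = 500,
                       seed = 3)
  err <- tryCatch(
    wham(ws, n_bins = 40, max_iterations = 2, accelerate = FALSE),
    ionpmf_convergence_error = function(e) e)
  expect_s3_class(err, "ionpmf_convergence_error")
  expect_equal(err$n_iterations, 2L)
  expect_true(is.finite(err$final_change))
})
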