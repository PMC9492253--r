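## profile with hand-set markers for curvature-fit tests
curvature_profile <- function(f, lam = seq(0, 1, by = 0.005), markers) {
  fake_profile(lam, f(lam), markers)
}

test_that("cubic fits recover exact quadratic curvature", {
  ## F = a (lambda - 0.5)^2 / 2 with a = 100 -> omega = 10
  a <- 100
  pr <- curvature_profile(
    function(l) a * (l - 0.5)^2 / 2,
    markers = data.frame(kind = "valley", lambda = 0.5, energy = 0,
                         state = 1))
  ex <- fit_curvature(pr, 0.5, window = 0.1)
  expect_equal(ex$omega, 10, tolerance = 1e-8)
  expect_equal(ex$lambda, 0.5, tolerance = 1e-10)
  expect_equal(ex$fit_residual, 0, tolerance = 1e-10)

  ## peaks must curve down; misclassification is a classed error
  pr2 <- curvature_profile(
    function(l) -a * (l - 0.5)^2 / 2,
    markers = data.frame(kind = "peak", lambda = 0.5, energy = 0, state = 1))
  expect_equal(fit_curvature(pr2, 0.5, window = 0.1)$omega, 10,
               tolerance = 1e-8)
  expect_error(fit_curvature(pr2, 0.5, window = 0.1, kind = "valley"),
               class = "ionpmf_classification_error")
})

test_that("quartic contamination vanishes as the fit window shrinks", {
  a <- 80; b <- 500
  pr <- curvature_profile(
    function(l) a * (l - 0.5)^2 / 2 + b * (l - 0.5)^4,
    lam = seq(0, 1, by = 0.002),
    markers = data.frame(kind = "valley", lambda = 0.5, energy = 0,
                         state = 1))
  errs <- vapply(c(0.2, 0.1, 0.05), function(w)
    abs(fit_curvature(pr, 0.5, window = w)$omega - sqrt(a)), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05 * sqrt(a))
})

test_that("curvature fits tolerate measurement noise", {
  a <- 150
  set.seed(41)
  lam <- seq(0, 1, by = 0.005)
  y <- a * (lam - 0.5)^2 / 2 + rnorm(length(lam), sd = 0.1)
  pr <- fake_profile(lam, y, data.frame(kind = "valley", lambda = 0.5,
                                        energy = 0, state = 1))
  ex <- fit_curvature(pr, 0.5, window = 0.15)
  expect_equal(ex$omega, sqrt(a), tolerance = 0.1)
  expect_gt(ex$fit_residual, 0.05)
  ## too few points in the window is an error
  expect_error(fit_curvature(pr, 0.5, window = 0.009), "5 profile points")
})

test_that("Kramers rates follow the closed form in log space", {
  expect_equal(kramers_rate(1, 1, 0, kT = 2.577), 1 / (2 * pi),
               tolerance = 1e-12)
  expect_equal(kramers_rate(1, 1, 2.577, kT = 2.577), exp(-1) / (2 * pi),
               tolerance = 1e-12)
  ## high-barrier value against independent arithmetic
  expect_equal(kramers_rate(2, 3, 44, kT = 2.577),
               6 / (2 * pi) * exp(-44 / 2.577), tolerance = 1e-12)
  ## log form stays finite where the plain rate underflows
  lr <- kramers_rate(1, 1, 500 * 2.577, kT = 2.577, log = TRUE)
  expect_true(is.finite(lr))
  expect_equal(lr, -log(2 * pi) - 500, tolerance = 1e-10)
  expect_error(kramers_rate(1, 1, -1, kT = 2.577), "negative barrier")
})

## smooth multi-well profile in lambda as a Gaussian mixture: wells are
## stationary at their centers, so curvature fits are well-posed everywhere
smooth_profile <- function(well_pos, well_depth, bump_pos = numeric(0),
                           bump_amp = numeric(0), w = 0.15, bw = 0.08) {
  lam <- seq(min(well_pos), max(well_pos), by = 0.002)
  f <- function(l) {
    v <- rep(0, length(l))
    for (i in seq_along(well_pos))
      v <- v - well_depth[i] * exp(-(l - well_pos[i])^2 / (2 * w^2))
    for (i in seq_along(bump_pos))
      v <- v + bump_amp[i] * exp(-(l - bump_pos[i])^2 / (2 * bw^2))
    v
  }
  project_1d(fake_path(lam, f(lam)), min_prominence = 0.2)
}

test_that("rate chains respect symmetry and detailed-balance algebra", {
  pr <- smooth_profile(c(0, 1), c(10, 10))
  ch <- build_chain(pr, temperature = 310, fit_window = 0.08)
  expect_equal(nrow(ch$rates), 2L)
  fwd <- ch$rates$rate[ch$rates$to == 2]
  bwd <- ch$rates$rate[ch$rates$to == 1]
  expect_equal(fwd, bwd, tolerance = 1e-4)

  ## asymmetric wells: r_f / r_b = (omega_1 / omega_2) exp(-delta / kT)
  pr2 <- smooth_profile(c(0, 1), c(8, 13))
  ch2 <- build_chain(pr2, temperature = 310, fit_window = 0.08)
  om <- vapply(ch2$valleys, `[[`, numeric(1), "omega")
  f2 <- ch2$rates[ch2$rates$to == 2, ]
  b2 <- ch2$rates[ch2$rates$to == 1, ]
  delta <- b2$barrier - f2$barrier        # = E(v1) - E(v2) = +5
  expect_equal(f2$rate / b2$rate, (om[1] / om[2]) * exp(delta / kT(310)),
               tolerance = 1e-6)

  ## five-valley profile carries 8 rates (4 forward, 4 backward)
  pr5 <- smooth_profile(0:4, c(5, 7, 6, 9, 10))
  ch5 <- build_chain(pr5, temperature = 310, fit_window = 0.1)
  expect_equal(ch5$n_states, 5L)
  expect_equal(nrow(ch5$rates), 8L)
})

test_that("the chain ODE matches closed forms and the matrix exponential", {
  ## 2-state: p2(t) = 1 - exp(-r t)
  ch <- rate_chain_from_rates(fwd = 0.8, bwd = 0)
  occ <- solve_chain(ch)
  expect_equal(occ$p[, 2], 1 - exp(-0.8 * occ$time), tolerance = 1e-7)
  expect_lt(occ$conservation_error, 1e-6)

  ## 3-state chain, all rates 1, against Matrix::expm
  ch3 <- rate_chain_from_rates(fwd = c(1, 1), bwd = c(1, 0))
  occ3 <- solve_chain(ch3)
  M <- matrix(0, 3, 3)
  M[1, 1] <- -1; M[2, 1] <- 1
  M[1, 2] <- 1; M[2, 2] <- -2; M[3, 2] <- 1
  sel <- c(10, 100, 300, length(occ3$time))
  for (k in sel) {
    pk <- as.numeric(Matrix::expm(M * occ3$time[k]) %*% c(1, 0, 0))
    expect_equal(unname(occ3$p[k, ]), pk, tolerance = 1e-7)
  }

  ## without absorption the occupancies settle into detailed balance
  chs <- rate_chain_from_rates(fwd = c(2, 1), bwd = c(1, 4))
  occs <- solve_chain(chs, absorbing_last = FALSE, horizon = 5000)
  pT <- occs$p[nrow(occs$p), ]
  expect_equal(unname(pT[2] / pT[1]), 2 / 1, tolerance = 1e-4)
  expect_equal(unname(pT[3] / pT[2]), 1 / 4, tolerance = 1e-4)
})

test_that("total rates invert the analytic mean first-passage time", {
  ## 2-state chain: exact
  ch <- rate_chain_from_rates(fwd = 2.5, bwd = 0)
  expect_equal(total_rate(solve_chain(ch))$rate, 2.5, tolerance = 1e-4)

  ## 3-state forward chain with back-hopping: analytic birth-death MFPT
  ch3 <- rate_chain_from_rates(fwd = c(1.2, 0.4), bwd = c(0.7, 0))
  tr <- total_rate(solve_chain(ch3))
  mfpt <- 1 / 1.2 + 1 / 0.4 + 0.7 / (1.2 * 0.4)
  expect_equal(tr$mfpt, mfpt, tolerance = 0.01)

  ## a deep middle well makes its escape rate limiting
  chd <- rate_chain_from_rates(fwd = c(50, 1e-3), bwd = c(1e-4, 0))
  expect_equal(total_rate(solve_chain(chd))$rate, 1e-3, tolerance = 0.02)
})

test_that("random chains: quadrature MFPT matches the linear-solve oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    fwd <- exp(runif(n - 1, log(0.05), log(20)))
    bwd <- c(exp(runif(n - 2, log(0.05), log(20))), 0)
    ch <- rate_chain_from_rates(fwd, bwd)
    tr <- total_rate(solve_chain(ch))
    ref <- mfpt_linear_solve(fwd, bwd)
    expect_equal(tr$mfpt, ref, tolerance = 0.01)
    ## the rate-limiting bound is an upper bound on the total rate
    expect_gte(rate_limiting_bound(ch)$rate * (1 + 1e-9), tr$rate)
  }
})

test_that("total rate decreases monotonically with any forward barrier", {
  base <- c(5, 2, 1)
  rates <- vapply(c(1, 2, 4, 8), function(f) {
    ch <- rate_chain_from_rates(fwd = c(base[1], base[2] / f, base[3]),
                                bwd = c(0.5, 0.5, 0))
    total_rate(solve_chain(ch))$rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("the overflow policy reports a flagged bound instead of crashing", {
  kt <- kT(310)
  ## first hop with a ~100 kT barrier: rate dynamic range beyond doubles
  pr <- smooth_profile(c(0, 1, 2), c(2, 4, 6),
                       bump_pos = c(0.5, 1.5), bump_amp = c(100 * kt, 8))
  ch <- build_chain(pr, temperature = 310, fit_window = 0.06)
  expect_error(solve_chain(ch), class = "ionpmf_overflow_error")
  bound <- rate_limiting_bound(ch)
  expect_true(bound$is_bound)
  expect_true(is.finite(bound$log_rate))
  expect_equal(bound$limiting_step, c(1, 2))

  ## compare_systems falls back to the bound and flags the ratio
  ref <- rate_chain_from_rates(fwd = c(1, 1), bwd = c(0.5, 0))
  tab <- compare_systems(list(na_like = ch, reference = ref),
                         reference = "reference")
  expect_equal(tab$bound[tab$system == "na_like"], "<=")
  expect_equal(tab$bound[tab$system == "reference"], "")
  expect_equal(tab$relative_rate[tab$system == "reference"], 1)
})

test_that("relative rates are log-safe and propagate bound flags", {
  r1 <- structure(list(rate = 1, log_rate = 0, is_bound = FALSE),
                  class = "ionpmf_rate")
  expect_equal(relative_rate(r1, r1)$value, 1)
  ## ratios stay finite for barrier differences of hundreds of kT
  tiny <- structure(list(rate = 0, log_rate = -600, is_bound = FALSE),
                    class = "ionpmf_rate")
  rr <- relative_rate(tiny, r1)
  expect_true(is.finite(rr$log_value))
  expect_equal(rr$log_value, -600)
  ## bound numerator flags "<="
  b <- structure(list(rate = 2, log_rate = log(2), is_bound = TRUE),
                 class = "ionpmf_rate")
  expect_equal(relative_rate(b, r1)$bound, "<=")
  expect_equal(relative_rate(r1, b)$bound, ">=")
  expect_error(relative_rate(0, r1), "zero")

  ## scaling every forward rate by exp(-1) scales a forward chain's total
  ## rate by exactly exp(-1)
  f <- c(3, 1, 0.5)
  ra <- total_rate(solve_chain(rate_chain_from_rates(f)))
  rb <- total_rate(solve_chain(rate_chain_from_rates(f * exp(-1))))
  expect_equal(relative_rate(rb, ra)$value, exp(-1), tolerance = 1e-3)
})

test_that("TST conversions reproduce conductance-rate-barrier relations", {
  ## 0.97 pS at 100 mV, one charge per event
  expect_equal(conductance_to_rate(0.97, 100, 1), 6.05e5, tolerance = 0.002)
  ## e = 1.602e-19 C: 1.602 pS at 100 mV is 1e6 ions/s
  expect_equal(conductance_to_rate(1.602176634, 100, 1), 1e6,
               tolerance = 1e-9)
  expect_error(conductance_to_rate(0, 100, 1))

  ## barrier from the lowest conductance estimate, at 298 K, rounds to 40
  expect_equal(round(rate_to_barrier_tst(6.05e5, 298)), 40)
  ## at the simulation temperature the same rate maps to ~41.7 kJ/mol
  expect_equal(rate_to_barrier_tst(6.05e5, 310), 41.7, tolerance = 0.002)
  ## a rate at the prefactor has zero barrier
  kBT_h <- 1.380649e-23 * 298 / 6.62607015e-34
  expect_equal(rate_to_barrier_tst(kBT_h, 298), 0, tolerance = 1e-10)
  expect_warning(rate_to_barrier_tst(kBT_h * 10, 298), "negative")

  ## exact round trip
  for (b in c(5, 20, 40, 80)) {
    expect_equal(rate_to_barrier_tst(barrier_to_rate_tst(b, 310), 310), b,
                 tolerance = 1e-10)
  }
})
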