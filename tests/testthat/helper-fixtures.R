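## shared fixtures and independent oracles for the test suite

## 2D two-well surface used across NEB / basin tests
two_well <- function(depth = 20, separation = 2, width = 0.3, ...) {
  preset_double_well_2d(depth, separation, width, ...)
}

## independent minimax oracle: threshold bisection + flood fill on a dense
## grid (no graph library, no NEB) — used to validate saddle heights
flood_minimax <- function(surface, a, b, n = 161, n_iter = 40) {
  bx <- surface$boundaries
  xs <- seq(bx[1, 1], bx[1, 2], length.out = n)
  ys <- seq(bx[2, 1], bx[2, 2], length.out = n)
  Fv <- matrix(fes_value(surface, cbind(rep(xs, times = n),
                                        rep(ys, each = n))), n, n)
  ia <- c(which.min(abs(xs - a[1])), which.min(abs(ys - a[2])))
  ib <- c(which.min(abs(xs - b[1])), which.min(abs(ys - b[2])))
  connected_below <- function(thr) {
    open <- Fv <= thr
    if (!open[ia[1], ia[2]] || !open[ib[1], ib[2]]) return(FALSE)
    seen <- matrix(FALSE, n, n)
    queue <- matrix(ia, ncol = 2)
    seen[ia[1], ia[2]] <- TRUE
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        i <- cur[1] + dx; j <- cur[2] + dy
        if (i < 1 || i > n || j < 1 || j > n) next
        if (seen[i, j] || !open[i, j]) next
        if (i == ib[1] && j == ib[2]) return(TRUE)
        seen[i, j] <- TRUE
        queue <- rbind(queue, c(i, j))
      }
    }
    FALSE
  }
  lo <- max(Fv[ia[1], ia[2]], Fv[ib[1], ib[2]])
  hi <- max(Fv)
  for (k in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (connected_below(mid)) hi <- mid else lo <- mid
  }
  hi  # minimax crossing energy
}

## analytic equilibrium CDF of a 1D surface at temperature T (fine-grid
## quadrature), for sampler distribution checks
boltzmann_cdf_1d <- function(surface, temperature = 310, n = 4001) {
  zz <- seq(surface$boundaries[1, 1], surface$boundaries[1, 2],
            length.out = n)
  dens <- exp(-fes_value(surface, matrix(zz, ncol = 1)) / kT(temperature))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  function(x) stats::approx(zz, cdf, xout = x, rule = 2)$y
}

## Kolmogorov-Smirnov distance of samples against a CDF function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  max(abs(cdf(x) - seq_len(n) / n), abs(cdf(x) - (seq_len(n) - 1) / n))
}

## evaluate an analytic surface on a regular grid as a pmf_grid-like object
grid_from_surface <- function(surface, n_bins = 100, boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- surface$boundaries
  axes <- lapply(1:2, function(dd)
    seq(boundaries[dd, 1], boundaries[dd, 2], length.out = n_bins + 1))
  mids <- lapply(axes, function(e) (e[-1] + e[-length(e)]) / 2)
  P <- cbind(rep(mids[[1]], times = n_bins), rep(mids[[2]], each = n_bins))
  Fm <- matrix(fes_value(surface, P), n_bins, n_bins)
  Fm <- Fm - min(Fm)
  list(axes = axes, midpoints = mids, free_energy = Fm,
       counts = matrix(1, n_bins, n_bins), prob = NULL,
       temperature = 310, dim = 2L)
}

## make a pmf_grid object (class attached) from plain pieces
as_pmf_grid <- function(g) structure(g, class = "pmf_grid")

## straight-line mfep_path with prescribed energies (for profile/rate tests)
fake_path <- function(lambda, energies, converged = TRUE) {
  structure(list(nodes = cbind(lambda, 0), energies = energies,
                 endpoints = rbind(c(lambda[1], 0),
                                   c(lambda[length(lambda)], 0)),
                 converged = converged, max_force_residual = 0,
                 n_iterations = 0L),
            class = "mfep_path")
}

## minimal profile object for curvature-fit tests (markers supplied by hand)
fake_profile <- function(lambda, energies, markers) {
  structure(list(lambda = lambda, free_energy = energies,
                 spline = stats::splinefun(lambda, energies, method = "fmm"),
                 markers = markers, length = max(lambda), path = NULL),
            class = "fes_profile")
}

## analytic MFPT of a birth-death chain by first-step linear solve
## (independent of the ODE integration route)
mfpt_linear_solve <- function(fwd, bwd) {
  n <- length(fwd) + 1L
  ## generator over transient states 1..n-1, absorbing n
  Q <- matrix(0, n - 1L, n - 1L)
  for (i in seq_len(n - 1L)) {
    out <- fwd[i] + if (i > 1L) bwd[i - 1L] else 0
    Q[i, i] <- -out
    if (i > 1L) Q[i, i - 1L] <- bwd[i - 1L]
    if (i < n - 1L) Q[i, i + 1L] <- fwd[i]
  }
  ## rows are "from" states: tau = solve(Q, -1)
  tau <- solve(Q, rep(-1, n - 1L))
  tau[1]
}
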