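#' Umbrella-window planning and biased sampling
#'
#' Umbrella sampling tiles CV space with harmonically restrained windows
#' (U_bias = 1/2 k (z - z0)^2 per CV, the standard pull-code convention; the
#' WHAM unbiasing uses the identical convention). Window centers sit on a
#' regular grid; the default spacing of 0.1 nm and force constant of
#' 1000 kJ/mol/nm^2 match common practice for ion-permeation PMFs.
#'
#' @name windows
NULL

#' Plan a regular grid of umbrella windows
#'
#' @param boundaries per-CV `c(low, high)` ranges in nm (d x 2 matrix or
#'   list).
#' @param spacing window spacing in nm (default 0.1).
#' @return an object of class `window_plan`: list with `boundaries`,
#'   `spacing` and `centers` (n x d matrix). Both bounds are included when
#'   they are grid-aligned.
#' @examples
#' plan_windows(rbind(c(-0.35, 1.85), c(-1.55, 0.55)), 0.1)  # 506 windows
#' @export
plan_windows <- function(boundaries, spacing = 0.1) {
  boundaries <- .as_boundaries(boundaries)
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  axes <- lapply(seq_len(nrow(boundaries)), function(dd) {
    lo <- boundaries[dd, 1]; hi <- boundaries[dd, 2]
    n <- floor((hi - lo) / spacing + 1e-9)
    if (n < 1L)
      stop("spacing larger than the CV range", call. = FALSE)
    lo + spacing * (0:n)
  })
  centers <- as.matrix(expand.grid(axes))
  dimnames(centers) <- list(NULL, paste0("z", seq_len(nrow(boundaries))))
  structure(list(boundaries = boundaries, spacing = spacing,
                 centers = centers),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %d windows, spacing %.3g nm, %dD\n",
              nrow(x$centers), x$spacing, ncol(x$centers)))
  invisible(x)
}

#' Adaptive window planning by breadth-first expansion
#'
#' A reduced stand-in for self-learning umbrella sampling: starting from a
#' seed window, grid neighbors are added whenever the surface value at the
#' candidate center lies below `energy_cutoff`, so the plan grows to cover
#' exactly the thermally relevant corridor. Uses the true synthetic surface;
#' for measured data the full regular grid applies instead.
#'
#' @param surface a `fes_surface`.
#' @param start CV point (snapped to the grid) from which expansion begins.
#' @param energy_cutoff kJ/mol; candidate centers with F below this are kept.
#' @param spacing grid spacing in nm.
#' @param boundaries optional domain; defaults to the surface domain.
#' @return a `window_plan` whose centers are a subset of
#'   `plan_windows(boundaries, spacing)`.
#' @export
plan_windows_adaptive <- function(surface, start, energy_cutoff,
                                  spacing = 0.1, boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- surface$boundaries
  boundaries <- .as_boundaries(boundaries)
  d <- nrow(boundaries)
  start <- as.numeric(start)
  stopifnot(length(start) == d)
  lo <- boundaries[, 1]; hi <- boundaries[, 2]
  nmax <- floor((hi - lo) / spacing + 1e-9)

  idx0 <- round((start - lo) / spacing)
  idx0 <- pmin(pmax(idx0, 0), nmax)
  center_of <- function(idx) lo + idx * spacing
  if (fes_value(surface, center_of(idx0)) >= energy_cutoff)
    stop("energy_cutoff below the surface value at the start window: ",
         "empty plan", call. = FALSE)

  key <- function(idx) paste(idx, collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(idx0), TRUE, envir = seen)
  accepted <- list(idx0)
  frontier <- list(idx0)
  steps <- diag(d)
  while (length(frontier)) {
    nxt <- list()
    for (idx in frontier) {
      for (dd in seq_len(d)) for (s in c(-1, 1)) {
        cand <- idx + s * steps[dd, ]
        if (any(cand < 0) || any(cand > nmax)) next
        k <- key(cand)
        if (exists(k, envir = seen, inherits = FALSE)) next
        assign(k, TRUE, envir = seen)
        if (fes_value(surface, center_of(cand)) < energy_cutoff) {
          accepted[[length(accepted) + 1L]] <- cand
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    frontier <- nxt
  }
  centers <- t(vapply(accepted, center_of, numeric(d)))
  centers <- centers[do.call(order, rev(as.data.frame(centers))), ,
                     drop = FALSE]
  dimnames(centers) <- list(NULL, paste0("z", seq_len(d)))
  structure(list(boundaries = boundaries, spacing = spacing,
                 centers = centers),
            class = "window_plan")
}

#' Sample one umbrella window by Metropolis-Hastings Monte Carlo
#'
#' Draws samples from the biased Boltzmann density
#' p(z) ~ exp(-(F(z) + sum_d 1/2 k (z_d - z0_d)^2) / kT). Only the
#' stationary distribution matters for WHAM, so a Monte Carlo chain replaces
#' Langevin dynamics: it is simpler and exactly seedable. The proposal is a
#' mixture of a local Gaussian random walk and (for biased windows) an
#' occasional independence draw from the bias distribution
#' N(z0, sqrt(kT/k)); the global component lets the chain cross free-energy
#' features inside a window (the regions of low sampling efficiency that
#' otherwise call for much longer runs), with the exact Hastings correction
#' so the stationary density is untouched. Proposals leaving the declared
#' domain are rejected, which keeps all samples inside it.
#'
#' @param surface a `fes_surface`.
#' @param centers bias center z0 per CV (nm).
#' @param force_constant harmonic bias k in kJ/mol/nm^2 (same k on every CV);
#'   default 1000.
#' @param n_samples number of retained samples (after burn-in removal).
#' @param burn_in number of discarded initial steps; default 10% of
#'   `n_samples`.
#' @param step_size local proposal standard deviation in nm; default
#'   `sqrt(kT/k)` (the bias width) or 0.1 nm for an unbiased window.
#' @param global_fraction probability of an independence proposal from the
#'   bias distribution (default 0.1; forced to 0 for unbiased windows).
#' @param temperature K, default 310.
#' @param seed integer; the chain is bit-reproducible for a fixed seed.
#' @return an object of class `umbrella_window`: list with `centers`,
#'   `force_constant`, `samples` (n x d matrix), `n_samples`, `seed`,
#'   `temperature`, `acceptance_rate`.
#' @export
sample_window <- function(surface, centers, force_constant = 1000,
                          n_samples, burn_in = NULL, step_size = NULL,
                          global_fraction = 0.1, temperature = 310, seed) {
  stopifnot(n_samples > 0, force_constant >= 0)
  d <- surface$dim
  centers <- as.numeric(centers)
  stopifnot(length(centers) == d)
  if (is.null(burn_in)) burn_in <- ceiling(0.1 * n_samples)
  kt <- kT(temperature)
  if (is.null(step_size))
    step_size <- if (force_constant > 0) sqrt(kt / force_constant) else 0.1
  stopifnot(step_size > 0, burn_in >= 0)
  lo <- surface$boundaries[, 1]; hi <- surface$boundaries[, 2]

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))

  f_of <- .fast_value_fn(surface)
  u_of <- function(z)
    f_of(z) + 0.5 * force_constant * sum((z - centers)^2)

  wg <- if (force_constant > 0) global_fraction else 0
  sig_g <- if (force_constant > 0) sqrt(kt / force_constant) else NA_real_
  ## proposal density (for the Hastings ratio of the mixture kernel)
  log_q <- function(from, to) {
    loc <- exp(-sum((to - from)^2) / (2 * step_size^2)) / step_size^d
    if (wg > 0) {
      glob <- exp(-sum((to - centers)^2) / (2 * sig_g^2)) / sig_g^d
      log((1 - wg) * loc + wg * glob)
    } else log(loc)
  }

  z <- pmin(pmax(centers, lo), hi)
  u <- u_of(z)
  total <- n_samples + burn_in
  out <- matrix(NA_real_, n_samples, d)
  ## pre-draw all random numbers: one pass, fully reproducible
  use_global <- stats::runif(total) < wg
  prop_loc <- matrix(stats::rnorm(total * d, sd = step_size), total, d)
  prop_glb <- if (wg > 0)
    matrix(stats::rnorm(total * d, sd = sig_g), total, d) else NULL
  lu <- log(stats::runif(total))
  n_acc <- 0L
  for (i in seq_len(total)) {
    zn <- if (use_global[i]) centers + prop_glb[i, ] else z + prop_loc[i, ]
    if (all(zn >= lo) && all(zn <= hi)) {
      un <- u_of(zn)
      lr <- (u - un) / kt
      if (wg > 0 || use_global[i]) lr <- lr + log_q(zn, z) - log_q(z, zn)
      if (lu[i] < lr) {
        z <- zn; u <- un; n_acc <- n_acc + 1L
      }
    }
    if (i > burn_in) out[i - burn_in, ] <- z
  }
  acc <- n_acc / total
  if (acc < 0.01)
    warning(sprintf(
      "window at (%s): acceptance rate %.2f%% < 1%%; consider a smaller step_size",
      paste(format(centers, digits = 3), collapse = ", "), 100 * acc),
      call. = FALSE)
  colnames(out) <- paste0("z", seq_len(d))
  structure(list(centers = centers, force_constant = force_constant,
                 samples = out, n_samples = n_samples,
                 seed = as.integer(seed), temperature = temperature,
                 acceptance_rate = acc),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "<umbrella_window> center (%s) nm, k = %g kJ/mol/nm^2, %d samples (acc %.0f%%)\n",
    paste(format(x$centers, digits = 3), collapse = ", "),
    x$force_constant, x$n_samples, 100 * x$acceptance_rate))
  invisible(x)
}

## single-point evaluator without matrix dispatch overhead (sampler hot path)
.fast_value_fn <- function(surface) {
  if (inherits(surface, "fes_surface") && surface$kind == "gaussian") {
    amp <- surface$amp
    C <- surface$centers
    S2i <- 1 / (2 * surface$widths^2)
    off <- surface$baseline - surface$shift
    if (surface$dim == 1L) {
      c1 <- C[, 1]; w1 <- S2i[, 1]
      function(z) off + sum(amp * exp(-(z - c1)^2 * w1))
    } else {
      c1 <- C[, 1]; c2 <- C[, 2]; w1 <- S2i[, 1]; w2 <- S2i[, 2]
      function(z) off + sum(amp * exp(-((z[1] - c1)^2 * w1 +
                                          (z[2] - c2)^2 * w2)))
    }
  } else {
    function(z) fes_value(surface, z)
  }
}

#' Sample every window of a plan
#'
#' Per-window seeds are derived as `seed + window index`, so any window set
#' is independently reproducible from one root seed.
#'
#' @param surface a `fes_surface`.
#' @param plan a `window_plan`.
#' @param seed root integer seed.
#' @inheritParams sample_window
#' @return list of `umbrella_window` objects.
#' @export
sample_windows <- function(surface, plan, n_samples, force_constant = 1000,
                           burn_in = NULL, step_size = NULL,
                           global_fraction = 0.1, temperature = 310, seed) {
  lapply(seq_len(nrow(plan$centers)), function(i)
    sample_window(surface, plan$centers[i, ], force_constant, n_samples,
                  burn_in, step_size, global_fraction, temperature,
                  seed = as.integer(seed) + i))
}
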