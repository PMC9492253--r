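#' Weighted histogram analysis method (WHAM)
#'
#' Combines the biased histograms of many harmonic umbrella windows into one
#' unbiased potential of mean force. The self-consistent equations
#'   p_i = n_i / sum_k N_k exp((f_k - U_k(x_i)) / kT)
#'   exp(-f_k / kT) = sum_i exp(-U_k(x_i) / kT) p_i
#' are iterated until the largest change of any window offset f_k falls below
#' the convergence tolerance (in kJ/mol). A convex-optimization warm start on
#' the equivalent maximum-likelihood objective precedes the fixed-point
#' iterations, which typically cuts the iteration count by orders of
#' magnitude; the converged result is identical.
#'
#' @name wham
NULL

## --- binning ----------------------------------------------------------------

.bin_axes <- function(boundaries, n_bins) {
  lapply(seq_len(nrow(boundaries)), function(dd)
    seq(boundaries[dd, 1], boundaries[dd, 2], length.out = n_bins[dd] + 1L))
}

## half-open bins [low, high), last bin closed; returns NA for out-of-range
.bin_index_1d <- function(x, edges) {
  n <- length(edges) - 1L
  lo <- edges[1]; hi <- edges[n + 1L]
  w <- (hi - lo) / n
  i <- floor((x - lo) / w) + 1L
  i[x == hi] <- n
  i[x < lo | x > hi] <- NA_integer_
  as.integer(i)
}

## flat (column-major) bin index for an n x d sample matrix; NA if any CV
## falls outside its axis
.flat_bin_index <- function(samples, axes) {
  d <- length(axes)
  nb <- vapply(axes, function(e) length(e) - 1L, integer(1))
  idx <- .bin_index_1d(samples[, 1], axes[[1]])
  if (d > 1L) {
    mult <- 1L
    for (dd in 2:d) {
      mult <- mult * nb[dd - 1L]
      idx <- idx + mult * (.bin_index_1d(samples[, dd], axes[[dd]]) - 1L)
    }
  }
  idx
}

#' Histogram umbrella windows on a shared grid
#'
#' @param windows list of `umbrella_window` objects.
#' @param bin_edges list of strictly increasing bin-edge vectors, one per CV.
#' @return list of per-window count arrays (vectors for 1D, matrices for 2D).
#'   Counts sum to the window's sample count unless samples fall outside the
#'   edges; out-of-range samples are dropped with a message.
#' @export
histogram_windows <- function(windows, bin_edges) {
  stopifnot(length(windows) >= 1L)
  if (!is.list(bin_edges) || is.numeric(bin_edges))
    bin_edges <- list(bin_edges)
  nb <- vapply(bin_edges, function(e) length(e) - 1L, integer(1))
  total_bins <- prod(nb)
  dropped <- 0L
  out <- lapply(windows, function(w) {
    idx <- .flat_bin_index(w$samples, bin_edges)
    dropped <<- dropped + sum(is.na(idx))
    counts <- tabulate(idx[!is.na(idx)], nbins = total_bins)
    if (length(nb) > 1L) array(counts, dim = nb) else counts
  })
  if (dropped > 0L)
    message(sprintf("histogram_windows: %d samples outside bin range dropped",
                    dropped))
  if (all(vapply(out, sum, numeric(1)) == 0))
    stop("all samples fall outside the bin range", call. = FALSE)
  out
}

## --- PMF grid container ------------------------------------------------------

.new_pmf_grid <- function(axes, free_energy, counts, prob, temperature) {
  structure(list(axes = axes,
                 midpoints = lapply(axes, function(e)
                   (e[-1] + e[-length(e)]) / 2),
                 free_energy = free_energy, counts = counts, prob = prob,
                 temperature = temperature,
                 dim = length(axes)),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  nb <- vapply(x$axes, function(e) length(e) - 1L, integer(1))
  cat(sprintf("<pmf_grid> %s bins, %d sampled, T = %g K\n",
              paste(nb, collapse = " x "), sum(x$counts > 0), x$temperature))
  fr <- range(x$free_energy[x$counts > 0])
  cat(sprintf("  free energy range [%.2f, %.2f] kJ/mol\n", fr[1], fr[2]))
  invisible(x)
}

#' @export
plot.pmf_grid <- function(x, levels = seq(0, 50, by = 5), ...) {
  if (x$dim == 2L) {
    graphics::filled.contour(
      x$midpoints[[1]], x$midpoints[[2]], x$free_energy,
      levels = levels, xlab = "z1 (nm)", ylab = "z2 (nm)",
      color.palette = grDevices::hcl.colors, ...)
  } else {
    graphics::plot(x$midpoints[[1]], x$free_energy, type = "l",
                   xlab = "z (nm)", ylab = "F (kJ/mol)", ...)
  }
  invisible(x)
}

## --- WHAM core ---------------------------------------------------------------

#' Unbias umbrella windows into a potential of mean force
#'
#' @param windows list of `umbrella_window` objects sharing the CV
#'   dimensionality and bias convention (U = 1/2 k (z - z0)^2 per CV).
#'   Windows with identical centers are pooled as separate windows, the
#'   statistically correct treatment when merging independent runs.
#' @param n_bins bins per CV (default 100, recycled to the dimension).
#' @param tolerance convergence tolerance on max |delta f_k| in kJ/mol
#'   (default 1e-6).
#' @param max_iterations cap on fixed-point iterations.
#' @param temperature K (default 310).
#' @param boundaries bin range per CV; default: the range of window centers
#'   (so repeated runs share a grid), or the data extent where that range is
#'   degenerate (e.g. a single unbiased window).
#' @param accelerate if `TRUE` (default) run an L-BFGS-B warm start on the
#'   convex WHAM likelihood before the fixed-point iterations.
#' @return an object of class `wham_fit`: list with `pmf` (a `pmf_grid` with
#'   `free_energy` normalized to min 0 and `NA` on unsampled bins),
#'   `offsets` (f_k in kJ/mol relative to f_1 = 0), `n_iterations`,
#'   `final_change` (kJ/mol) and `converged`.
#' @export
wham <- function(windows, n_bins = 100L, tolerance = 1e-6,
                 max_iterations = 100000L, temperature = 310,
                 boundaries = NULL, accelerate = TRUE) {
  stopifnot(length(windows) >= 1L)
  d <- ncol(windows[[1]]$samples)
  if (!all(vapply(windows, function(w) ncol(w$samples), integer(1)) == d))
    stop("all windows must share the CV dimensionality", call. = FALSE)
  if (any(vapply(windows, function(w) nrow(w$samples), integer(1)) == 0) &&
      all(vapply(windows, function(w) nrow(w$samples), integer(1)) == 0))
    stop("all windows are empty", call. = FALSE)
  n_bins <- rep_len(as.integer(n_bins), d)
  if (any(n_bins < 1L)) stop("n_bins must be >= 1", call. = FALSE)
  kt <- kT(temperature)

  if (is.null(boundaries)) {
    ctr <- do.call(rbind, lapply(windows, `[[`, "centers"))
    boundaries <- t(apply(ctr, 2L, range))
    for (dd in seq_len(d)) {
      if (diff(boundaries[dd, ]) <= 0) {
        xs <- unlist(lapply(windows, function(w) w$samples[, dd]))
        boundaries[dd, ] <- range(xs)
      }
    }
  }
  boundaries <- .as_boundaries(boundaries)
  axes <- .bin_axes(boundaries, n_bins)
  total_bins <- prod(n_bins)

  K <- length(windows)
  N <- numeric(K)
  n_tot <- numeric(total_bins)
  win_bins <- vector("list", K)  # unique sampled bins per window
  dropped <- 0L
  for (k in seq_len(K)) {
    idx <- .flat_bin_index(windows[[k]]$samples, axes)
    dropped <- dropped + sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    N[k] <- length(idx)
    cnt <- tabulate(idx, nbins = total_bins)
    n_tot <- n_tot + cnt
    win_bins[[k]] <- which(cnt > 0L)
  }
  if (dropped > 0L)
    message(sprintf("wham: %d samples outside the bin range dropped", dropped))
  sampled <- which(n_tot > 0)
  if (!length(sampled))
    stop("no samples inside the bin range", call. = FALSE)

  ## warn on non-overlapping window clusters (offsets between clusters are
  ## then arbitrary)
  if (K > 1L) {
    parent <- seq_len(K)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    bin_owner <- integer(total_bins)
    for (k in seq_len(K)) {
      for (b in win_bins[[k]]) {
        if (bin_owner[b] == 0L) bin_owner[b] <- k
        else {
          ra <- find(k); rb <- find(bin_owner[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    live <- which(N > 0)
    ncomp <- length(unique(vapply(live, find, integer(1))))
    if (ncomp > 1L)
      warning(sprintf(
        "windows form %d non-overlapping clusters; relative offsets between clusters are unreliable",
        ncomp), call. = FALSE)
  }

  ## bias energies at sampled bin centers, in kT units: u[k, i]
  mids <- lapply(axes, function(e) (e[-1] + e[-length(e)]) / 2)
  coord <- matrix(0, length(sampled), d)
  tmp <- sampled - 1L
  for (dd in seq_len(d)) {
    coord[, dd] <- mids[[dd]][tmp %% n_bins[dd] + 1L]
    tmp <- tmp %/% n_bins[dd]
  }
  kk <- vapply(windows, `[[`, numeric(1), "force_constant")
  ctr <- do.call(rbind, lapply(windows, `[[`, "centers"))
  D2 <- matrix(0, K, length(sampled))
  for (dd in seq_len(d))
    D2 <- D2 + (outer(ctr[, dd], coord[, dd], "-"))^2
  C <- exp(-(0.5 * kk * D2) / kt)   # K x I bias factors
  rm(D2)
  n_i <- n_tot[sampled]

  ## a_k = f_k / kT. One full fixed-point update:
  fp_update <- function(a) {
    denom <- drop(crossprod(C, N * exp(a)))   # I
    p <- n_i / denom
    -log(drop(C %*% p))
  }

  a <- numeric(K)
  iter <- 0L
  if (accelerate && K > 1L) {
    obj <- function(a) {
      denom <- drop(crossprod(C, N * exp(a)))
      -sum(N * a) + sum(n_i * log(denom))
    }
    grd <- function(a) {
      denom <- drop(crossprod(C, N * exp(a)))
      p <- n_i / denom
      -N + N * exp(a) * drop(C %*% p)
    }
    op <- tryCatch(
      stats::optim(a, obj, grd, method = "L-BFGS-B",
                   control = list(maxit = 2000L, factr = 10)),
      error = function(e) NULL)
    if (!is.null(op)) a <- op$par - op$par[1]
  }

  change <- Inf
  while (iter < max_iterations) {
    a_new <- fp_update(a)
    a_new <- a_new - a_new[1]
    change <- kt * max(abs(a_new - a))
    a <- a_new
    iter <- iter + 1L
    if (change < tolerance) break
  }
  converged <- change < tolerance
  if (!converged) {
    cond <- structure(
      class = c("ionpmf_convergence_error", "error", "condition"),
      list(message = sprintf(
        "WHAM did not converge in %d iterations (last change %.3g kJ/mol)",
        max_iterations, change),
        call = sys.call(-1),
        offsets = kt * a, n_iterations = iter, final_change = change))
    stop(cond)
  }

  denom <- drop(crossprod(C, N * exp(a)))
  p <- n_i / denom
  p <- p / sum(p)
  Fb <- rep(NA_real_, total_bins)
  Fb[sampled] <- -kt * log(p)
  Fb <- Fb - min(Fb, na.rm = TRUE)
  pb <- rep(0, total_bins)
  pb[sampled] <- p
  if (d > 1L) {
    Fb <- array(Fb, dim = n_bins)
    pb <- array(pb, dim = n_bins)
    cnt_arr <- array(n_tot, dim = n_bins)
  } else {
    cnt_arr <- n_tot
  }

  structure(list(
    pmf = .new_pmf_grid(axes, Fb, cnt_arr, pb, temperature),
    offsets = kt * a,
    n_iterations = iter,
    final_change = change,
    converged = converged,
    n_samples = N,
    boundaries = boundaries),
    class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf(
    "<wham_fit> %d windows, %d iterations, final change %.2g kJ/mol\n",
    length(x$offsets), x$n_iterations, x$final_change))
  print(x$pmf)
  invisible(x)
}
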