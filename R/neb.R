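#' Nudged elastic band minimum free-energy paths
#'
#' A chain of images between two minima is relaxed under the projected NEB
#' force: the potential force perpendicular to the path plus a spring force
#' along it, with the improved-tangent scheme and a climbing image on the
#' highest interior node during the final stretch of the optimization, so the
#' top image converges onto the saddle point.
#'
#' @name neb
NULL

.as_cv_point <- function(p) {
  if (is.data.frame(p)) as.numeric(p[1, c("z1", "z2")])
  else as.numeric(p)
}

## resample a polyline to n nodes uniformly in arc length
.resample_path <- function(nodes, n) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  lam <- c(0, cumsum(seg))
  L <- lam[length(lam)]
  tt <- seq(0, L, length.out = n)
  out <- matrix(0, n, ncol(nodes))
  for (dd in seq_len(ncol(nodes)))
    out[, dd] <- stats::approx(lam, nodes[, dd], xout = tt, ties = "ordered")$y
  out
}

## straight-line seed; if it crosses a masked region of an interpolant,
## reroute through low-energy sampled grid cells
.seed_path <- function(surface, a, b, n_images) {
  tt <- seq(0, 1, length.out = n_images)
  seed <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  if (!inherits(surface, "fes_interpolant")) return(seed)
  if (all(is_interpolable(surface, seed))) return(seed)

  ## grid reroute: Dijkstra over cells whose full interpolation stencil is
  ## sampled, energy-weighted
  x <- surface$x; y <- surface$y
  nx <- length(x); ny <- length(y)
  Fv <- surface$padded[2:(nx + 1L), 2:(ny + 1L)]
  ok <- matrix(is_interpolable(surface,
                               cbind(rep(x, times = ny), rep(y, each = nx))),
               nx, ny)
  Fv[!ok] <- NA
  id <- matrix(seq_len(nx * ny), nx, ny)
  ed <- list(); wt <- list()
  base <- Fv - min(Fv, na.rm = TRUE) + 1e-3
  push <- function(i1, j1, i2, j2) {
    sel <- ok[cbind(i1, j1)] & ok[cbind(i2, j2)]
    ed[[length(ed) + 1L]] <<- cbind(id[cbind(i1, j1)][sel],
                                    id[cbind(i2, j2)][sel])
    wt[[length(wt) + 1L]] <<- (base[cbind(i1, j1)][sel] +
                                 base[cbind(i2, j2)][sel]) / 2
  }
  ii <- rep(seq_len(nx - 1L), ny);       jj <- rep(seq_len(ny), each = nx - 1L)
  push(ii, jj, ii + 1L, jj)
  ii <- rep(seq_len(nx), ny - 1L);       jj <- rep(seq_len(ny - 1L), each = nx)
  push(ii, jj, ii, jj + 1L)
  g <- igraph::graph_from_edgelist(do.call(rbind, ed), directed = FALSE)
  igraph::E(g)$weight <- unlist(wt)
  near <- function(p) id[which.min(abs(x - p[1])), which.min(abs(y - p[2]))]
  va <- near(a); vb <- near(b)
  if (!ok[va] || !ok[vb])
    .masked_error("path endpoint lies in an unsampled region")
  sp <- tryCatch(
    suppressWarnings(igraph::shortest_paths(g, va, vb)$vpath[[1]]),
    error = function(e) integer(0))
  if (length(sp) < 2L)
    .masked_error("no sampled route between path endpoints")
  vi <- as.integer(sp)
  nodes <- cbind(x[(vi - 1L) %% nx + 1L], y[(vi - 1L) %/% nx + 1L])
  nodes[1, ] <- a; nodes[nrow(nodes), ] <- b
  .resample_path(nodes, n_images)
}

#' Relax a minimum free-energy path between two minima
#'
#' @param surface a `fes_surface` or `fes_interpolant`.
#' @param start,end endpoint minima: CV points (length-2) or single rows of a
#'   `fes_minima` table. Must differ.
#' @param n_images number of images including endpoints (default 32).
#' @param spring_constant NEB spring constant in kJ/mol/nm^2 (default 500).
#' @param max_iterations optimizer budget (default 5000). The climbing image
#'   is switched on for the final 25% of the budget, or as soon as the
#'   regular band is converged.
#' @param force_tolerance convergence threshold on the largest perpendicular
#'   (and climbing) force in kJ/mol/nm (default 0.5; statistical gradient
#'   noise on histogrammed PMFs calls for a larger value).
#' @param seed_nodes optional matrix of initial images overriding the
#'   straight-line/rerouted seed (endpoints are still pinned).
#' @return an object of class `mfep_path`: list with `nodes` (n x 2),
#'   `energies`, `converged`, `max_force_residual`, `n_iterations`,
#'   `endpoints`.
#' @export
neb <- function(surface, start, end, n_images = 32L, spring_constant = 500,
                max_iterations = 5000L, force_tolerance = 0.5,
                seed_nodes = NULL) {
  a <- .as_cv_point(start); b <- .as_cv_point(end)
  if (sqrt(sum((a - b)^2)) < 1e-9)
    stop("start and end minima must differ", call. = FALSE)
  stopifnot(n_images >= 5L, spring_constant > 0)
  n <- as.integer(n_images)

  if (is.null(seed_nodes)) {
    X <- .seed_path(surface, a, b, n)
  } else {
    X <- .resample_path(seed_nodes, n)
    ## resampling can cut a corner into a masked pocket; the original nodes
    ## are known-evaluable, so fall back to them unchanged
    if (inherits(surface, "fes_interpolant") && !all(is_interpolable(surface, X))) {
      X <- seed_nodes
      n <- nrow(X)
    }
  }
  X[1, ] <- a; X[n, ] <- b

  eval_E <- function(P) fes_value(surface, P)
  eval_G <- function(P) fes_grad(surface, P)

  E <- eval_E(X); G <- eval_G(X)
  interior <- 2:(n - 1L)
  ## relaxation: projected steepest descent with a Barzilai-Borwein spectral
  ## step (self-scales to the local stiffness, which spans orders of
  ## magnitude between smooth analytic surfaces and histogram-noisy PMFs);
  ## per-node displacements are capped at half the median image spacing so
  ## no image can be ejected from the valley corridor
  cap0 <- 0.5 * stats::median(sqrt(rowSums(diff(X)^2)))
  dt0 <- sqrt(0.05 * cap0 / max(1, max(sqrt(rowSums(G^2)))))
  dt <- dt0
  X_prev <- NULL; F_prev <- NULL
  climb_after <- ceiling(0.75 * max_iterations)
  converged <- FALSE
  fmax <- Inf
  fhist <- rep(Inf, max_iterations)
  climbing <- FALSE
  iter <- 0L

  while (iter < max_iterations) {
    iter <- iter + 1L
    ## latch the climbing image on once the plain band is relaxed (or
    ## stagnant), and in any case for the final quarter of the budget
    if (!climbing &&
        (iter > climb_after || fmax < 5 * force_tolerance ||
         (iter > 150L && fmax > 0.98 * fhist[iter - 100L])))
      climbing <- TRUE
    ## improved tangents
    TAU <- matrix(0, n, 2L)
    for (i in interior) {
      dp <- X[i + 1L, ] - X[i, ]
      dm <- X[i, ] - X[i - 1L, ]
      if (E[i + 1L] > E[i] && E[i] > E[i - 1L]) tau <- dp
      else if (E[i + 1L] < E[i] && E[i] < E[i - 1L]) tau <- dm
      else {
        dEmax <- max(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
        dEmin <- min(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
        tau <- if (E[i + 1L] > E[i - 1L]) dp * dEmax + dm * dEmin
               else dp * dEmin + dm * dEmax
      }
      TAU[i, ] <- tau / max(sqrt(sum(tau^2)), 1e-12)
    }
    gpar <- rowSums(G * TAU)
    Fperp <- -(G - gpar * TAU)
    seg <- sqrt(rowSums(diff(X)^2))          # n-1 segment lengths
    Fspring <- matrix(0, n, 2L)
    Fspring[interior, ] <- spring_constant *
      (seg[interior] - seg[interior - 1L]) * TAU[interior, , drop = FALSE]
    Ftot <- Fperp + Fspring
    Ftot[1, ] <- 0; Ftot[n, ] <- 0

    imax <- interior[which.max(E[interior])]
    if (climbing)
      Ftot[imax, ] <- -G[imax, ] + 2 * gpar[imax] * TAU[imax, ]

    fres <- sqrt(rowSums(Fperp[interior, , drop = FALSE]^2))
    if (climbing) fres[imax - 1L] <- sqrt(sum(Ftot[imax, ]^2))
    fmax <- max(fres)
    fhist[iter] <- fmax
    if (climbing && fmax < force_tolerance) { converged <- TRUE; break }

    ## Barzilai-Borwein spectral step from the force differences
    if (!is.null(X_prev)) {
      s <- as.vector(X - X_prev)
      y <- as.vector(F_prev - Ftot)
      sy <- sum(s * y); yy <- sum(y * y)
      dt <- if (sy > 0 && yy > 0) sy / yy else dt0
    }
    X_prev <- X; F_prev <- Ftot
    disp <- dt * Ftot
    dn <- sqrt(rowSums(disp^2))
    cap <- 0.5 * stats::median(seg)
    over <- dn > cap
    if (any(over)) disp[over, ] <- disp[over, ] * (cap / dn[over])
    Xn <- X + disp
    lo <- surface$boundaries[, 1]; hi <- surface$boundaries[, 2]
    Xn[, 1] <- pmin(pmax(Xn[, 1], lo[1]), hi[1])
    Xn[, 2] <- pmin(pmax(Xn[, 2], lo[2]), hi[2])
    ## nodes whose stencil would touch an unsampled bin stay put this
    ## iteration (their velocity is reset); the rest of the band relaxes
    if (inherits(surface, "fes_interpolant")) {
      bad <- !is_interpolable(surface, Xn)
      if (any(bad)) Xn[bad, ] <- X[bad, ]
    }
    res <- tryCatch(list(E = eval_E(Xn), G = eval_G(Xn)),
                    ionpmf_masked_region = function(e) NULL)
    if (is.null(res))
      .masked_error("NEB path is trapped against an unsampled region")
    X <- Xn; E <- res$E; G <- res$G
  }

  structure(list(nodes = X, energies = E,
                 endpoints = rbind(a, b),
                 converged = converged,
                 max_force_residual = fmax,
                 n_iterations = iter,
                 spring_constant = spring_constant,
                 force_tolerance = force_tolerance),
            class = "mfep_path")
}

#' @export
print.mfep_path <- function(x, ...) {
  cat(sprintf(
    "<mfep_path> %d images, barrier %.2f kJ/mol, %s (max residual %.3g kJ/mol/nm, %d iterations)\n",
    nrow(x$nodes), max(x$energies) - x$energies[1],
    if (x$converged) "converged" else "NOT converged",
    x$max_force_residual, x$n_iterations))
  invisible(x)
}

#' Re-evaluate a path's energies on another surface
#'
#' Used to carry the geometry of a path optimized on a smoothed interpolant
#' back onto the unsmoothed PMF before projecting and measuring barriers.
#'
#' @param path an `mfep_path`.
#' @param surface the surface to evaluate on.
#' @return the path with `energies` replaced.
#' @export
path_energies <- function(path, surface) {
  path$energies <- fes_value(surface, path$nodes)
  path
}

#' Dense-grid minimax-path barrier (independent oracle)
#'
#' Computes the minimax barrier between two points by an exact graph method:
#' the surface is sampled on an n x n grid, lattice edges are weighted by the
#' larger of the two node energies, and the minimax path is read off the
#' minimum spanning tree (the unique MST path minimizes the maximum edge
#' weight). This is an NEB-free reference for saddle heights.
#'
#' @param surface anything implementing [fes_value()].
#' @param start,end CV points.
#' @param n grid resolution per CV (default 500).
#' @param boundaries region to grid; defaults to the surface domain.
#' @return list with `barrier` (max F along the minimax path minus F(start)),
#'   `max_energy`, and `start_energy`.
#' @export
grid_minimax_barrier <- function(surface, start, end, n = 500L,
                                 boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- surface$boundaries
  boundaries <- .as_boundaries(boundaries)
  a <- .as_cv_point(start); b <- .as_cv_point(end)
  xs <- seq(boundaries[1, 1], boundaries[1, 2], length.out = n)
  ys <- seq(boundaries[2, 1], boundaries[2, 2], length.out = n)
  P <- cbind(rep(xs, times = n), rep(ys, each = n))
  Fv <- matrix(fes_value(surface, P), n, n)

  id <- matrix(seq_len(n * n), n, n)
  edges <- list(); ww <- list()
  add <- function(A, B) {
    edges[[length(edges) + 1L]] <<- cbind(as.vector(A), as.vector(B))
    ww[[length(ww) + 1L]] <<- pmax(Fv[as.vector(A)], Fv[as.vector(B)])
  }
  add(id[-n, ], id[-1, ])                 # right
  add(id[, -n], id[, -1])                 # up
  add(id[-n, -n], id[-1, -1])             # diagonal
  add(id[-1, -n], id[-n, -1])             # anti-diagonal
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  igraph::E(g)$weight <- unlist(ww)
  mst <- igraph::mst(g)
  near <- function(p) id[which.min(abs(xs - p[1])), which.min(abs(ys - p[2]))]
  va <- near(a); vb <- near(b)
  path <- igraph::shortest_paths(mst, va, vb, output = "epath")$epath[[1]]
  mx <- max(igraph::E(mst)$weight[as.integer(path)])
  list(barrier = mx - Fv[va], max_energy = mx, start_energy = Fv[va])
}
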