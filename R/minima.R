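#' Locating minima and assigning basins on a PMF
#'
#' Minima are detected as strict 8-neighbor local minima of the gridded PMF
#' (plateaus therefore yield no minima), refined by bounded quasi-Newton
#' descent on the continuous interpolant, merged when closer than
#' `min_separation` (keeping the lower), and sorted by energy. For
#' histogram-noisy PMFs, detection can run on a Gaussian-smoothed copy of the
#' grid and candidates can be required to exceed a prominence threshold; the
#' reported energies always come from the unsmoothed interpolant.
#'
#' @name minima
NULL

#' Find local minima of a PMF grid
#'
#' @param pmf a 2D `pmf_grid`.
#' @param min_separation minima closer than this (nm) are merged keeping the
#'   lower; default 0.1 nm (one umbrella interval) to suppress
#'   histogram-noise twins.
#' @param max_energy ceiling in kJ/mol; default global minimum + 50,
#'   comfortably above any physically meaningful barrier here.
#' @param smoothing Gaussian bandwidth in bins used for detection and
#'   refinement only (default 0).
#' @param min_prominence candidates whose connecting ridge to a lower
#'   minimum rises less than this above them (kJ/mol) are treated as noise
#'   and merged into that minimum; default 0 (off).
#' @return data frame of class `fes_minima` with columns `index`, `z1`, `z2`,
#'   `energy`, `label`, sorted by energy. The unsmoothed interpolant is
#'   attached as attribute `"interpolant"`.
#' @export
find_minima <- function(pmf, min_separation = 0.1, max_energy = NULL,
                        smoothing = 0, min_prominence = 0) {
  stopifnot(min_separation >= 0)
  itp_raw <- interpolate_pmf(pmf, smoothing = 0)
  itp_det <- if (smoothing > 0) interpolate_pmf(pmf, smoothing = smoothing)
             else itp_raw
  M <- if (smoothing > 0) .smooth_grid(pmf$free_energy, smoothing)
       else pmf$free_energy
  if (is.null(max_energy))
    max_energy <- min(pmf$free_energy, na.rm = TRUE) + 50

  nx <- nrow(M); ny <- ncol(M)
  cand <- list()
  for (i in 2:(nx - 1L)) for (j in 2:(ny - 1L)) {
    c0 <- M[i, j]
    if (is.na(c0)) next
    nb <- M[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    if (any(is.na(nb))) next
    nb[2, 2] <- Inf
    if (all(c0 < nb)) cand[[length(cand) + 1L]] <- c(i, j)
  }
  if (!length(cand)) {
    out <- data.frame(index = integer(0), z1 = numeric(0), z2 = numeric(0),
                      energy = numeric(0), label = character(0))
    class(out) <- c("fes_minima", "data.frame")
    attr(out, "interpolant") <- itp_raw
    return(out)
  }

  xs <- pmf$midpoints[[1]]; ys <- pmf$midpoints[[2]]
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  pts <- matrix(NA_real_, length(cand), 2L)
  for (q in seq_along(cand)) {
    ij <- cand[[q]]
    p0 <- c(xs[ij[1]], ys[ij[2]])
    lob <- pmax(p0 - 2 * c(hx, hy), c(xs[1], ys[1]))
    upb <- pmin(p0 + 2 * c(hx, hy), c(xs[nx], ys[ny]))
    op <- tryCatch(
      stats::optim(p0, function(p) fes_value(itp_det, p),
                   function(p) drop(fes_grad(itp_det, p)),
                   method = "L-BFGS-B", lower = lob, upper = upb,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    pts[q, ] <- if (is.null(op)) p0 else op$par
  }
  ## candidates whose stencil touches an unsampled bin are not trustworthy
  en <- vapply(seq_len(nrow(pts)), function(q)
    tryCatch(fes_value(itp_raw, pts[q, ]),
             ionpmf_masked_region = function(e) NA_real_), numeric(1))

  keep <- !is.na(en) & en <= max_energy
  pts <- pts[keep, , drop = FALSE]; en <- en[keep]
  if (!nrow(pts)) {
    out <- data.frame(index = integer(0), z1 = numeric(0), z2 = numeric(0),
                      energy = numeric(0), label = character(0))
    class(out) <- c("fes_minima", "data.frame")
    attr(out, "interpolant") <- itp_raw
    return(out)
  }

  ## merge near-duplicates, lower energy wins
  ord <- order(en)
  pts <- pts[ord, , drop = FALSE]; en <- en[ord]
  sel <- integer(0)
  for (q in seq_along(en)) {
    dup <- FALSE
    for (s in sel)
      if (sqrt(sum((pts[q, ] - pts[s, ])^2)) < min_separation) {
        dup <- TRUE; break
      }
    if (!dup) sel <- c(sel, q)
  }
  pts <- pts[sel, , drop = FALSE]; en <- en[sel]

  ## prominence filter: a candidate separated from a lower minimum by a
  ## ridge of less than min_prominence is histogram noise, not a state
  if (min_prominence > 0 && nrow(pts) > 1L) {
    ridge_height <- function(p, q) {
      ## max energy on the straight line, skipping masked points (candidates
      ## living next to unsampled bins should still be judged by the
      ## evaluable part of their connecting ridge)
      tt <- seq(0, 1, length.out = 64L)
      line <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
      v <- vapply(seq_len(nrow(line)), function(k)
        tryCatch(fes_value(itp_det, line[k, ]),
                 ionpmf_masked_region = function(e) NA_real_), numeric(1))
      if (all(is.na(v))) Inf else max(v, na.rm = TRUE)
    }
    det_at <- function(p)
      tryCatch(fes_value(itp_det, p), ionpmf_masked_region = function(e) Inf)
    keep <- rep(TRUE, nrow(pts))
    for (q in seq_len(nrow(pts))[-1]) {       # ascending energy; q > 1
      for (s in which(keep[seq_len(q - 1L)])) {
        if (ridge_height(pts[q, ], pts[s, ]) - det_at(pts[q, ]) <
            min_prominence) {
          keep[q] <- FALSE; break
        }
      }
    }
    pts <- pts[keep, , drop = FALSE]; en <- en[keep]
  }

  out <- data.frame(index = seq_len(nrow(pts)), z1 = pts[, 1], z2 = pts[, 2],
                    energy = en, label = paste0("m", seq_len(nrow(pts))))
  class(out) <- c("fes_minima", "data.frame")
  attr(out, "interpolant") <- itp_raw
  out
}

#' Assign samples to free-energy basins
#'
#' Each sample is moved by a coarse fixed-step gradient descent (50 steps by
#' default) on the surface, then assigned to the nearest minimum of the
#' descent endpoint. This approximates steepest-descent basin membership
#' while staying cheap; samples above `max_energy` remain unassigned (`NA`).
#'
#' @param samples n x 2 matrix of CV points.
#' @param minima a `fes_minima` data frame (needs >= 1 row).
#' @param surface a `fes_surface` or `fes_interpolant`.
#' @param max_energy ceiling in kJ/mol (default `Inf`).
#' @param n_steps descent steps (default 50).
#' @param step_length descent step in nm (default 0.02).
#' @return integer vector of minimum indices (`NA` above the ceiling).
#' @export
assign_basins <- function(samples, minima, surface, max_energy = Inf,
                          n_steps = 50L, step_length = 0.02) {
  stopifnot(nrow(minima) >= 1L)
  z <- .as_points(samples, 2L)
  lo <- surface$boundaries[, 1]; hi <- surface$boundaries[, 2]
  en0 <- tryCatch(fes_value(surface, z), error = function(e)
    vapply(seq_len(nrow(z)), function(i)
      tryCatch(fes_value(surface, z[i, ]), error = function(e2) Inf),
      numeric(1)))
  unassigned <- en0 > max_energy

  movable <- function(p) {
    if (inherits(surface, "fes_interpolant")) is_interpolable(surface, p)
    else rep(TRUE, nrow(p))
  }
  for (s in seq_len(n_steps)) {
    ok <- movable(z)
    if (!any(ok)) break
    g <- matrix(0, nrow(z), 2L)
    g[ok, ] <- fes_grad(surface, z[ok, , drop = FALSE])
    gn <- sqrt(rowSums(g^2))
    mv <- ok & gn > 1e-8
    if (!any(mv)) break
    step <- z
    step[mv, ] <- z[mv, ] - step_length * g[mv, ] / gn[mv]
    step[, 1] <- pmin(pmax(step[, 1], lo[1]), hi[1])
    step[, 2] <- pmin(pmax(step[, 2], lo[2]), hi[2])
    stuck <- !movable(step)
    step[stuck, ] <- z[stuck, ]
    z <- step
  }
  mins <- as.matrix(minima[, c("z1", "z2")])
  d2 <- outer(rowSums(z^2), rowSums(mins^2), "+") - 2 * z %*% t(mins)
  idx <- minima$index[max.col(-d2, ties.method = "first")]
  idx[unassigned] <- NA_integer_
  idx
}

#' Representative sample of a basin
#'
#' Returns the index of the basin member closest to the basin centroid
#' (lowest index wins ties), mirroring the extraction of representative
#' snapshots along a conduction pathway.
#'
#' @param assignment integer vector from [assign_basins()].
#' @param minimum_index which minimum's basin to summarize.
#' @param samples the n x 2 sample matrix the assignment refers to.
#' @return integer sample index.
#' @export
representative_snapshot <- function(assignment, minimum_index, samples) {
  samples <- .as_points(samples, 2L)
  members <- which(!is.na(assignment) & assignment == minimum_index)
  if (!length(members))
    stop("basin of minimum ", minimum_index, " is empty", call. = FALSE)
  pts <- samples[members, , drop = FALSE]
  centroid <- colMeans(pts)
  d2 <- rowSums(sweep(pts, 2L, centroid)^2)
  members[which.min(d2)]
}

#' @export
print.fes_minima <- function(x, ...) {
  cat(sprintf("<fes_minima> %d minima\n", nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write/read a minima table
#'
#' CSV round trip used between the minima and path stages.
#'
#' @param minima a `fes_minima` data frame.
#' @param path file path.
#' @return `write_minima` returns `path` invisibly; `read_minima` the data
#'   frame.
#' @export
write_minima <- function(minima, path) {
  utils::write.csv(as.data.frame(minima), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_minima
#' @export
read_minima <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("fes_minima", "data.frame")
  out
}
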