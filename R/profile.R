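#' 1D projection of an MFEP and barrier readout
#'
#' The conduction path is projected onto its cumulative arc length lambda
#' (nm). Free-energy extrema along lambda are located on a cubic-spline
#' re-interpolation, small-amplitude extremum pairs are filtered as noise,
#' and the surviving markers must alternate valley/peak: those valleys are
#' the conduction states. Barriers between states are read off the profile;
#' a transition "over the periodic boundary" (to an earlier state) continues
#' the profile cyclically WITHOUT an energy shift, because in a finite
#' simulation box the first and last states are distinct configurations of
#' the same system, so re-entering costs the full net free-energy drop in
#' addition to the local barrier.
#'
#' @name profile1d
NULL

.profile_error <- function(msg, markers = NULL) {
  stop(structure(class = c("ionpmf_profile_error", "error", "condition"),
                 list(message = msg, call = NULL, markers = markers)))
}

#' Project an MFEP onto its arc length
#'
#' @param path an `mfep_path` (should be converged; a warning is issued
#'   otherwise).
#' @param min_prominence adjacent extremum pairs whose energies differ by
#'   less than this (kJ/mol) are removed as noise before the alternation
#'   check (default 0.25).
#' @return an object of class `fes_profile`: list with `lambda` and
#'   `free_energy` at the path nodes, `spline` (function of lambda),
#'   `markers` (data frame kind/lambda/energy/state with alternating
#'   valley/peak), and `length`.
#' @export
project_1d <- function(path, min_prominence = 0.25) {
  if (!isTRUE(path$converged))
    warning("projecting an unconverged path", call. = FALSE)
  nodes <- path$nodes
  E <- path$energies
  seg <- sqrt(rowSums(diff(nodes)^2))
  if (any(seg <= 0))
    .profile_error("repeated path nodes: arc length not strictly increasing")
  lam <- c(0, cumsum(seg))
  L <- lam[length(lam)]
  spl <- stats::splinefun(lam, E, method = "fmm")

  ## locate interior extrema on a dense spline evaluation
  tt <- seq(0, L, length.out = max(2000L, 20L * length(lam)))
  vv <- spl(tt)
  dv <- diff(vv)
  sgn <- sign(dv)
  sgn[sgn == 0] <- 1
  flips <- which(diff(sgn) != 0) + 1L
  ext <- lapply(flips, function(k) {
    lo <- tt[max(1L, k - 1L)]; hi <- tt[min(length(tt), k + 1L)]
    if (sgn[k] < 0 && sgn[k - 1L] > 0) {        # peak
      op <- stats::optimize(spl, c(lo, hi), maximum = TRUE)
      data.frame(kind = "peak", lambda = op$maximum, energy = op$objective)
    } else {
      op <- stats::optimize(spl, c(lo, hi))
      data.frame(kind = "valley", lambda = op$minimum, energy = op$objective)
    }
  })
  mk <- rbind(data.frame(kind = "valley", lambda = 0, energy = E[1]),
              do.call(rbind, ext),
              data.frame(kind = "valley", lambda = L, energy = E[length(E)]))
  mk <- mk[order(mk$lambda), , drop = FALSE]

  merge_same_kind <- function(mk) {
    repeat {
      same <- which(mk$kind[-1] == mk$kind[-nrow(mk)])
      if (!length(same)) return(mk)
      s <- same[1]
      drop <- if (mk$kind[s] == "valley") {
        if (mk$energy[s] <= mk$energy[s + 1L]) s + 1L else s
      } else {
        if (mk$energy[s] >= mk$energy[s + 1L]) s + 1L else s
      }
      ## never drop the path endpoints
      if (drop == 1L) drop <- 2L
      if (drop == nrow(mk)) drop <- nrow(mk) - 1L
      mk <- mk[-drop, , drop = FALSE]
    }
  }
  mk <- merge_same_kind(mk)

  ## prominence filter: remove the weakest adjacent pair below threshold
  repeat {
    if (nrow(mk) < 4L) break
    amp <- abs(diff(mk$energy))
    inner <- 2:(nrow(mk) - 2L)            # pairs (i, i+1) fully interior
    if (!length(inner)) break
    cand <- inner[amp[inner] < min_prominence]
    if (!length(cand)) break
    s <- cand[which.min(amp[cand])]
    mk <- mk[-c(s, s + 1L), , drop = FALSE]
    mk <- merge_same_kind(mk)
  }

  kinds <- mk$kind
  alternating <- all(kinds[-1] != kinds[-length(kinds)]) &&
    kinds[1] == "valley" && kinds[length(kinds)] == "valley"
  if (!alternating)
    .profile_error("extrema do not alternate valley/peak after filtering",
                   markers = mk)
  mk$state <- NA_integer_
  mk$state[mk$kind == "valley"] <- seq_len(sum(mk$kind == "valley"))
  mk$state[mk$kind == "peak"] <- seq_len(sum(mk$kind == "peak"))
  rownames(mk) <- NULL

  structure(list(lambda = lam, free_energy = E, spline = spl,
                 markers = mk, length = L, path = path),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  nv <- sum(x$markers$kind == "valley")
  cat(sprintf("<fes_profile> length %.3f nm, %d states, %d peaks\n",
              x$length, nv, sum(x$markers$kind == "peak")))
  print.data.frame(x$markers, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fes_profile <- function(x, ...) {
  tt <- seq(0, x$length, length.out = 500L)
  graphics::plot(tt, x$spline(tt), type = "l", xlab = "lambda (nm)",
                 ylab = "F (kJ/mol)", ...)
  v <- x$markers[x$markers$kind == "valley", ]
  graphics::points(v$lambda, v$energy, pch = 19)
  graphics::text(v$lambda, v$energy, labels = v$state, pos = 1)
  invisible(x)
}

#' Free-energy barrier between two states of a profile
#'
#' Returns the height of the free-energy barrier for the directed transition
#' `from_state -> to_state`: the maximum of F on the directed segment minus
#' F(from_state). If `to_state` lies before `from_state` along lambda, the
#' profile is continued cyclically without an energy shift, so the barrier
#' over the periodic boundary includes climbing back the net free-energy drop
#' of the whole path.
#'
#' @param profile a `fes_profile`.
#' @param from_state,to_state valley (state) numbers on the profile.
#' @return barrier height in kJ/mol.
#' @export
barrier <- function(profile, from_state, to_state) {
  v <- profile$markers[profile$markers$kind == "valley", ]
  if (!(from_state %in% v$state) || !(to_state %in% v$state))
    stop("undefined state on this profile", call. = FALSE)
  if (from_state == to_state) return(0)
  lf <- v$lambda[v$state == from_state]
  lt <- v$lambda[v$state == to_state]
  ef <- v$energy[v$state == from_state]
  seg_max <- function(a, b) {
    if (b < a) return(-Inf)
    tt <- seq(a, b, length.out = max(64L, ceiling((b - a) / profile$length *
                                                    2000L)))
    max(profile$spline(tt))
  }
  mx <- if (lt > lf) seg_max(lf, lt)
        else max(seg_max(lf, profile$length), seg_max(0, lt))
  mx - ef
}

#' Write/read a path or profile as a CSV table
#'
#' Columns: node index, CV coordinates, cumulative arc length lambda, free
#' energy.
#'
#' @param path an `mfep_path`.
#' @param file file path.
#' @return `write_path` returns `file` invisibly; `read_path_table` the data
#'   frame.
#' @export
write_path <- function(path, file) {
  seg <- sqrt(rowSums(diff(path$nodes)^2))
  df <- data.frame(node = seq_len(nrow(path$nodes)),
                   z1 = path$nodes[, 1], z2 = path$nodes[, 2],
                   lambda = c(0, cumsum(seg)), F = path$energies)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @export
read_path_table <- function(file) utils::read.csv(file)
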