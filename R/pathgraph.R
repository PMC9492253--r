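#' Joining MFEP snippets into candidate conduction paths
#'
#' NEB snippets are computed between nearby pairs of minima; converged
#' snippets become edges of a path graph whose simple paths between chosen
#' start and end states are the candidate conduction routes. Each candidate
#' is re-relaxed as a whole band and ranked by the quantity that controls the
#' rate: the highest energy along the path (ties broken by the path action).
#'
#' @name pathgraph
NULL

.neb_defaults <- function(settings = list()) {
  utils::modifyList(list(n_images = 32L, spring_constant = 500,
                         max_iterations = 5000L, force_tolerance = 0.5),
                    settings)
}

#' Build the graph of converged NEB snippets between minima
#'
#' @param surface a `fes_surface` or `fes_interpolant`.
#' @param minima a `fes_minima` table with >= 2 rows.
#' @param neb_settings list overriding the NEB defaults (`n_images`,
#'   `spring_constant`, `max_iterations`, `force_tolerance`).
#' @param cutoff only pairs closer than this (nm) get a snippet; default 3x
#'   the median nearest-neighbor distance.
#' @return an object of class `path_graph`: list with `minima`, `edges` (data
#'   frame i, j, barrier), `snippets` (named `"i-j"`), `excluded` (data frame
#'   of skipped pairs with reasons) and `graph` (igraph).
#' @export
build_path_graph <- function(surface, minima, neb_settings = list(),
                             cutoff = NULL) {
  stopifnot(nrow(minima) >= 2L)
  ns <- .neb_defaults(neb_settings)
  P <- as.matrix(minima[, c("z1", "z2")])
  m <- nrow(P)
  D <- as.matrix(stats::dist(P))
  if (is.null(cutoff)) {
    nn <- apply(D + diag(Inf, m), 1L, min)
    cutoff <- 3 * stats::median(nn)
  }
  edges <- NULL; snippets <- list(); excluded <- NULL
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (D[i, j] >= cutoff) next
    key <- paste0(minima$index[i], "-", minima$index[j])
    snip <- tryCatch(
      neb(surface, P[i, ], P[j, ], n_images = ns$n_images,
          spring_constant = ns$spring_constant,
          max_iterations = ns$max_iterations,
          force_tolerance = ns$force_tolerance),
      ionpmf_masked_region = function(e) e)
    if (inherits(snip, "condition")) {
      excluded <- rbind(excluded, data.frame(
        i = minima$index[i], j = minima$index[j],
        reason = conditionMessage(snip)))
      next
    }
    if (!snip$converged) {
      excluded <- rbind(excluded, data.frame(
        i = minima$index[i], j = minima$index[j],
        reason = sprintf("NEB not converged (residual %.3g kJ/mol/nm)",
                         snip$max_force_residual)))
      next
    }
    barrier <- max(snip$energies) - min(snip$energies[c(1L, length(snip$energies))])
    edges <- rbind(edges, data.frame(i = minima$index[i],
                                     j = minima$index[j], barrier = barrier))
    snippets[[key]] <- snip
  }
  if (!is.null(excluded))
    message("build_path_graph: excluded ", nrow(excluded), " pair(s): ",
            paste(sprintf("%d-%d (%s)", excluded$i, excluded$j,
                          excluded$reason), collapse = "; "))
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(match(edges$i, minima$index),
                                    match(edges$j, minima$index)))
  structure(list(minima = minima, edges = edges, snippets = snippets,
                 excluded = excluded, graph = g, neb_settings = ns,
                 surface = surface),
            class = "path_graph")
}

#' @export
print.path_graph <- function(x, ...) {
  cat(sprintf("<path_graph> %d minima, %d snippets, %d excluded pair(s)\n",
              nrow(x$minima),
              if (is.null(x$edges)) 0L else nrow(x$edges),
              if (is.null(x$excluded)) 0L else nrow(x$excluded)))
  invisible(x)
}

## joined node list of a vertex sequence, reusing the stored snippets
.join_snippets <- function(pg, verts) {
  nodes <- NULL; energies <- NULL
  idx <- pg$minima$index
  for (s in seq_len(length(verts) - 1L)) {
    u <- idx[verts[s]]; v <- idx[verts[s + 1L]]
    key <- paste0(min(u, v), "-", max(u, v))
    snip <- pg$snippets[[key]]
    nn <- snip$nodes; ee <- snip$energies
    if (u > v) {
      nn <- nn[rev(seq_len(nrow(nn))), , drop = FALSE]
      ee <- rev(ee)
    }
    if (is.null(nodes)) {
      nodes <- nn; energies <- ee
    } else {
      nodes <- rbind(nodes, nn[-1, , drop = FALSE])
      energies <- c(energies, ee[-1])
    }
  }
  list(nodes = nodes, energies = energies)
}

#' Enumerate and rank candidate paths between two states
#'
#' All simple paths (no repeated minima) from `start` to `end` are joined
#' from the stored snippets, optionally re-relaxed as whole bands, and ranked
#' by (1) the highest energy along the path and (2) the path action
#' (sum of segment length x mean segment energy) as tie-break.
#'
#' @param pg a `path_graph`.
#' @param start,end minimum indices (values of `minima$index`).
#' @param max_paths number of ranked paths to return (default 10).
#' @param rerelax re-relax each joined path as a whole NEB band (default
#'   `TRUE`); with `FALSE` the concatenated snippets are used as-is.
#' @param rank_tolerance paths whose highest energies differ by less than
#'   this (kJ/mol) are treated as tied and ordered by action; differences
#'   below the statistical uncertainty of a histogrammed PMF are not
#'   meaningful (default 0.5).
#' @return list of `mfep_path` objects, best first, with a data frame of
#'   ranking metrics attached as attribute `"ranking"`.
#' @export
enumerate_paths <- function(pg, start, end, max_paths = 10L, rerelax = TRUE,
                            rank_tolerance = 0.5) {
  vs <- match(start, pg$minima$index)
  ve <- match(end, pg$minima$index)
  if (is.na(vs) || is.na(ve))
    stop("start/end must be indices present in the minima table",
         call. = FALSE)
  sp <- suppressWarnings(
    igraph::all_simple_paths(pg$graph, from = vs, to = ve))
  if (!length(sp))
    stop(structure(class = c("ionpmf_connectivity_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "no path between minima %s and %s in the snippet graph",
                     start, end), call = NULL)))
  ns <- pg$neb_settings
  paths <- lapply(sp, function(vp) {
    verts <- as.integer(vp)
    joined <- .join_snippets(pg, verts)
    nodes <- joined$nodes
    if (rerelax) {
      n_img <- min(160L, (length(verts) - 1L) * (ns$n_images - 1L) + 1L)
      p <- tryCatch(
        neb(pg$surface, nodes[1, ], nodes[nrow(nodes), ],
            n_images = n_img, spring_constant = ns$spring_constant,
            max_iterations = ns$max_iterations,
            force_tolerance = ns$force_tolerance, seed_nodes = nodes),
        ionpmf_masked_region = function(e) NULL)
      if (is.null(p)) {
        message("enumerate_paths: joint relaxation blocked by an unsampled ",
                "region; using the concatenated snippets as-is")
        rerelax <- FALSE
      }
    }
    if (!rerelax) {
      p <- structure(list(nodes = nodes,
                          energies = joined$energies,
                          endpoints = nodes[c(1L, nrow(nodes)), ],
                          converged = all(vapply(pg$snippets, `[[`,
                                                 logical(1), "converged")),
                          max_force_residual = NA_real_,
                          n_iterations = 0L),
                     class = "mfep_path")
    }
    p$via <- pg$minima$index[verts]
    p
  })
  peak <- vapply(paths, function(p) max(p$energies), numeric(1))
  action <- vapply(paths, function(p) {
    seg <- sqrt(rowSums(diff(p$nodes)^2))
    e <- p$energies - min(p$energies)
    sum(seg * (e[-1] + e[-length(e)]) / 2)
  }, numeric(1))
  ## group near-tied maxima (gaps <= rank_tolerance), order groups by height
  ## and members by action
  ord0 <- order(peak)
  grp <- cumsum(c(1, diff(peak[ord0]) > rank_tolerance))
  ord <- ord0[order(grp, action[ord0])]
  paths <- paths[ord][seq_len(min(max_paths, length(paths)))]
  attr(paths, "ranking") <- data.frame(
    rank = seq_along(ord),
    via = vapply(sp[ord], function(v)
      paste(pg$minima$index[as.integer(v)], collapse = ">"), character(1)),
    max_energy = peak[ord], action = action[ord])[seq_len(length(paths)), ]
  paths
}
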