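## hand-built path graph with prescribed snippet energetics, for testing the
## enumeration and ranking logic in isolation (rerelax = FALSE)
toy_graph <- function(layout, edges, barrier_tops) {
  minima <- data.frame(index = seq_len(nrow(layout)),
                       z1 = layout[, 1], z2 = layout[, 2],
                       energy = 0, label = paste0("m", seq_len(nrow(layout))))
  class(minima) <- c("fes_minima", "data.frame")
  snippets <- list()
  g <- igraph::make_empty_graph(n = nrow(layout), directed = FALSE)
  for (k in seq_len(nrow(edges))) {
    i <- min(edges[k, ]); j <- max(edges[k, ])   # snippets run min -> max
    tt <- seq(0, 1, length.out = 11)
    nodes <- cbind(layout[i, 1] + tt * (layout[j, 1] - layout[i, 1]),
                   layout[i, 2] + tt * (layout[j, 2] - layout[i, 2]))
    en <- barrier_tops[k] * sin(pi * tt)^2
    snippets[[paste0(min(i, j), "-", max(i, j))]] <- structure(
      list(nodes = nodes, energies = en, converged = TRUE,
           endpoints = nodes[c(1, 11), ], max_force_residual = 0,
           n_iterations = 0L),
      class = "mfep_path")
    g <- igraph::add_edges(g, c(i, j))
  }
  structure(list(minima = minima,
                 edges = data.frame(i = edges[, 1], j = edges[, 2],
                                    barrier = barrier_tops),
                 snippets = snippets, excluded = NULL, graph = g,
                 neb_settings = list(n_images = 11L, spring_constant = 500,
                                     max_iterations = 100L,
                                     force_tolerance = 0.5),
                 surface = NULL),
            class = "path_graph")
}

test_that("two minima give a single snippet edge", {
  sf <- two_well()
  m <- find_minima(as_pmf_grid(grid_from_surface(sf, 61)))
  pg <- build_path_graph(sf, m)
  expect_equal(nrow(pg$edges), 1L)
  expect_equal(length(pg$snippets), 1L)
  expect_equal(pg$edges$barrier, 19.85, tolerance = 0.01)
})

test_that("collinear wells give a chain graph with long-range pairs pruned", {
  terms <- lapply(0:4, function(i)
    gaussian_term(-20, c(i * 0.5 - 1, 0), 0.12))
  sf <- make_surface(terms, rbind(c(-1.5, 1.5), c(-0.6, 0.6)))
  gt <- sf$ground_truth[sf$ground_truth$type == "min", ]
  m <- data.frame(index = 1:5, z1 = sort(gt$z1), z2 = gt$z2[order(gt$z1)],
                  energy = 0, label = paste0("m", 1:5))
  pg <- build_path_graph(sf, m, neb_settings = list(n_images = 16L))
  ## cutoff = 3 x median NN distance = 1.5 nm prunes pairs 0.5 * |i-j| >= 1.5
  pairs <- pg$edges[, c("i", "j")]
  expect_true(all(abs(pairs$i - pairs$j) <= 2))
  expect_equal(nrow(pairs), 4L + 3L)
})

test_that("path enumeration ranks the low-saddle branch of a diamond first", {
  layout <- rbind(c(0, 0), c(1, 1), c(1, -1), c(2, 0))
  edges <- rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4))
  pg <- toy_graph(layout, edges, barrier_tops = c(30, 30, 10, 10))
  ranked <- enumerate_paths(pg, 1, 4, rerelax = FALSE)
  expect_equal(length(ranked), 2L)
  expect_equal(ranked[[1]]$via, c(1, 3, 4))     # low-saddle branch first
  rk <- attr(ranked, "ranking")
  expect_equal(rk$max_energy, c(10, 30))
  ## max_paths = 1 returns only the MFEP
  expect_equal(length(enumerate_paths(pg, 1, 4, max_paths = 1,
                                      rerelax = FALSE)), 1L)
  ## chain subgraph has exactly one simple path
  pg2 <- toy_graph(layout[c(1, 2, 4), ], rbind(c(1, 2), c(2, 3)), c(5, 8))
  expect_equal(length(enumerate_paths(pg2, 1, 3, rerelax = FALSE)), 1L)
  ## missing connectivity is a classed error
  pg3 <- toy_graph(layout, rbind(c(1, 2), c(3, 4)), c(5, 5))
  expect_error(enumerate_paths(pg3, 1, 4, rerelax = FALSE),
               class = "ionpmf_connectivity_error")
})

test_that("ranking is invariant to the order minima are listed in", {
  layout <- rbind(c(0, 0), c(1, 1), c(1, -1), c(2, 0))
  edges <- rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4))
  perm <- c(4, 2, 1, 3)
  ## relabel: minima permuted, edges and tops expressed in new labels
  inv <- order(perm)
  edges2 <- matrix(inv[edges], ncol = 2)
  pg1 <- toy_graph(layout, edges, c(30, 30, 10, 10))
  pg2 <- toy_graph(layout[perm, ], edges2, c(30, 30, 10, 10))
  r1 <- attr(enumerate_paths(pg1, 1, 4, rerelax = FALSE), "ranking")
  r2 <- attr(enumerate_paths(pg2, inv[1], inv[4], rerelax = FALSE), "ranking")
  expect_equal(r1$max_energy, r2$max_energy)
  expect_equal(r1$action, r2$action, tolerance = 1e-12)
})

test_that("1D projection measures arc length and alternating extrema", {
  ## straight 11-node path with 0.1 nm spacing: lambda runs 0..1
  lam <- seq(0, 1, by = 0.1)
  p <- fake_path(lam, 10 * sin(pi * lam)^2)
  pr <- project_1d(p)
  expect_equal(pr$lambda, lam)
  expect_equal(pr$length, 1)
  ## symmetric double well: single peak at mid-lambda
  mk <- pr$markers
  expect_equal(mk$kind, c("valley", "peak", "valley"))
  expect_equal(mk$lambda[2], 0.5, tolerance = 1e-3)
  ## endpoint energies preserved exactly
  expect_equal(mk$energy[c(1, 3)], c(0, 0))
})

test_that("the five-well conduction MFEP projects to 5 valleys and 4 peaks", {
  sf <- preset_conduction_surface()
  gt <- sf$ground_truth
  m <- gt[gt$type == "min", ]
  minima <- data.frame(index = seq_len(5), z1 = m$z1, z2 = m$z2,
                       energy = m$energy, label = paste0("s", 1:5))
  class(minima) <- c("fes_minima", "data.frame")
  pg <- build_path_graph(sf, minima, neb_settings = list(n_images = 20L))
  start <- minima$index[which.max(minima$z1)]
  end <- minima$index[which.min(minima$z1)]
  ranked <- enumerate_paths(pg, start, end, max_paths = 3)
  pr <- project_1d(ranked[[1]])
  expect_equal(sum(pr$markers$kind == "valley"), 5L)
  expect_equal(sum(pr$markers$kind == "peak"), 4L)
  ## valley energies match the ground-truth state energies
  v <- pr$markers[pr$markers$kind == "valley", ]
  expect_equal(sort(v$energy), sort(m$energy), tolerance = 0.15)
})

test_that("barriers are read off profiles, including cyclic re-entry", {
  ## simple valley-peak-valley: forward barrier is the peak height
  p <- fake_path(seq(0, 1, 0.05), 10 * sin(pi * seq(0, 1, 0.05))^2)
  pr <- project_1d(p)
  expect_equal(barrier(pr, 1, 2), 10, tolerance = 1e-6)
  expect_equal(barrier(pr, 1, 1), 0)
  expect_error(barrier(pr, 1, 3), "undefined")

  ## smooth downhill staircase: states near 2, 0, -10, -25 kJ/mol with a
  ## 5 kJ/mol hump before state 2 and peaks of 12 and 4 further along. The
  ## cyclic re-entry from the last state into state 2 must climb the hump
  ## AND the net drop: 5 + 25 = 30 (no energy shift on wrap-around)
  lam <- seq(0, 3, by = 0.01)
  lvl <- function(l, at) 1 / (1 + exp(-(l - at) / 0.06))
  shape <- function(l)
    2 - 2 * lvl(l, 0.45) - 10 * lvl(l, 1.35) - 15 * lvl(l, 2.35) +
    3 * exp(-(l - 0.25)^2 / 0.02) + 12 * exp(-(l - 0.9)^2 / 0.02) +
    14 * exp(-(l - 1.9)^2 / 0.02)
  pr2 <- project_1d(fake_path(lam, shape(lam)), min_prominence = 0.2)
  v <- pr2$markers[pr2$markers$kind == "valley", ]
  expect_equal(nrow(v), 4L)
  expect_equal(v$energy, c(2, 0, -10, -25), tolerance = 0.1)
  expect_equal(barrier(pr2, 4, 2), max(v$energy[1] + 3, 5) - v$energy[4],
               tolerance = 0.1)
  expect_equal(barrier(pr2, 4, 2), 30, tolerance = 0.15)
  ## forward barrier between states 2 and 3 for comparison
  expect_equal(barrier(pr2, 2, 3), 12, tolerance = 0.15)
})

test_that("paths round-trip through their CSV table", {
  p <- fake_path(seq(0, 1, 0.1), rep(0, 11))
  f <- tempfile(fileext = ".csv")
  write_path(p, f)
  tab <- read_path_table(f)
  expect_equal(tab$lambda, seq(0, 1, 0.1), tolerance = 1e-12)
  expect_equal(nrow(tab), 11L)
  unlink(f)
})
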