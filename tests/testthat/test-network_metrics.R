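test_that("degree census counts frames per degree and conserves totals", {
  # constant degree 1 over 10 frames
  graphs <- replicate(10, fake_graph(3, cbind(1, 2)), simplify = FALSE)
  cen <- degree_census(graphs, c("s1", "s3"))
  expect_equal(cen$counts$s1, c(0L, 10L))     # N(0)=0, N(1)=10
  expect_equal(cen$counts$s3, 10L)            # never bonded
  df <- as.data.frame(cen)
  expect_equal(sum(df$count[df$site == "s1"]), 10L)
  # zero frames: empty census
  cen0 <- degree_census(list())
  expect_equal(cen0$n_frames, 0L)
  expect_length(cen0$counts, 0L)
  # unknown site label
  expect_error(degree_census(graphs, "nope"), "unknown site")
})

test_that("census conservation holds for every site on random graphs", {
  set.seed(101)
  graphs <- replicate(25, random_graph(12, 0.15), simplify = FALSE)
  cen <- degree_census(graphs, sprintf("s%d", 1:12))
  for (cnt in cen$counts) expect_equal(sum(cnt), 25L)
})

test_that("census histogram totals tie back to twice the edge count", {
  set.seed(55)
  graphs <- replicate(20, random_graph(10, 0.2), simplify = FALSE)
  cen <- degree_census(graphs, sprintf("s%d", 1:10))
  total_degree <- sum(vapply(names(cen$counts), function(s) {
    cnt <- cen$counts[[s]]
    sum((seq_along(cnt) - 1) * cnt)
  }, 0))
  total_edges <- sum(vapply(graphs, function(g) nrow(g$edges), 0L))
  expect_equal(total_degree, 2 * total_edges)
})

test_that("weighted mean degree follows the histogram formula", {
  mk <- function(counts_list, frames) {
    structure(list(counts = counts_list, n_frames = frames),
              class = "degree_census")
  }
  # {2:10} halved -> 1.0 (the divide-by-two water convention)
  cen <- mk(list(O = c(0L, 0L, 10L)), 10L)
  expect_equal(unname(weighted_mean_degree(cen, halve = TRUE)), 1.0)
  expect_equal(unname(weighted_mean_degree(cen)), 2.0)
  # {0:5, 2:5} unhalved -> 1.0
  cen2 <- mk(list(O = c(5L, 0L, 5L)), 10L)
  expect_equal(unname(weighted_mean_degree(cen2)), 1.0)
  # random censuses equal the expanded per-frame mean
  set.seed(77)
  for (k in 1:20) {
    cnt <- as.integer(rpois(6, 4))
    if (sum(cnt) == 0) cnt[1] <- 1L
    cen3 <- mk(list(X = cnt), sum(cnt))
    expanded <- rep(seq_along(cnt) - 1L, cnt)
    expect_equal(unname(weighted_mean_degree(cen3)), mean(expanded))
  }
  # empty census is an error
  expect_error(weighted_mean_degree(mk(list(), 0L)), "undefined")
})

test_that("mean degree recovers the generator's stationary occupancy", {
  tr <- generate_trajectory(synthetic_params(n_waters = 40,
                                             n_frames = 600, seed = 21))
  graphs <- build_frame_graphs(tr$frames, tr$topology)
  cen <- degree_census(graphs, c("O9", "O9p", "O3", "O4", "O4p", "O5p"))
  md <- weighted_mean_degree(cen)
  p_occ <- tr$expectations$occupancy
  # binomial-style error band; autocorrelated frames, so be generous
  se <- sqrt(p_occ * (1 - p_occ) / 600) * 6
  for (s in names(md)) expect_lt(abs(md[[s]] - p_occ), se + 0.02)
})

test_that("halved raw degrees equal molecule-level degrees", {
  # both-hydrogen placement: every bound water contributes two edges
  tr <- generate_trajectory(synthetic_params(n_waters = 25, n_frames = 120,
                                             both_hydrogens = TRUE,
                                             seed = 33))
  graphs <- build_frame_graphs(tr$frames, tr$topology)
  cen <- degree_census(graphs, "O9")
  st <- pair_state_matrix(graphs, "O9", partner_mode = "molecule")
  molecule_mean <- mean(rowSums(st))
  expect_equal(unname(weighted_mean_degree(cen, halve = TRUE)),
               molecule_mean)
})

test_that("Floyd-Warshall reproduces hand-enumerated geodesics", {
  gm <- geodesic_matrix(fake_graph(3, rbind(c(1, 2), c(2, 3))))
  expect_equal(unname(gm$gd[1, 3]), 2)
  expect_equal(unname(diag(gm$gd)), rep(0, 3))
  # two disconnected edges: cross-pairs unreachable
  gm2 <- geodesic_matrix(fake_graph(4, rbind(c(1, 2), c(3, 4))))
  expect_equal(unname(gm2$gd[1, 2]), 1)
  expect_true(is.infinite(gm2$gd[1, 3]) && is.infinite(gm2$gd[2, 4]))
})

test_that("Floyd-Warshall equals BFS on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(1234)
  for (k in 1:100) {
    n <- sample(2:50, 1)
    g <- random_graph(n, runif(1, 0.02, 0.3))
    gm <- geodesic_matrix(g)
    expect_equal(unname(gm$gd), unname(igraph_distances(g)))
  }
})

test_that("geodesic matrices are symmetric and satisfy the triangle bound", {
  set.seed(9)
  for (k in 1:10) {
    gm <- geodesic_matrix(random_graph(20, 0.1))$gd
    expect_equal(gm, t(gm), ignore_attr = TRUE)
    fin <- is.finite(gm)
    for (a in 1:20) for (b in 1:20) if (fin[a, b])
      expect_true(all(gm[a, b] <= gm[a, ] + gm[, b] + 1e-9))
  }
})

test_that("reconstructed geodesic paths are valid shortest paths", {
  set.seed(17)
  g <- random_graph(15, 0.15)
  gm <- geodesic_matrix(g)
  p <- geodesic_paths(gm)
  if (nrow(p)) {
    edge_set <- paste(g$edges$v1, g$edges$v2)
    for (r in sample(nrow(p), min(20, nrow(p)))) {
      verts <- match(strsplit(p$path[r], "->", fixed = TRUE)[[1]],
                     gm$keys)
      expect_equal(length(verts) - 1L, p$distance[r])
      steps <- paste(pmin(verts[-length(verts)], verts[-1]),
                     pmax(verts[-length(verts)], verts[-1]))
      expect_true(all(steps %in% edge_set))
    }
  }
})

test_that("geodesic persistence reports constant runs with durations", {
  graphs <- replicate(20, fake_graph(3, cbind(1, 2)), simplify = FALSE)
  for (i in seq_along(graphs)) graphs[[i]]$frame_index <- i - 1L
  gp <- geodesic_persistence(graphs, "s1", "s2", frame_interval = 0.5)
  expect_equal(nrow(gp$runs), 1L)
  expect_equal(gp$runs$duration_ps, 10)
  expect_equal(gp$runs$gd, 1)
  # alternating connected/disconnected: runs of length one
  alt <- lapply(0:9, function(i) {
    g <- fake_graph(3, if (i %% 2 == 0) cbind(1, 2) else cbind(2, 3))
    g$frame_index <- i
    g
  })
  gp2 <- geodesic_persistence(alt, "s1", "s2", frame_interval = 0.5)
  expect_equal(nrow(gp2$runs), 5L)
  expect_true(all(gp2$runs$length_frames == 1L))
})

test_that("persistence run lengths match the generator's switching law", {
  set.seed(61)
  # two-state Markov edge between s1 and s2 with break probability 0.25:
  # constant-gd runs while connected should average 1/0.25 = 4 frames
  a <- 0.25; b <- 0.5
  s <- markov_series(4000, a, b)
  graphs <- lapply(seq_along(s), function(t) {
    g <- fake_graph(2, if (s[t]) cbind(1, 2) else NULL)
    g$frame_index <- t - 1L
    g
  })
  gp <- geodesic_persistence(graphs, "s1", "s2", frame_interval = 1)
  expect_gt(nrow(gp$runs), 200)
  expect_lt(abs(mean(gp$runs$length_frames) - 1 / a), 0.4)
})
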