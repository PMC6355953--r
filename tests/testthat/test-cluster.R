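test_that("trajectory distances match closed forms and a double-loop oracle", {
  mk_panel <- function(traj) {
    do.call(rbind, lapply(seq_along(traj), function(i) {
      data.frame(player_id = sprintf("p%02d", i), round = seq_along(traj[[i]]),
                 r = 2, contribution = traj[[i]], is_robot = FALSE)
    }))
  }
  same <- mk_panel(list(rep(5L, 30), rep(5L, 30)))
  expect_equal(trajectory_distances(same)["p01", "p02"], 0)
  extreme <- mk_panel(list(rep(0L, 30), rep(20L, 30)))
  expect_equal(trajectory_distances(extreme)["p01", "p02"], 20 * sqrt(30))

  panel <- sim_markov_panel(8, persistent_matrix(0.5), seed = 66, n_rounds = 12)
  D <- trajectory_distances(panel)
  human <- panel[!panel$is_robot, ]
  for (a in rownames(D)) for (b in colnames(D)) {
    xa <- human$contribution[human$player_id == a][order(human$round[human$player_id == a])]
    xb <- human$contribution[human$player_id == b][order(human$round[human$player_id == b])]
    expect_equal(D[a, b], sqrt(sum((xa - xb)^2)))
  }
  expect_true(all(abs(D - t(D)) < 1e-12))
  expect_true(all(diag(D) == 0))

  incomplete <- panel[-5, ]
  expect_error(trajectory_distances(incomplete), "incomplete trajectories")
})

test_that("forced merge orders come out as expected on 1-D points", {
  D <- as.matrix(dist(c(0, 1, 10)))
  dend <- complete_linkage(D)
  expect_equal(dend$height, c(1, 10))
  expect_equal(dendrogram_merge_sets(dend), list(c(1L, 2L), c(1L, 2L, 3L)))
  # duplicated points merge at height zero first
  D2 <- as.matrix(dist(c(3, 7, 3)))
  dend2 <- complete_linkage(D2)
  expect_equal(dend2$height[1], 0)
  expect_equal(dendrogram_merge_sets(dend2)[[1]], c(1L, 3L))
  expect_error(complete_linkage(matrix(0, 1, 1)), "at least two")
})

test_that("merge sequences equal the exhaustive-search oracle on random instances", {
  set.seed(7)
  for (rep in 1:30) {
    X <- matrix(runif(6 * 3), 6, 3)
    D <- as.matrix(dist(X))
    dend <- complete_linkage(D)
    oracle <- brute_force_complete_linkage(D)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-12)
    expect_equal(dendrogram_merge_sets(dend), oracle$merges)
    expect_true(all(diff(dend$height) >= -1e-12))  # no inversions
  }
})

test_that("heights agree with hclust's complete linkage", {
  set.seed(8)
  X <- matrix(runif(12 * 4), 12, 4)
  D <- as.matrix(dist(X))
  dend <- complete_linkage(D)
  h <- hclust(as.dist(D), method = "complete")
  expect_equal(dend$height, h$height, tolerance = 1e-12)
  for (k in c(2, 4, 6)) {
    ours <- cut_clusters(dend, k)
    theirs <- cutree(h, k)
    # same partition up to relabeling
    expect_equal(length(unique(paste(ours, theirs))), k)
  }
})

test_that("permuting input order changes neither heights nor the partition", {
  set.seed(9)
  X <- matrix(runif(10 * 5), 10, 5)
  rownames(X) <- sprintf("p%02d", 1:10)
  D <- as.matrix(dist(X))
  perm <- sample(10)
  Dp <- D[perm, perm]
  d1 <- complete_linkage(D)
  d2 <- complete_linkage(Dp)
  expect_equal(sort(d1$height), sort(d2$height), tolerance = 1e-12)
  a1 <- cut_clusters(d1, 3)
  a2 <- cut_clusters(d2, 3)[names(a1)]
  expect_equal(length(unique(paste(a1, a2))), 3L)
})

test_that("cuts respect the merge hierarchy and number clusters deterministically", {
  D <- as.matrix(dist(c(0, 1, 10)))
  dend <- complete_linkage(D)
  expect_equal(unname(cut_clusters(dend, 1)), c(1L, 1L, 1L))
  expect_equal(unname(cut_clusters(dend, 2)), c(1L, 1L, 2L))
  expect_equal(unname(cut_clusters(dend, 3)), c(1L, 2L, 3L))
  expect_error(cut_clusters(dend, 4), "1\\.\\.3")
})

test_that("cluster profiles tally level shares per cluster", {
  panel <- rbind(
    sim_markov_panel(6, iid_matrix(c(0, 0, 0, 0, 1)), seed = 70, n_rounds = 10,
                     init = c(0, 0, 0, 0, 1)),
    sim_markov_panel(6, iid_matrix(c(1, 0, 0, 0, 0)), seed = 71, n_rounds = 10,
                     init = c(1, 0, 0, 0, 0), session_id = "S2"))
  D <- trajectory_distances(panel)
  dend <- complete_linkage(D)
  assign <- cut_clusters(dend, 2)
  prof <- cluster_profiles(assign, panel)
  share_cols <- paste0("share_", level_labels)
  expect_true(all(abs(rowSums(prof[share_cols]) - 100) < 1e-9))
  # one pure full-contribution cluster, one pure free-riding cluster
  expect_setequal(round(prof$share_L5), c(100, 0))
  expect_setequal(round(prof$share_L1), c(100, 0))
  expect_equal(sort(prof$size), c(6L, 6L))
  # brute-force tally oracle for one cluster
  g1 <- names(assign)[assign == 1]
  human <- panel[!panel$is_robot & panel$player_id %in% g1, ]
  tal <- table(factor(discretize_contribution(human$contribution), levels = 1:5))
  expect_equal(as.numeric(prof[1, share_cols]),
               as.numeric(100 * tal / sum(tal)))
})

test_that("clear player clusters are detected as significant structure", {
  panel <- rbind(
    sim_markov_panel(6, iid_matrix(c(0, 0, 0, 0.2, 0.8)), seed = 80, n_rounds = 8),
    sim_markov_panel(6, iid_matrix(c(0.8, 0.2, 0, 0, 0)), seed = 81, n_rounds = 8,
                     session_id = "S2"))
  res <- cluster_significance(panel, reps = 99, seed = 5)
  expect_lt(res$p_value, 0.05)
  # exchangeable contributions: no structure
  panel2 <- sim_markov_panel(12, iid_matrix(), seed = 82, n_rounds = 8)
  res2 <- cluster_significance(panel2, reps = 99, seed = 6)
  expect_gt(res2$p_value, 0.05)
})

test_that("newick export writes a tree with all players as tips", {
  panel <- sim_markov_panel(7, persistent_matrix(0.5), seed = 90, n_rounds = 6)
  dend <- complete_linkage(trajectory_distances(panel))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, dend$labels)
})
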