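#' Euclidean distances between contribution trajectories
#'
#' Treats each human player's round-ordered contribution vector over the
#' retained rounds as a point in R^P (P = number of retained rounds; 30 for
#' an unfiltered session, 15 for the r = 2 rounds of the alternating
#' treatment) and returns the pairwise Euclidean distance matrix.
#'
#' @inheritParams mean_contribution_by_round
#' @return A symmetric matrix with zero diagonal, players as dimnames, and
#'   attributes `metric` and `rounds`.
#' @export
trajectory_distances <- function(panel, r_filter = NULL) {
  panel <- .filter_panel(panel, r_filter)
  if (nrow(panel) == 0L) stop("no observations left after filtering", call. = FALSE)
  rounds <- sort(unique(panel$round))
  players <- sort(unique(panel$player_id))
  X <- matrix(NA_real_, nrow = length(players), ncol = length(rounds),
              dimnames = list(players, rounds))
  idx <- cbind(match(panel$player_id, players), match(panel$round, rounds))
  X[idx] <- panel$contribution
  bad <- rowSums(is.na(X)) > 0
  if (any(bad)) {
    stop("incomplete trajectories for player(s): ",
         paste(players[bad], collapse = ", "), call. = FALSE)
  }
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  attr(D, "metric") <- "euclidean"
  attr(D, "rounds") <- rounds
  D
}

#' Complete-linkage agglomerative clustering
#'
#' Starting from singletons, repeatedly merges the pair of clusters whose
#' complete-linkage distance — the maximum pairwise distance between their
#' members — is smallest; the merge height records that distance. Complete
#' linkage guarantees the heights are non-decreasing. When several pairs
#' tie for the minimal distance, the pair containing the lowest member
#' index is merged (comparing the other member next), which makes the
#' merge order deterministic and independent of input order.
#'
#' @param d A symmetric distance matrix, e.g. from
#'   [trajectory_distances()].
#' @return An object of class `"pgg_dendrogram"`: a list with `merge` and
#'   `height` in [stats::hclust()] convention, `labels`, and `order`. Use
#'   [as.hclust()] for plotting or [write_newick()] for export.
#' @export
complete_linkage <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("at least two observations are required", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0)) {
    stop("`d` must be a symmetric matrix with zero diagonal", call. = FALSE)
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  members <- as.list(seq_len(n))       # leaf indices per active cluster
  node_id <- as.integer(-seq_len(n))   # hclust convention: leaves negative
  active <- rep(TRUE, n)
  link <- D                            # complete-linkage distances
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    best_d <- Inf
    for (ai in seq_along(act)[-length(act)]) {
      for (bi in seq((ai + 1L), length(act))) {
        i <- act[ai]; j <- act[bi]
        dij <- link[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        } else if (dij < best_d + 1e-12) {
          # tie: prefer the pair with the lowest member index, then the
          # lowest index in the other cluster
          cand <- sort(c(min(members[[i]], members[[j]]),
                         max(min(members[[i]]), min(members[[j]]))))
          cur <- sort(c(min(members[[best[1]]], members[[best[2]]]),
                        max(min(members[[best[1]]]), min(members[[best[2]]]))))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best_d <- min(best_d, dij); best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- sort(c(node_id[i], node_id[j]),
                       decreasing = FALSE)
    # hclust orders singleton entries (negative) before cluster entries
    if (merge[s, 1] > 0 && merge[s, 2] < 0) merge[s, ] <- merge[s, 2:1]
    height[s] <- link[i, j]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    node_id[i] <- s
    active[j] <- FALSE
    for (k in which(active)) {
      if (k != i) {
        m <- max(link[i, k], link[j, k])
        link[i, k] <- m; link[k, i] <- m
      }
    }
  }

  ord <- .dendrogram_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, method = "complete",
                 dist.method = attr(d, "metric")),
            class = "pgg_dendrogram")
}

.dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' @export
as.hclust.pgg_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method, call = match.call()),
            class = "hclust")
}

#' @export
print.pgg_dendrogram <- function(x, ...) {
  cat(sprintf("Complete-linkage dendrogram over %d trajectories\n",
              length(x$labels)))
  cat(sprintf("  merge heights %.3f .. %.3f\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' @export
plot.pgg_dendrogram <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges and returns the resulting partition.
#' Clusters are numbered deterministically: cluster 1 contains the
#' lowest-indexed player, cluster 2 the lowest-indexed player not in
#' cluster 1, and so on.
#'
#' @param dend A [complete_linkage()] dendrogram.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return A named integer vector mapping each player to a cluster.
#' @export
cut_clusters <- function(dend, k) {
  stopifnot(inherits(dend, "pgg_dendrogram"))
  n <- length(dend$labels)
  if (k < 1L || k > n) stop(sprintf("`k` must lie in 1..%d", n), call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  cluster_of_node <- integer(n - 1L)   # leaf representative per merge node
  n_keep <- n - k
  for (s in seq_len(n_keep)) {
    a <- dend$merge[s, 1L]; b <- dend$merge[s, 2L]
    ra <- if (a < 0L) find(-a) else find(cluster_of_node[a])
    rb <- if (b < 0L) find(-b) else find(cluster_of_node[b])
    parent[rb] <- ra
    cluster_of_node[s] <- ra
  }
  if (n_keep < n - 1L) {
    for (s in seq((n_keep + 1L), n - 1L)) {
      a <- dend$merge[s, 1L]
      cluster_of_node[s] <- if (a < 0L) find(-a) else cluster_of_node[a]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first_seen <- unique(roots)              # ordered by leaf index
  assign <- match(roots, first_seen)
  names(assign) <- dend$labels
  assign
}

#' Level profile of each cluster
#'
#' For every cluster, tallies all of its members' retained round
#' observations by contribution level and reports percentages.
#'
#' @param assignment Named vector from [cut_clusters()].
#' @param panel The panel the clustering was computed from.
#' @param r_filter The same filter used for [trajectory_distances()].
#' @return A `data.frame` with columns `cluster`, `size`, `n_obs`, and
#'   `share_L1` .. `share_L5` (percent, summing to 100 per cluster).
#' @export
cluster_profiles <- function(assignment, panel, r_filter = NULL) {
  panel <- .filter_panel(panel, r_filter)
  missing <- setdiff(unique(panel$player_id), names(assignment))
  if (length(missing)) {
    stop("assignment does not cover player(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lev <- discretize_contribution(panel$contribution)
  cl <- assignment[panel$player_id]
  out <- lapply(sort(unique(assignment)), function(g) {
    sel <- cl == g
    counts <- tabulate(lev[sel], nbins = 5L)
    row <- data.frame(cluster = g, size = sum(assignment == g),
                      n_obs = sum(sel))
    row[paste0("share_", level_labels)] <- as.list(100 * counts / sum(counts))
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Permutation test of clustering structure
#'
#' Quantifies whether player trajectories carry more hierarchical
#' structure than expected if contributions were exchangeable across
#' players within each round. The statistic is the cophenetic correlation
#' of the complete-linkage dendrogram; the null distribution permutes each
#' round's contributions independently across players (preserving every
#' per-round marginal while destroying within-player persistence). This is
#' one reasonable operationalization of cluster "significance", not a
#' canonical one.
#'
#' @inheritParams trajectory_distances
#' @param reps Number of permutation replicates.
#' @param seed Optional seed.
#' @return A list with `statistic` (observed cophenetic correlation),
#'   `p_value`, and `null` (the replicate values).
#' @export
cluster_significance <- function(panel, r_filter = NULL, reps = 200L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- .filter_panel(panel, r_filter)
  coph_cor <- function(p) {
    D <- trajectory_distances(cbind(p, is_robot = FALSE))
    h <- stats::as.hclust(complete_linkage(D))
    stats::cor(stats::as.dist(D), stats::cophenetic(h))
  }
  base <- panel[c("player_id", "round", "r", "contribution")]
  obs <- coph_cor(base)
  null <- vapply(seq_len(reps), function(b) {
    perm <- base
    for (t in unique(perm$round)) {
      sel <- perm$round == t
      perm$contribution[sel] <- sample(perm$contribution[sel])
    }
    coph_cor(perm)
  }, numeric(1))
  list(statistic = obs, p_value = (1 + sum(null >= obs)) / (1 + reps),
       null = null)
}

#' Heuristic cluster count from the largest relative height gap
#'
#' Suggests `k` as the cut below the largest relative gap between
#' consecutive merge heights. Offered as a labelled heuristic only; it is
#' never applied implicitly.
#'
#' @param dend A [complete_linkage()] dendrogram.
#' @param k_max Largest k considered.
#' @return A single integer k.
#' @export
suggest_k <- function(dend, k_max = 10L) {
  h <- rev(dend$height)                 # highest merge first
  k_max <- min(k_max, length(h))
  gaps <- h[seq_len(k_max - 1L)] / pmax(h[seq_len(k_max - 1L) + 1L], 1e-12)
  which.max(gaps) + 1L
}

#' Export a dendrogram in Newick format
#'
#' Writes the merge tree with branch lengths derived from the merge
#' heights, readable by standard tree viewers.
#'
#' @param dend A [complete_linkage()] dendrogram.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}
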