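# shared builders for small in-code fixtures

mid_init <- c(0.10, 0.15, 0.40, 0.15, 0.20)

# strongly persistent 5-state matrix (diagonal-dominant)
persistent_matrix <- function(stay = 0.8) {
  P <- matrix((1 - stay) / 4, 5, 5)
  diag(P) <- stay
  P
}

# i.i.d. levels: every row the same distribution
iid_matrix <- function(p = rep(0.2, 5)) {
  matrix(p, 5, 5, byrow = TRUE)
}

sim_markov_panel <- function(n_players, P, seed, n_rounds = 30L,
                             treatment = "homogeneous", init = mid_init,
                             drift = 0, session_id = "S1") {
  cfg <- game_config(treatment, n_rounds = n_rounds)
  active <- if (treatment == "heterogeneous") "odd" else "all"
  off <- if (treatment == "heterogeneous") c(0.05, 0.05, 0.15, 0.14, 0.61) else NULL
  pol <- rep(list(markov_policy(init, P, drift = drift, active = active,
                                off_round_dist = off)), n_players)
  simulate_session(session_plan(session_id, n_players, treatment, seed),
                   pol, cfg)
}

# exhaustive complete-linkage oracle: cluster distances recomputed from the
# raw matrix at every step (max over all member pairs), same tie-break rule
brute_force_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m)) {
      dd <- max(D[clusters[[a]], clusters[[b]]])
      pick <- FALSE
      if (dd < best_d - 1e-12) pick <- TRUE
      else if (dd < best_d + 1e-12) {
        cand <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        cur <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
        pick <- cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
      }
      if (pick) { best <- c(a, b); best_d <- dd }
    }
    heights[s] <- best_d
    merges[[s]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merges[[s]]
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# member sets produced by each merge of a pgg_dendrogram, for comparison
dendrogram_merge_sets <- function(dend) {
  n <- length(dend$labels)
  sets <- vector("list", n - 1L)
  leaves_of <- function(node) {
    if (node < 0L) return(-node)
    sets[[node]]
  }
  for (s in seq_len(n - 1L)) {
    sets[[s]] <- sort(c(leaves_of(dend$merge[s, 1L]),
                        leaves_of(dend$merge[s, 2L])))
  }
  sets
}
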