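test_that("a 7-player session pads the short group with one robot, every round", {
  cfg <- game_config("homogeneous", n_rounds = 10)
  panel <- simulate_session(session_plan("S1", 7, "homogeneous", seed = 3),
                            rep(list(free_rider()), 7), cfg)
  for (t in unique(panel$round)) {
    rt <- panel[panel$round == t, ]
    expect_equal(nrow(rt), 8L)             # 2 complete groups of 4
    expect_equal(sum(rt$is_robot), 1L)
    sizes <- table(rt$group_id)
    expect_true(all(sizes == 4L))
    expect_true(all(rt$contribution[rt$is_robot] == 0L))
  }
})

test_that("all-full-contributor play at r = 2 pays 40 in robot-free groups", {
  cfg <- game_config("homogeneous", n_rounds = 5)
  panel <- simulate_session(session_plan("S1", 8, "homogeneous", seed = 1),
                            rep(list(full_contributor()), 8), cfg)
  expect_true(all(panel$payoff == 40))
})

test_that("the same seed reproduces the panel exactly", {
  cfg <- game_config("heterogeneous", n_rounds = 8)
  gen <- function() make_reference_generator(cfg, n_players = 9)
  p1 <- simulate_session(session_plan("X", 9, "heterogeneous", seed = 99), gen(), cfg)
  p2 <- simulate_session(session_plan("X", 9, "heterogeneous", seed = 99), gen(), cfg)
  expect_identical(p1, p2)
})

test_that("unknown policy kinds and invalid parameters are rejected", {
  cfg <- game_config("homogeneous", n_rounds = 2)
  fake <- structure(list(kind = "psychic"), class = "agent_policy")
  expect_error(simulate_session(session_plan("S", 4, "homogeneous", 1),
                                rep(list(fake), 4), cfg), "unknown policy kind")
  expect_error(markov_policy(c(0.5, 0.5, 0.5, 0, 0), persistent_matrix()),
               "summing to 1")
  expect_error(markov_policy(mid_init, matrix(1, 5, 5)), "rows summing to 1")
  expect_error(markov_policy(mid_init, persistent_matrix(), active = "odd"),
               "off_round_dist")
})

test_that("markov agents emit contributions inside their level's token range", {
  P <- persistent_matrix(0.6)
  panel <- sim_markov_panel(30, P, seed = 21, n_rounds = 15)
  human <- panel[!panel$is_robot, ]
  lev <- discretize_contribution(human$contribution)
  ranges <- list(0L, 1:5, 6:14, 15:19, 20L)
  for (k in 1:5) {
    expect_true(all(human$contribution[lev == k] %in% ranges[[k]]))
  }
})

test_that("empirical level-transition frequencies converge to the generator", {
  M <- reference_matrix("homogeneous")
  panel <- sim_markov_panel(500, M, seed = 404)
  pairs <- transition_pairs(level_sequences(panel))
  emp <- matrix(0, 5, 5)
  for (i in seq_len(nrow(pairs))) {
    emp[pairs$origin[i], pairs$dest[i]] <- emp[pairs$origin[i], pairs$dest[i]] + 1
  }
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - M)), 0.05)
})

test_that("group shuffling is uniform: share-a-group frequency matches 3/7 for n = 8", {
  cfg <- game_config("custom", n_rounds = 600, r_schedule = rep(2, 600))
  panel <- simulate_session(session_plan("S", 8, "homogeneous", seed = 17),
                            rep(list(free_rider()), 8), cfg)
  a <- panel[panel$player_id == "S_P01", c("round", "group_id")]
  b <- panel[panel$player_id == "S_P02", c("round", "group_id")]
  shared <- mean(a$group_id[order(a$round)] == b$group_id[order(b$round)])
  p <- 3 / 7
  expect_lt(abs(shared - p), 3.5 * sqrt(p * (1 - p) / 600))
})

test_that("robot padding keeps human payoffs on the payoff equation", {
  cfg <- game_config("homogeneous", n_rounds = 6)
  panel <- simulate_session(session_plan("S", 5, "homogeneous", seed = 9),
                            rep(list(conditional_cooperator(alpha = 2)), 5), cfg)
  expect_equal(nrow(validate_panel(panel, cfg)), 0L)
})

test_that("conditional cooperators track the others' previous average", {
  cfg <- game_config("homogeneous", n_rounds = 12)
  # one perfect matcher among three constant full contributors
  pols <- c(list(conditional_cooperator(alpha = 0, beta = 1)),
            rep(list(full_contributor()), 3))
  panel <- simulate_session(session_plan("S", 4, "homogeneous", seed = 2), pols, cfg)
  cc <- panel[panel$player_id == "S_P01" & panel$round > 1, ]
  expect_true(all(cc$contribution == 20L))
})

test_that("session order is stable when sessions are appended", {
  a <- simulate_study(5, sizes_homogeneous = c(8L), sizes_heterogeneous = integer(0),
                      n_rounds = 4)
  b <- simulate_study(5, sizes_homogeneous = c(8L, 7L), sizes_heterogeneous = integer(0),
                      n_rounds = 4)
  bb <- b[b$session_id == "H1", ]
  rownames(bb) <- NULL
  expect_identical(a, bb)
})
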