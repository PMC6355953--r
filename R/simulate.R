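#' Describe one experimental session
#'
#' @param session_id Character label, unique within a study.
#' @param n_players Number of human participants (at least 1).
#' @param treatment Treatment label recorded in the panel.
#' @param seed Integer seed for the session's private random stream, or
#'   `NULL` to use the current RNG state.
#' @return An object of class `"session_plan"`.
#' @export
session_plan <- function(session_id, n_players, treatment, seed = NULL) {
  n_players <- as.integer(n_players)
  if (n_players < 1L) stop("`n_players` must be at least 1", call. = FALSE)
  structure(list(session_id = as.character(session_id), n_players = n_players,
                 treatment = as.character(treatment), seed = seed),
            class = "session_plan")
}

.sample_level <- function(p) sample.int(5L, 1L, prob = p)

.level_contribution <- function(level) {
  tok <- level_tokens(level)
  if (length(tok) == 1L) tok else sample(tok, 1L)
}

.drifted <- function(P, drift, step) {
  if (drift <= 0 || step <= 1L) return(P)
  d <- min(1, drift * (step - 1L))
  Q <- matrix(0, 5, 5); Q[, 1] <- 1
  (1 - d) * P + d * Q
}

#' Simulate one session of the repeated public goods game
#'
#' Plays `config$n_rounds` rounds. Each round, the human players are
#' partitioned uniformly at random into groups of `config$group_size`; when
#' the session size is not a multiple of the group size, the single
#' under-filled group is completed with robots that contribute zero tokens.
#' Contributions come from each player's [agent_policy]; payoffs follow
#' [compute_payoffs()] with the round's multiplier. Agents observe only
#' their own history (own contribution, own payoff, own group's total), as
#' in the experimental interface.
#'
#' Given the same `plan$seed`, policies, and configuration, the returned
#' panel is identical across calls.
#'
#' @param plan A [session_plan()].
#' @param policies List of `plan$n_players` [agent_policy] objects.
#' @param config A [game_config()].
#' @return A `data.frame` in long panel format with one row per (player,
#'   round), columns `session_id`, `player_id`, `round`, `group_id`,
#'   `treatment`, `r`, `contribution`, `payoff`, `is_robot`. Robots appear
#'   as additional rows so every group is complete.
#' @export
simulate_session <- function(plan, policies, config = game_config()) {
  stopifnot(inherits(plan, "session_plan"))
  n <- plan$n_players
  if (length(policies) != n) {
    stop("`policies` must supply one policy per human player", call. = FALSE)
  }
  kinds <- vapply(policies, function(p) {
    if (!inherits(p, "agent_policy")) {
      stop("each policy must be an `agent_policy`", call. = FALSE)
    }
    p$kind
  }, character(1))
  known <- c("markov_policy", "free_rider", "full_contributor",
             "conditional_cooperator")
  if (any(!kinds %in% known)) {
    stop("unknown policy kind: ", paste(setdiff(kinds, known), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(plan$seed)) set.seed(plan$seed)

  gs <- config$group_size
  w <- config$endowment
  n_rounds <- config$n_rounds
  n_groups <- ceiling(n / gs)
  n_robots <- n_groups * gs - n
  player_ids <- sprintf("%s_P%02d", plan$session_id, seq_len(n))
  robot_ids <- if (n_robots > 0) sprintf("%s_R%02d", plan$session_id,
                                         seq_len(n_robots)) else character(0)

  cur_level <- integer(n)      # markov chain state (also cond-coop round 1)
  step_count <- integer(n)     # transitions taken so far, per markov agent
  prev_own_c <- rep(NA_real_, n)
  prev_own_G <- rep(NA_real_, n)

  rows <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    r_t <- config$r_schedule[t]
    contrib <- integer(n)
    for (i in seq_len(n)) {
      pol <- policies[[i]]
      contrib[i] <- switch(pol$kind,
        free_rider = 0L,
        full_contributor = w,
        markov_policy = {
          if (pol$active == "all") {
            if (t == 1L) {
              cur_level[i] <- .sample_level(pol$init)
            } else {
              step_count[i] <- step_count[i] + 1L
              P <- .drifted(pol$P, pol$drift, step_count[i])
              cur_level[i] <- .sample_level(P[cur_level[i], ])
            }
            .level_contribution(cur_level[i])
          } else {                       # chain lives on the odd rounds
            if (t %% 2L == 0L) {
              .level_contribution(.sample_level(pol$off_round_dist))
            } else {
              if (t == 1L) {
                cur_level[i] <- .sample_level(pol$init)
              } else {
                step_count[i] <- step_count[i] + 1L
                P <- .drifted(pol$P, pol$drift, step_count[i])
                cur_level[i] <- .sample_level(P[cur_level[i], ])
              }
              .level_contribution(cur_level[i])
            }
          }
        },
        conditional_cooperator = {
          if (t == 1L) {
            .level_contribution(.sample_level(pol$init_dist))
          } else {
            others_avg <- (prev_own_G[i] - prev_own_c[i]) / (gs - 1)
            as.integer(min(w, max(0, round(pol$alpha + pol$beta * others_avg))))
          }
        })
    }

    perm <- sample.int(n)
    group_of <- integer(n)
    group_of[perm] <- ceiling(seq_len(n) / gs)

    round_rows <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      members <- which(group_of == g)
      pad <- gs - length(members)
      g_contrib <- c(contrib[members], rep(0L, pad))
      out <- compute_payoffs(g_contrib, r_t, config)
      ids <- c(player_ids[members],
               if (pad > 0) robot_ids[seq_len(pad)] else character(0))
      round_rows[[g]] <- data.frame(
        session_id = plan$session_id, player_id = ids, round = t,
        group_id = g, treatment = plan$treatment, r = r_t,
        contribution = out$contributions, payoff = out$payoffs,
        is_robot = c(rep(FALSE, length(members)), rep(TRUE, pad)),
        stringsAsFactors = FALSE)
      prev_own_c[members] <- contrib[members]
      prev_own_G[members] <- out$total_contribution
    }
    rows[[t]] <- do.call(rbind, round_rows)
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel
}

#' Simulate a full two-treatment study
#'
#' Reproduces the deposited study's design: three homogeneous sessions of
#' 13, 16 and 7 participants and three heterogeneous sessions of 14, 14 and
#' 7, each playing 30 rounds in randomly reshuffled groups of 4. Players
#' follow the treatment's [make_reference_generator()] population unless
#' `policies_fn` overrides it. Each session draws its seed from the master
#' seed in order, so adding sessions to the end of a size list never
#' changes earlier sessions.
#'
#' @param seed Master integer seed.
#' @param sizes_homogeneous,sizes_heterogeneous Session-size vectors; either
#'   may be empty to skip that treatment.
#' @param drift Passed to [make_reference_generator()].
#' @param n_rounds Rounds per session.
#' @param policies_fn Optional `function(config, treatment, n_players)`
#'   returning the session's policy list.
#' @return A combined long-format panel `data.frame` (see
#'   [simulate_session()]).
#' @export
simulate_study <- function(seed = 1L,
                           sizes_homogeneous = c(13L, 16L, 7L),
                           sizes_heterogeneous = c(14L, 14L, 7L),
                           drift = 0, n_rounds = 30L,
                           policies_fn = NULL) {
  set.seed(seed)
  plans <- list()
  for (k in seq_along(sizes_homogeneous)) {
    plans[[length(plans) + 1L]] <- list(id = sprintf("H%d", k),
                                        n = sizes_homogeneous[k],
                                        treatment = "homogeneous")
  }
  for (k in seq_along(sizes_heterogeneous)) {
    plans[[length(plans) + 1L]] <- list(id = sprintf("X%d", k),
                                        n = sizes_heterogeneous[k],
                                        treatment = "heterogeneous")
  }
  panels <- vector("list", length(plans))
  for (k in seq_along(plans)) {
    p <- plans[[k]]
    s <- sample.int(.Machine$integer.max, 1L)
    config <- game_config(p$treatment, n_rounds = n_rounds)
    policies <- if (is.null(policies_fn)) {
      make_reference_generator(config, n_players = p$n, drift = drift)
    } else {
      policies_fn(config, p$treatment, p$n)
    }
    panels[[k]] <- simulate_session(
      session_plan(p$id, p$n, p$treatment, seed = s), policies, config)
  }
  out <- do.call(rbind, panels)
  rownames(out) <- NULL
  out
}
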