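#' Agent policies for the session simulator
#'
#' Policies describe how a simulated player chooses a contribution each
#' round. Four kinds are available:
#'
#' * `markov_policy()` — the player occupies one of the five contribution
#'   levels and moves between them according to a 5x5 transition matrix,
#'   emitting a token amount drawn uniformly from the level's range (levels
#'   1 and 5 are the degenerate amounts 0 and 20). With `active = "odd"`
#'   the level chain is observed and stepped on odd rounds only — the
#'   design used for the social-dilemma rounds of the alternating
#'   treatment — and on even rounds the player emits from `off_round_dist`.
#' * `free_rider()` — always contributes 0.
#' * `full_contributor()` — always contributes the endowment.
#' * `conditional_cooperator()` — matches the average contribution the rest
#'   of the group made in the previous round:
#'   `clip(round(alpha + beta * (G_prev - c_prev) / (n - 1)), 0, w)`, with
#'   the first round drawn from `init_dist` over levels.
#'
#' @param init Length-5 initial level distribution (sums to 1).
#' @param P 5x5 row-stochastic level transition matrix.
#' @param drift Non-negative rate of a linear drift of mass toward level 1:
#'   at transition step s the matrix used is
#'   `(1 - d) * P + d * Q` with `d = min(1, drift * (s - 1))` and Q the
#'   matrix sending every state to level 1. `0` (the default) keeps `P`
#'   constant across rounds.
#' @param active `"all"` (chain stepped every round) or `"odd"` (chain
#'   stepped between consecutive odd rounds).
#' @param off_round_dist Length-5 level distribution used on even rounds
#'   when `active = "odd"`.
#' @param alpha,beta Intercept and slope of the conditional cooperator's
#'   response, in tokens.
#' @param init_dist Length-5 level distribution for a conditional
#'   cooperator's first round.
#'
#' @return An object of class `"agent_policy"`.
#' @name agent_policy
NULL

.check_dist <- function(p, what) {
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must be a length-5 probability vector summing to 1", what),
         call. = FALSE)
  }
  as.numeric(p)
}

.check_stochastic <- function(P, what = "transition matrix", tol = 1e-9) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(5L, 5L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > tol)) {
    stop(sprintf("%s must be 5x5 with non-negative rows summing to 1", what),
         call. = FALSE)
  }
  unname(P)
}

#' @rdname agent_policy
#' @export
markov_policy <- function(init, P, drift = 0,
                          active = c("all", "odd"), off_round_dist = NULL) {
  active <- match.arg(active)
  init <- .check_dist(init, "`init`")
  P <- .check_stochastic(P)
  stopifnot(is.numeric(drift), length(drift) == 1L, drift >= 0)
  if (active == "odd") {
    if (is.null(off_round_dist)) {
      stop("`off_round_dist` is required when `active = \"odd\"`", call. = FALSE)
    }
    off_round_dist <- .check_dist(off_round_dist, "`off_round_dist`")
  }
  structure(list(kind = "markov_policy", init = init, P = P, drift = drift,
                 active = active, off_round_dist = off_round_dist),
            class = "agent_policy")
}

#' @rdname agent_policy
#' @export
free_rider <- function() {
  structure(list(kind = "free_rider"), class = "agent_policy")
}

#' @rdname agent_policy
#' @export
full_contributor <- function() {
  structure(list(kind = "full_contributor"), class = "agent_policy")
}

#' @rdname agent_policy
#' @export
conditional_cooperator <- function(alpha = 0, beta = 1,
                                   init_dist = c(0.1, 0.2, 0.4, 0.2, 0.1)) {
  structure(list(kind = "conditional_cooperator", alpha = alpha, beta = beta,
                 init_dist = .check_dist(init_dist, "`init_dist`")),
            class = "agent_policy")
}

#' Packaged round-10 transition-matrix estimates
#'
#' Loads the round-10 level transition matrix reported for the homogeneous
#' treatment or for the social-dilemma (r = 2) rounds of the heterogeneous
#' treatment. The matrices ship as printed, to two decimals; one row of the
#' homogeneous matrix sums to 0.99 due to rounding, so rows are
#' renormalized to sum to exactly 1 by default.
#'
#' @param treatment `"homogeneous"` or `"heterogeneous_r2"`.
#' @param normalize Renormalize each row to sum to 1 (default `TRUE`).
#' @return A 5x5 matrix with dimnames `L1..L5`.
#' @examples
#' reference_matrix("homogeneous")["L5", "L5"]      # 0.54
#' reference_matrix("heterogeneous_r2")["L5", "L5"] # 0.76
#' @export
reference_matrix <- function(treatment = c("homogeneous", "heterogeneous_r2"),
                             normalize = TRUE) {
  treatment <- match.arg(treatment)
  file <- switch(treatment,
    homogeneous = "transition_homogeneous_round10.csv",
    heterogeneous_r2 = "transition_heterogeneous_r2_round10.csv")
  path <- system.file("extdata", file, package = "pggmarkov", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(tab[, level_labels])
  rownames(M) <- tab$level
  if (normalize) M <- M / rowSums(M)
  M
}

#' Default population of Markov-level agents for a treatment
#'
#' Builds `n_players` identical [markov_policy()] agents whose level
#' transition matrix is the packaged round-10 estimate for the requested
#' treatment, held constant across rounds unless `drift > 0`. For the
#' heterogeneous treatment the chain is active on odd (r = 2) rounds and
#' even (r = 6) rounds emit from a high-contribution level distribution
#' with 61% of its mass on full contribution.
#'
#' @param config A [game_config()].
#' @param treatment `"homogeneous"` or `"heterogeneous"`; defaults to the
#'   configuration's treatment.
#' @param n_players Number of policies to return.
#' @param drift Passed to [markov_policy()].
#' @param init Initial level distribution; the default places most mass on
#'   intermediate contributions, the typical opening of repeated public
#'   goods play.
#' @return A list of `n_players` agent policies.
#' @export
make_reference_generator <- function(config, treatment = config$treatment,
                                     n_players, drift = 0,
                                     init = c(0.10, 0.15, 0.40, 0.15, 0.20)) {
  treatment <- match.arg(treatment, c("homogeneous", "heterogeneous"))
  if (treatment == "homogeneous") {
    pol <- markov_policy(init, reference_matrix("homogeneous"), drift = drift)
  } else {
    pol <- markov_policy(init, reference_matrix("heterogeneous_r2"),
                         drift = drift, active = "odd",
                         off_round_dist = c(0.05, 0.05, 0.15, 0.14, 0.61))
  }
  rep(list(pol), n_players)
}
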