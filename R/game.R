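#' Configure a repeated public goods game
#'
#' A game configuration holds the exogenous variables of a repeated public
#' goods experiment: the group size \eqn{n}, the per-round endowment \eqn{w},
#' the number of rounds, and the schedule of synergy multipliers
#' \eqn{r_t > 1}. Two presets reproduce the standard designs: the
#' `"homogeneous"` treatment plays \eqn{r = 2} in every round, while the
#' `"heterogeneous"` treatment alternates \eqn{r = 2} in odd rounds with
#' \eqn{r = 6} in even rounds (rounds are 1-based throughout).
#'
#' @param treatment `"homogeneous"`, `"heterogeneous"`, or `"custom"`. The
#'   presets fill `r_schedule`; `"custom"` requires an explicit schedule.
#' @param group_size Number of players per group \eqn{n} (default 4).
#' @param endowment Tokens received at the start of each round \eqn{w}
#'   (default 20).
#' @param n_rounds Number of rounds played (default 30).
#' @param r_schedule Numeric vector of length `n_rounds` with the multiplier
#'   of each round; every entry must exceed 1. Ignored for the presets.
#' @param conversion_rate Optional token-to-currency rate, stored only.
#'
#' @return An object of class `"game_config"`.
#' @examples
#' cfg <- game_config("heterogeneous")
#' cfg$r_schedule[1:4]  # 2 6 2 6
#' @export
game_config <- function(treatment = c("homogeneous", "heterogeneous", "custom"),
                        group_size = 4L, endowment = 20L, n_rounds = 30L,
                        r_schedule = NULL, conversion_rate = NULL) {
  treatment <- match.arg(treatment)
  group_size <- as.integer(group_size)
  endowment <- as.integer(endowment)
  n_rounds <- as.integer(n_rounds)
  if (group_size < 2L) stop("`group_size` must be at least 2", call. = FALSE)
  if (endowment < 1L) stop("`endowment` must be at least 1", call. = FALSE)
  if (n_rounds < 1L) stop("`n_rounds` must be at least 1", call. = FALSE)

  if (treatment == "homogeneous") {
    r_schedule <- rep(2, n_rounds)
  } else if (treatment == "heterogeneous") {
    r_schedule <- ifelse(seq_len(n_rounds) %% 2L == 1L, 2, 6)
  } else {
    if (is.null(r_schedule)) {
      stop("`r_schedule` is required for a custom treatment", call. = FALSE)
    }
  }
  r_schedule <- as.numeric(r_schedule)
  if (length(r_schedule) != n_rounds) {
    stop("`r_schedule` must have one multiplier per round", call. = FALSE)
  }
  if (any(!is.finite(r_schedule)) || any(r_schedule <= 1)) {
    stop("every multiplier must be a finite number > 1", call. = FALSE)
  }

  structure(
    list(treatment = treatment, group_size = group_size,
         endowment = endowment, n_rounds = n_rounds,
         r_schedule = r_schedule, conversion_rate = conversion_rate),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat("Public goods game configuration\n")
  cat(sprintf("  treatment : %s\n", x$treatment))
  cat(sprintf("  groups of %d, endowment %d tokens, %d rounds\n",
              x$group_size, x$endowment, x$n_rounds))
  cat(sprintf("  multipliers: %s\n",
              paste(unique(x$r_schedule), collapse = ", ")))
  invisible(x)
}

#' Payoffs of one public goods group in one round
#'
#' Each player keeps the uncontributed part of the endowment and receives an
#' equal share of the multiplied pool:
#' \deqn{g_i = w - c_i + r G / n, \qquad G = \sum_k c_k.}
#' Payoffs are kept as doubles; \eqn{r G / n} need not be an integer (for
#' example \eqn{r = 2}, \eqn{G = 1} yields a share of 0.5) and is not rounded.
#'
#' @param contributions Integer vector of length `config$group_size`, each
#'   entry in `[0, endowment]`.
#' @param r Synergy multiplier applied this round.
#' @param config A [game_config()].
#'
#' @return An object of class `"group_outcome"`: a list with
#'   `contributions`, `total_contribution` (\eqn{G}), `payoffs`, and `r`.
#'   The payoffs always satisfy the conservation identity
#'   \eqn{\sum_i g_i = n w + (r - 1) G}.
#' @examples
#' cfg <- game_config("homogeneous")
#' compute_payoffs(c(20, 0, 0, 0), r = 2, config = cfg)$payoffs  # 10 30 30 30
#' @export
compute_payoffs <- function(contributions, r, config = game_config()) {
  n <- config$group_size
  w <- config$endowment
  if (length(contributions) != n) {
    stop(sprintf("expected %d contributions, got %d", n, length(contributions)),
         call. = FALSE)
  }
  if (any(contributions != round(contributions))) {
    stop("contributions must be whole token amounts", call. = FALSE)
  }
  if (any(contributions < 0) || any(contributions > w)) {
    stop(sprintf("contributions must lie in [0, %d]", w), call. = FALSE)
  }
  if (!is.finite(r) || r <= 1) stop("`r` must be a finite number > 1", call. = FALSE)
  G <- sum(contributions)
  payoffs <- w - contributions + r * G / n
  structure(
    list(contributions = as.integer(contributions),
         total_contribution = as.integer(G),
         payoffs = payoffs, r = r),
    class = "group_outcome"
  )
}

#' Nash-equilibrium contribution for a given multiplier
#'
#' When \eqn{r < n} each contributed token returns less than a token to its
#' contributor, so the payoff-maximizing action is to contribute nothing;
#' when \eqn{r > n} every token returns more than a token, so full contribution
#' is dominant. At \eqn{r = n} every contribution level is payoff-equivalent
#' and no equilibrium action is defined.
#'
#' @param r Synergy multiplier.
#' @param config A [game_config()].
#' @return The equilibrium contribution in tokens (0 or the endowment).
#' @export
nash_action <- function(r, config = game_config()) {
  n <- config$group_size
  if (r == n) {
    stop("r equals the group size: every contribution level is payoff-equivalent",
         call. = FALSE)
  }
  if (r < n) 0L else config$endowment
}

#' Nash-equilibrium contribution level for a given multiplier
#'
#' Maps [nash_action()] through the level discretization: level 1 (zero
#' contribution) when \eqn{r < n}, level 5 (full contribution) when \eqn{r > n}.
#'
#' @inheritParams nash_action
#' @return Integer level index, 1 or 5.
#' @export
nash_level <- function(r, config = game_config()) {
  discretize_contribution(nash_action(r, config), endowment = config$endowment)
}
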