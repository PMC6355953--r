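#' Contribution levels
#'
#' Token contributions in `[0, 20]` are discretized into five behavioural
#' levels: L1 = \{0\}, L2 = \[1, 5\], L3 = \[6, 14\], L4 = \[15, 19\],
#' L5 = \{20\}. The extreme levels are the Nash-equilibrium actions of the
#' two game regimes: L1 for \eqn{r < n} and L5 for \eqn{r > n}.
#'
#' @format `level_labels` is the character vector `c("L1", ..., "L5")`.
#' @name levels
NULL

#' @rdname levels
#' @export
level_labels <- c("L1", "L2", "L3", "L4", "L5")

# lower bounds of L1..L5 for endowment 20; upper bound of level k is
# lower[k + 1] - 1
.level_lower <- c(0L, 1L, 6L, 15L, 20L)

#' Discretize token contributions into levels
#'
#' @param c Integer vector of contributions.
#' @param endowment Maximum contribution; the level boundaries are defined
#'   for the standard endowment of 20 tokens.
#' @return Integer vector of level indices in 1..5.
#' @examples
#' discretize_contribution(c(0, 5, 6, 15, 20))  # 1 2 3 4 5
#' @export
discretize_contribution <- function(c, endowment = 20L) {
  if (endowment != 20L) {
    stop("level boundaries are defined for an endowment of 20 tokens",
         call. = FALSE)
  }
  if (any(!is.finite(c)) || any(c != round(c)) || any(c < 0) || any(c > endowment)) {
    stop("contributions must be integers in [0, 20]", call. = FALSE)
  }
  findInterval(c, .level_lower)
}

#' Token range of a contribution level
#'
#' @param level Integer level index in 1..5.
#' @return Integer vector of the tokens belonging to that level.
#' @export
level_tokens <- function(level) {
  stopifnot(length(level) == 1L, level %in% 1:5)
  upper <- c(0L, 5L, 14L, 19L, 20L)
  .level_lower[level]:upper[level]
}
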