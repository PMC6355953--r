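.as_level_set <- function(x, K = 5L) {
  if (is.character(x)) x <- match(x, level_labels)
  x <- unique(as.integer(x))
  if (length(x) == 0L || any(is.na(x)) || any(x < 1L | x > K)) {
    stop("state sets must be non-empty subsets of the state space", call. = FALSE)
  }
  sort(x)
}

.check_occupancy <- function(p, tol = 1e-9) {
  if (length(p) < 2L || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop("`initial` must be a probability vector summing to 1",
         call. = FALSE)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Iterate the occupancy distribution through per-round matrices
#'
#' Starting from `initial`, applies `dist <- dist %*% P_t` for each matrix
#' in order. Each output row is renormalized to machine precision so
#' rounding never accumulates.
#'
#' @param initial Length-5 probability vector (e.g. the round-1 empirical
#'   level shares).
#' @param matrices List of square row-stochastic matrices ordered by round.
#' @return A matrix with `length(matrices) + 1` rows (round-indexed
#'   occupancy distributions), class `"occupancy_trajectory"`.
#' @export
iterate_occupancy <- function(initial, matrices) {
  dist <- .check_occupancy(initial)
  K <- length(dist)
  out <- matrix(NA_real_, nrow = length(matrices) + 1L, ncol = K,
                dimnames = list(NULL, if (K == 5L) level_labels else NULL))
  out[1L, ] <- dist
  for (t in seq_along(matrices)) {
    P <- as.matrix(matrices[[t]])
    if (!all(dim(P) == c(K, K))) {
      stop("every transition matrix must match the state-space dimension",
           call. = FALSE)
    }
    dist <- as.numeric(dist %*% P)
    dist <- dist / sum(dist)
    out[t + 1L, ] <- dist
  }
  structure(out, class = c("occupancy_trajectory", "matrix", "array"))
}

# communicating classes of the support graph; reach = boolean transitive
# closure of the one-step support
.communicating_classes <- function(P, tol = 1e-12) {
  A <- (as.matrix(P) > tol) | diag(TRUE, nrow(P))
  reach <- A
  for (k in seq_len(nrow(P))) {
    reach <- reach | (reach %*% reach > 0)
  }
  mutual <- reach & t(reach)
  classes <- unique(apply(mutual, 1L, function(row) which(row), simplify = FALSE))
  closed <- vapply(classes, function(cl) {
    !any(reach[cl, setdiff(seq_len(nrow(P)), cl), drop = FALSE])
  }, logical(1))
  list(classes = classes, closed = closed)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi P = pi`, `sum(pi) = 1` via the leading left eigenvector.
#' The chain must be irreducible (its support graph strongly connected)
#' and aperiodic; otherwise the error names the closed communicating
#' classes.
#'
#' @param P A 5x5 (or KxK) row-stochastic matrix.
#' @return A probability vector `pi` with `pi %*% P = pi`.
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE))
#' # 5/6, 1/6
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  K <- nrow(P)
  if (ncol(P) != K || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("`P` must be a square row-stochastic matrix", call. = FALSE)
  }
  cc <- .communicating_classes(P)
  if (length(cc$classes) > 1L) {
    desc <- vapply(cc$classes[cc$closed], function(cl) {
      paste0("{", paste(if (K == 5L) level_labels[cl] else cl, collapse = ","), "}")
    }, character(1))
    stop("chain is reducible; closed classes: ", paste(desc, collapse = " "),
         call. = FALSE)
  }
  ev <- eigen(t(P))
  mods <- Mod(ev$values)
  lead <- which.max(mods)
  if (sum(mods > 1 - 1e-8) > 1L) {
    stop("chain is periodic (multiple eigenvalues on the unit circle)",
         call. = FALSE)
  }
  pi <- Re(ev$vectors[, lead])
  pi <- pi / sum(pi)
  if (any(pi < -1e-10)) stop("failed to extract a non-negative stationary vector",
                             call. = FALSE)
  pi <- pmax(pi, 0) / sum(pmax(pi, 0))
  names(pi) <- rownames(P)
  pi
}

#' Probability flux from one state set into another
#'
#' \deqn{F(A \to B) = \sum_{i \in A} \sum_{j \in B} d(i) P(i, j).}
#' With `dist` the stationary distribution this is the long-run fraction
#' of steps that move from A into B; with `dist` an occupancy distribution
#' at round t it is that round's expected flow.
#'
#' @param dist Probability vector over the state space.
#' @param P 5x5 row-stochastic matrix.
#' @param A,B Non-empty source and target state sets (indices 1..5 or
#'   labels `"L1"`..`"L5"`).
#' @return A number in `[0, 1]`.
#' @export
flux <- function(dist, P, A, B) {
  dist <- .check_occupancy(dist)
  K <- length(dist)
  A <- .as_level_set(A, K)
  B <- .as_level_set(B, K)
  P <- as.matrix(P)
  sum(outer(dist[A], rep(1, length(B))) * P[A, B, drop = FALSE])
}

#' Per-round probability flux toward the Nash state
#'
#' Iterates the occupancy distribution through the model's predicted
#' per-round matrices, starting from `initial` (typically the round-1
#' empirical level shares), and reports the flux from `source` into the
#' Nash state of the analysed multiplier: level 1 (zero contribution) when
#' \eqn{r < n}, level 5 (full contribution) when \eqn{r > n}. The multiplier is
#' taken from the model's fitting window (`r_filter`) or may be given
#' explicitly.
#'
#' @param model A parametric [fit_markov_model()].
#' @param config A [game_config()].
#' @param initial Length-5 probability vector for round 1.
#' @param treatment Treatment dummy or label passed to [predict_matrix()].
#' @param r Multiplier whose Nash state is the target; defaults to the
#'   model's `r_filter` or, failing that, the schedule's first multiplier.
#' @param source Source state set A (default: all five levels, so the flux
#'   at round t is the probability of occupying the Nash state at t + 1).
#' @return An object of class `"flux_result"`: a `data.frame` with columns
#'   `round` and `flux` plus attributes `source`, `target`, `mode`.
#' @export
flux_to_nash <- function(model, config = game_config(), initial,
                         treatment = 0, r = NULL, source = 1:5) {
  stopifnot(inherits(model, "markov_fit"))
  if (is.null(r)) r <- model$window$r_filter
  if (is.null(r)) r <- config$r_schedule[1L]
  target <- nash_level(r, config)
  source <- .as_level_set(source)
  n_steps <- model$n_rounds - 1L
  mats <- lapply(seq_len(n_steps), predict_matrix, model = model,
                 treatment = treatment)
  occ <- iterate_occupancy(initial, mats)
  fl <- vapply(seq_len(n_steps), function(t) {
    flux(occ[t, ], mats[[t]], source, target)
  }, numeric(1))
  structure(data.frame(round = seq_len(n_steps), flux = fl),
            source = level_labels[source], target = level_labels[target],
            mode = "occupancy", class = c("flux_result", "data.frame"))
}
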