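#' Per-player level sequences
#'
#' Discretizes a panel's contributions into levels and returns one
#' observation per retained (player, round), robots excluded. With
#' `r_filter = 2` on the alternating treatment this retains the odd rounds
#' only, so consecutive observations there are two experimental rounds
#' apart; transitions are always taken between consecutive *observed*
#' rounds (see [transition_pairs()]).
#'
#' @inheritParams mean_contribution_by_round
#' @return A `data.frame` with columns `player_id`, `treatment`, `round`,
#'   `level`, ordered by player and round.
#' @export
level_sequences <- function(panel, r_filter = NULL) {
  panel <- .filter_panel(panel, r_filter)
  if (nrow(panel) == 0L) stop("no observations left after filtering", call. = FALSE)
  out <- data.frame(player_id = panel$player_id,
                    treatment = panel$treatment,
                    round = panel$round,
                    level = discretize_contribution(panel$contribution),
                    stringsAsFactors = FALSE)
  out <- out[order(out$player_id, out$round), ]
  rownames(out) <- NULL
  out
}

#' Transitions between consecutive observed rounds
#'
#' @param sequences Output of [level_sequences()].
#' @return A `data.frame` with one row per transition: `player_id`,
#'   `treatment`, `round` (the origin round), `gap` (rounds between the two
#'   observations), `origin`, `dest`.
#' @export
transition_pairs <- function(sequences) {
  stopifnot(all(c("player_id", "round", "level") %in% names(sequences)))
  by_player <- split(sequences, sequences$player_id)
  rows <- lapply(by_player, function(s) {
    s <- s[order(s$round), ]
    m <- nrow(s)
    if (m < 2L) return(NULL)
    data.frame(player_id = s$player_id[-m], treatment = s$treatment[-m],
               round = s$round[-m], gap = diff(s$round),
               origin = s$level[-m], dest = s$level[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no player has two or more observed rounds", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

.term_set <- c("intercept", "round", "treatment", "round:treatment")

.covariate_spec <- function(terms) {
  terms <- union("intercept", terms)
  bad <- setdiff(terms, .term_set)
  if (length(bad)) {
    stop("unknown covariate terms: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("round:treatment" %in% terms &&
      !all(c("round", "treatment") %in% terms)) {
    stop("`round:treatment` requires both main effects", call. = FALSE)
  }
  .term_set[.term_set %in% terms]   # canonical order
}

.treatment_dummy <- function(labels) {
  u <- sort(unique(labels))
  if (length(u) > 2L) {
    stop("the treatment dummy requires at most two treatment labels", call. = FALSE)
  }
  ref <- if ("heterogeneous" %in% u && length(u) == 2L) {
    setdiff(u, "heterogeneous")
  } else {
    u[1L]
  }
  list(dummy = as.integer(labels != ref), reference = ref,
       coded_one = setdiff(u, ref))
}

.design_matrix <- function(terms, round, treatment01, round_center) {
  cols <- list(intercept = rep(1, length(round)),
               round = round - round_center,
               treatment = treatment01,
               "round:treatment" = (round - round_center) * treatment01)
  Z <- do.call(cbind, cols[terms])
  colnames(Z) <- terms
  Z
}

# negative log-likelihood and gradient for one origin state, on aggregated
# counts: Z is u x p unique covariate patterns, C is u x 5 destination counts
.origin_negll <- function(beta, Z, C) {
  B <- matrix(beta, nrow = 4L)               # dest 2..5 by term
  eta <- cbind(0, Z %*% t(B))                # u x 5
  m <- apply(eta, 1L, max)
  lse <- m + log(rowSums(exp(eta - m)))
  -(sum(C * eta) - sum(rowSums(C) * lse))
}

.origin_grad <- function(beta, Z, C) {
  B <- matrix(beta, nrow = 4L)
  eta <- cbind(0, Z %*% t(B))
  m <- apply(eta, 1L, max)
  P <- exp(eta - (m + log(rowSums(exp(eta - m)))))
  tot <- rowSums(C)
  G <- matrix(0, nrow = 4L, ncol = ncol(Z))
  for (j in 2:5) {
    G[j - 1L, ] <- crossprod(Z, C[, j] - tot * P[, j])
  }
  -as.numeric(G)
}

#' Fit a multi-state Markov model of level transitions
#'
#' Models each player's movement between the five contribution levels as a
#' (possibly non-homogeneous) Markov chain observed at the retained rounds.
#' Two estimation modes are provided:
#'
#' * `"parametric"` — a multinomial-logistic link per origin state: with
#'   covariate vector `z` (intercept, centered round, treatment dummy,
#'   their interaction, per `terms`), the transition probability is
#'   `P(dest = j | origin = i, z) = exp(z'b_ij) / sum_k exp(z'b_ik)` with
#'   `b_i1 = 0`. Coefficients are estimated by maximum likelihood over all
#'   players' consecutive observation pairs (BFGS with analytic gradient,
#'   deterministic zero initialization, per-origin separable fits). This
#'   yields a smooth predicted matrix for every round 1..`n_rounds`,
#'   including rounds the filtered data never observe directly.
#' * `"saturated"` — empirical per-origin-round transition frequencies with
#'   an additive pseudo-count (`smoothing`, default 0.5 per cell) to avoid
#'   zero rows; one matrix per observed origin round, no pooling across
#'   rounds or treatments.
#'
#' The discrete-round formulation is the estimation core; a continuous-time
#' rate-matrix view of any predicted matrix is available through
#' [transition_to_rate()].
#'
#' @param x A panel `data.frame` or the output of [transition_pairs()].
#' @param r_filter Optional multiplier filter applied when `x` is a panel.
#' @param terms Character vector of covariate terms from `"intercept"`,
#'   `"round"`, `"treatment"`, `"round:treatment"`; the intercept is always
#'   included. The round covariate is centered at `round_center`
#'   (mid-experiment by default); the treatment dummy codes the
#'   heterogeneous treatment as 1.
#' @param mode `"parametric"` or `"saturated"`.
#' @param smoothing Pseudo-count per cell for the saturated mode.
#' @param n_rounds Number of rounds predictions may be requested for.
#' @param round_center Centering constant for the round covariate.
#' @param grad_tol Gradient max-norm declaring convergence (default 1e-6).
#' @return An object of class `"markov_fit"` with elements `mode`, `terms`,
#'   `coef` (origin x destination x term array, parametric mode), `logLik`,
#'   `npar`, `n_pairs`, `convergence`, `window` (a description of the
#'   observations used), and `matrices` (saturated mode).
#' @seealso [predict_matrix()], [lrt()], [flux_to_nash()]
#' @export
fit_markov_model <- function(x, r_filter = NULL,
                             terms = "intercept",
                             mode = c("parametric", "saturated"),
                             smoothing = 0.5, n_rounds = 30L,
                             round_center = (n_rounds + 1) / 2,
                             grad_tol = 1e-6) {
  mode <- match.arg(mode)
  pairs <- if (all(c("origin", "dest") %in% names(x))) {
    x
  } else {
    transition_pairs(level_sequences(x, r_filter))
  }
  terms <- .covariate_spec(terms)
  tr <- .treatment_dummy(pairs$treatment)
  window <- list(
    r_filter = r_filter,
    treatments = sort(unique(pairs$treatment)),
    treatment_coded_one = tr$coded_one,
    rounds = range(pairs$round),
    n_players = length(unique(pairs$player_id)),
    n_pairs = nrow(pairs))

  if (mode == "saturated") {
    return(.fit_saturated(pairs, smoothing, n_rounds, window))
  }

  p <- length(terms)
  coef_arr <- array(0, dim = c(5L, 4L, p),
                    dimnames = list(origin = level_labels,
                                    dest = level_labels[-1L],
                                    term = terms))
  ll <- 0
  worst_grad <- 0
  iterations <- 0L
  for (i in 1:5) {
    sel <- pairs$origin == i
    if (!any(sel)) next
    sub <- pairs[sel, , drop = FALSE]
    key <- paste(sub$round, tr$dummy[sel])
    uk <- !duplicated(key)
    Z <- .design_matrix(terms, sub$round[uk], tr$dummy[sel][uk], round_center)
    C <- matrix(0, nrow = sum(uk), ncol = 5L)
    idx <- match(key, key[uk])
    for (r in seq_len(nrow(sub))) C[idx[r], sub$dest[r]] <- C[idx[r], sub$dest[r]] + 1
    beta <- numeric(4L * p)
    prev_val <- Inf
    for (attempt in 1:5) {
      opt <- stats::optim(beta, .origin_negll, .origin_grad, Z = Z, C = C,
                          method = "BFGS",
                          control = list(maxit = 500L, reltol = 1e-14))
      beta <- opt$par
      iterations <- iterations + opt$counts[1L]
      gmax <- max(abs(.origin_grad(beta, Z, C)))
      plateau <- abs(prev_val - opt$value) < 1e-10 * (1 + abs(opt$value))
      prev_val <- opt$value
      if (gmax < grad_tol || plateau) break
    }
    if (gmax >= grad_tol && gmax >= 1e-3) {
      cond <- structure(
        class = c("pggmarkov_convergence_error", "error", "condition"),
        list(message = sprintf(
               "origin state %s did not converge (gradient max-norm %.3g)",
               level_labels[i], gmax),
             call = sys.call(-1), last_iterate = beta))
      stop(cond)
    }
    worst_grad <- max(worst_grad, gmax)
    coef_arr[i, , ] <- matrix(beta, nrow = 4L)
    ll <- ll - opt$value
  }

  structure(list(
    mode = "parametric", terms = terms, coef = coef_arr,
    logLik = ll, npar = 5L * 4L * p, n_pairs = nrow(pairs),
    convergence = list(grad_norm = worst_grad,
                       converged = worst_grad < max(grad_tol, 1e-3),
                       iterations = as.integer(iterations)),
    window = window, round_center = round_center, n_rounds = as.integer(n_rounds)),
    class = "markov_fit")
}

.fit_saturated <- function(pairs, smoothing, n_rounds, window) {
  rounds <- sort(unique(pairs$round))
  mats <- list()
  ll <- 0
  for (t in rounds) {
    sub <- pairs[pairs$round == t, , drop = FALSE]
    counts <- matrix(0, 5L, 5L, dimnames = list(level_labels, level_labels))
    for (r in seq_len(nrow(sub))) {
      counts[sub$origin[r], sub$dest[r]] <- counts[sub$origin[r], sub$dest[r]] + 1
    }
    sm <- counts + smoothing
    P <- sm / rowSums(sm)          # rows with no data and no smoothing -> NaN
    mats[[as.character(t)]] <- P
    obs <- counts > 0
    ll <- ll + sum(counts[obs] * log(P[obs]))
  }
  npar <- length(rounds) * 5L * 4L
  structure(list(
    mode = "saturated", terms = "by_round", coef = NULL,
    logLik = ll, npar = npar, n_pairs = nrow(pairs),
    convergence = list(grad_norm = 0, converged = TRUE, iterations = 0L),
    window = window, smoothing = smoothing,
    matrices = mats, n_rounds = as.integer(n_rounds)),
    class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("Multi-state Markov fit (%s mode)\n", x$mode))
  cat(sprintf("  terms      : %s\n", paste(x$terms, collapse = ", ")))
  cat(sprintf("  transitions: %d from %d players, rounds %d-%d\n",
              x$n_pairs, x$window$n_players, x$window$rounds[1],
              x$window$rounds[2]))
  cat(sprintf("  logLik %.3f on %d parameters\n", x$logLik, x$npar))
  invisible(x)
}

#' @export
logLik.markov_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_pairs,
            class = "logLik")
}

#' Predicted one-step transition matrix at a given round
#'
#' For a parametric fit, evaluates the multinomial-logistic link at the
#' round's covariates, so a matrix exists for every round in
#' 1..`n_rounds` — including rounds the filtered data never observe at the
#' analysed multiplier, which is how the model extrapolates for a
#' consistent cross-treatment comparison. For a saturated fit, returns the
#' stored empirical matrix for that origin round; a round with no observed
#' transitions yields a uniform matrix with a warning, as does an origin
#' level never observed when `smoothing = 0`.
#'
#' @param model A [fit_markov_model()] object.
#' @param round Round index in 1..`model$n_rounds`.
#' @param treatment Value of the treatment dummy (0/1) or a treatment
#'   label, for fits that include the treatment term.
#' @return A 5x5 row-stochastic matrix with dimnames `L1..L5`.
#' @export
predict_matrix <- function(model, round, treatment = 0) {
  stopifnot(inherits(model, "markov_fit"))
  if (length(round) != 1L || round < 1L || round > model$n_rounds) {
    stop(sprintf("`round` must lie in 1..%d", model$n_rounds), call. = FALSE)
  }
  if (is.character(treatment)) {
    treatment <- as.integer(treatment %in% model$window$treatment_coded_one)
  }
  if (model$mode == "saturated") {
    P <- model$matrices[[as.character(round)]]
    if (is.null(P)) {
      warning(sprintf("no transitions observed at round %d; returning a uniform matrix", round),
              call. = FALSE)
      P <- matrix(0.2, 5, 5, dimnames = list(level_labels, level_labels))
      return(P)
    }
    bad <- !is.finite(P[, 1])
    if (any(bad)) {
      warning(sprintf("origin level(s) %s unobserved at round %d; substituting uniform rows",
                      paste(level_labels[bad], collapse = ", "), round),
              call. = FALSE)
      P[bad, ] <- 0.2
    }
    return(P)
  }
  Z <- .design_matrix(model$terms, round, treatment, model$round_center)
  P <- matrix(0, 5, 5, dimnames = list(level_labels, level_labels))
  for (i in 1:5) {
    eta <- c(0, as.numeric(Z %*% t(matrix(model$coef[i, , ], nrow = 4L))))
    e <- exp(eta - max(eta))
    P[i, ] <- e / sum(e)
  }
  P
}

#' Likelihood-ratio test of nested covariate specifications
#'
#' Compares two parametric fits estimated on the same transitions, the
#' null's terms being a subset of the alternative's. The statistic
#' `2 * (logLik_alt - logLik_null)` is referred to a chi-square with
#' degrees of freedom equal to the parameter-count difference.
#'
#' @param null_model,alt_model Nested [fit_markov_model()] objects
#'   (parametric mode).
#' @return A list of class `"pgg_lrt"` with `statistic`, `df`, `p_value`,
#'   and the two log-likelihoods.
#' @export
lrt <- function(null_model, alt_model) {
  stopifnot(inherits(null_model, "markov_fit"), inherits(alt_model, "markov_fit"))
  if (null_model$mode != "parametric" || alt_model$mode != "parametric") {
    stop("the likelihood-ratio test requires parametric fits", call. = FALSE)
  }
  if (!all(null_model$terms %in% alt_model$terms)) {
    stop("the null model's terms must be a subset of the alternative's", call. = FALSE)
  }
  if (null_model$n_pairs != alt_model$n_pairs) {
    stop("both models must be fitted on the same transitions", call. = FALSE)
  }
  stat <- 2 * (alt_model$logLik - null_model$logLik)
  if (stat < -1e-6) {
    stop(sprintf("negative likelihood-ratio statistic (%.3g): check convergence", stat),
         call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- alt_model$npar - null_model$npar
  if (df < 0L) stop("the alternative must have at least as many parameters as the null", call. = FALSE)
  if (df == 0L && stat > 1e-6) {
    stop("models with equal parameter counts but different likelihoods are not nested", call. = FALSE)
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df,
                 p_value = p,
                 logLik_null = null_model$logLik,
                 logLik_alt = alt_model$logLik),
            class = "pgg_lrt")
}

#' @export
print.pgg_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of nested transition models\n")
  cat(sprintf("  chi-square = %.3f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Continuous-time view of a transition matrix
#'
#' `transition_to_rate()` returns the matrix logarithm of a one-step
#' transition matrix — the generator whose unit-time exponential recovers
#' the matrix; rows sum to zero. Not every stochastic matrix embeds in a
#' continuous-time chain, in which case some off-diagonal rates come out
#' negative and a warning is issued. `rate_to_transition()` exponentiates a
#' generator over `dt` time units.
#'
#' @param P A row-stochastic matrix.
#' @param L A rate matrix (rows summing to zero).
#' @param dt Time step.
#' @return A square matrix of the same dimension.
#' @export
transition_to_rate <- function(P) {
  L <- Re(pracma::logm(as.matrix(P)))
  off <- L - diag(diag(L))
  if (any(off < -1e-8)) {
    warning("matrix is not embeddable: negative off-diagonal rates", call. = FALSE)
  }
  dimnames(L) <- dimnames(P)
  L
}

#' @rdname transition_to_rate
#' @export
rate_to_transition <- function(L, dt = 1) {
  P <- as.matrix(Matrix::expm(Matrix::Matrix(as.matrix(L) * dt)))
  dimnames(P) <- dimnames(L)
  P
}
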