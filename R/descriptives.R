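.filter_panel <- function(panel, r_filter = NULL, drop_robots = TRUE) {
  need <- c("player_id", "round", "r", "contribution", "is_robot")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (drop_robots) panel <- panel[!panel$is_robot, , drop = FALSE]
  if (!is.null(r_filter)) panel <- panel[panel$r == r_filter, , drop = FALSE]
  panel
}

#' Average contribution per round with a confidence interval
#'
#' Averages the human players' contributions within each retained round.
#' The default interval is the t interval
#' `mean +/- t(0.975, m - 1) * sd / sqrt(m)` over the `m` players observed
#' in the round; `method = "bootstrap"` replaces it with a percentile
#' bootstrap over players.
#'
#' @param panel A long-format panel (see [simulate_session()]).
#' @param r_filter Optional multiplier; keeps only rounds played at that
#'   `r` (e.g. `r_filter = 2` in the alternating treatment keeps the odd
#'   rounds).
#' @param conf_level Confidence level (default 0.95).
#' @param method `"t"` or `"bootstrap"`.
#' @param reps,seed Bootstrap replicates and seed (bootstrap method only).
#' @return A `data.frame` with columns `round`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`; zero rows (with a warning) if the filter removes everything.
#' @export
mean_contribution_by_round <- function(panel, r_filter = NULL,
                                       conf_level = 0.95,
                                       method = c("t", "bootstrap"),
                                       reps = 1000L, seed = NULL) {
  method <- match.arg(method)
  panel <- .filter_panel(panel, r_filter)
  if (nrow(panel) == 0L) {
    warning("no observations left after filtering", call. = FALSE)
    return(data.frame(round = integer(0), n = integer(0), mean = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  }
  if (!is.null(seed)) set.seed(seed)
  alpha <- 1 - conf_level
  rounds <- sort(unique(panel$round))
  out <- lapply(rounds, function(t) {
    x <- panel$contribution[panel$round == t]
    m <- length(x)
    mu <- mean(x)
    if (method == "t") {
      half <- if (m > 1L) stats::qt(1 - alpha / 2, m - 1L) * stats::sd(x) / sqrt(m)
              else NA_real_
      lo <- mu - half; hi <- mu + half
    } else {
      boot <- vapply(seq_len(reps),
                     function(b) mean(x[sample.int(m, m, replace = TRUE)]),
                     numeric(1))
      q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo <- q[1]; hi <- q[2]
    }
    data.frame(round = t, n = m, mean = mu, ci_lo = lo, ci_hi = hi)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percentage of players at each contribution level, per round
#'
#' @inheritParams mean_contribution_by_round
#' @return A `data.frame` with columns `round`, `n`, and `share_L1` ..
#'   `share_L5` in percent; the five shares sum to 100 in every round.
#' @export
level_shares_by_round <- function(panel, r_filter = NULL) {
  panel <- .filter_panel(panel, r_filter)
  if (nrow(panel) == 0L) {
    warning("no observations left after filtering", call. = FALSE)
    out <- data.frame(round = integer(0), n = integer(0))
    out[paste0("share_", level_labels)] <- numeric(0)
    return(out)
  }
  lev <- discretize_contribution(panel$contribution)
  rounds <- sort(unique(panel$round))
  out <- lapply(rounds, function(t) {
    sel <- panel$round == t
    counts <- tabulate(lev[sel], nbins = 5L)
    row <- data.frame(round = t, n = sum(sel))
    row[paste0("share_", level_labels)] <- as.list(100 * counts / sum(counts))
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Lagged self-correlation of contributions
#'
#' For each lag `k`, pools the pairs (c_{i,t}, c_{i,t-k}) over all players
#' and valid retained rounds (lags are counted in retained observation
#' steps when `r_filter` is used) and reports the Pearson correlation. The
#' p-value comes from a per-player circular-shift permutation null: each
#' replicate shifts every player's series by an independent random offset
#' and recomputes the pooled coefficient, which respects the dependence
#' within a player's series.
#'
#' @inheritParams mean_contribution_by_round
#' @param max_lag Largest lag, in retained rounds.
#' @param reps Permutation replicates for the p-value.
#' @return A `data.frame` with columns `lag`, `n_pairs`, `estimate`,
#'   `p_value`, `undefined`. A lag whose pooled pairs have zero variance is
#'   flagged `undefined = TRUE` with `NA` estimate rather than returning
#'   NaN.
#' @export
lagged_self_correlation <- function(panel, max_lag = 5L, r_filter = NULL,
                                    reps = 1000L, seed = NULL) {
  panel <- .filter_panel(panel, r_filter)
  if (nrow(panel) == 0L) stop("no observations left after filtering", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  panel <- panel[order(panel$player_id, panel$round), ]
  series <- split(panel$contribution, panel$player_id)
  len <- lengths(series)
  if (max_lag >= max(len)) stop("`max_lag` must be below the series length", call. = FALSE)

  pooled_cor <- function(ser, k) {
    xs <- unlist(lapply(ser, function(s) if (length(s) > k) s[seq_len(length(s) - k)] else numeric(0)))
    ys <- unlist(lapply(ser, function(s) if (length(s) > k) s[-seq_len(k)] else numeric(0)))
    if (length(xs) < 3L) return(list(r = NA_real_, n = length(xs), flat = TRUE))
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(list(r = NA_real_, n = length(xs), flat = TRUE))
    }
    list(r = stats::cor(xs, ys), n = length(xs), flat = FALSE)
  }

  obs <- lapply(seq_len(max_lag), function(k) pooled_cor(series, k))
  null_mat <- matrix(NA_real_, nrow = reps, ncol = max_lag)
  for (b in seq_len(reps)) {
    shifted <- lapply(series, function(s) {
      off <- sample.int(length(s) - 1L, 1L)
      c(s[-seq_len(off)], s[seq_len(off)])
    })
    for (k in seq_len(max_lag)) {
      if (!obs[[k]]$flat) null_mat[b, k] <- pooled_cor(shifted, k)$r
    }
  }
  out <- data.frame(
    lag = seq_len(max_lag),
    n_pairs = vapply(obs, function(o) o$n, numeric(1)),
    estimate = vapply(obs, function(o) o$r, numeric(1)),
    p_value = vapply(seq_len(max_lag), function(k) {
      if (obs[[k]]$flat) return(NA_real_)
      null_k <- null_mat[, k]
      null_k <- null_k[is.finite(null_k)]
      (1 + sum(abs(null_k) >= abs(obs[[k]]$r))) / (1 + length(null_k))
    }, numeric(1)),
    undefined = vapply(obs, function(o) o$flat, logical(1))
  )
  out
}
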