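test_that("a player locked in L1 gives a saturated estimate of P(L1,L1) = 1", {
  panel <- data.frame(session_id = "S", player_id = "p1", round = 1:10,
                      group_id = 1L, treatment = "homogeneous", r = 2,
                      contribution = 0L, payoff = 20, is_robot = FALSE)
  fit <- fit_markov_model(panel, mode = "saturated", smoothing = 0,
                          n_rounds = 10)
  for (t in 1:9) {
    suppressWarnings(P <- predict_matrix(fit, t))
    expect_equal(P["L1", "L1"], 1)
  }
})

test_that("parametric and saturated fits both recover a time-constant generator", {
  M <- reference_matrix("homogeneous")
  panel <- sim_markov_panel(500, M, seed = 1001)
  fit <- fit_markov_model(panel, terms = "intercept")
  expect_lt(max(abs(predict_matrix(fit, 10) - M)), 0.05)
  sat <- fit_markov_model(panel, mode = "saturated")
  avg <- Reduce(`+`, sat$matrices) / length(sat$matrices)
  expect_lt(max(abs(avg - M)), 0.05)
  # the two modes agree with each other as well
  expect_lt(max(abs(avg - predict_matrix(fit, 10))), 0.05)
})

test_that("the odd-round observation window recovers an odd-to-odd generator", {
  # in the alternating treatment the r = 2 chain is observed every other
  # round, so consecutive observed pairs are two rounds apart
  M2 <- reference_matrix("heterogeneous_r2")
  panel <- sim_markov_panel(500, M2, seed = 11, treatment = "heterogeneous")
  fit <- fit_markov_model(panel, r_filter = 2, terms = "intercept")
  expect_lt(max(abs(predict_matrix(fit, 10) - M2)), 0.05)
  expect_equal(sort(unique(transition_pairs(
    level_sequences(panel, r_filter = 2))$gap)), 2L)
})

test_that("the intercept-only MLE equals pooled empirical frequencies", {
  panel <- sim_markov_panel(60, persistent_matrix(0.6), seed = 3, n_rounds = 12)
  pairs <- transition_pairs(level_sequences(panel))
  fit <- fit_markov_model(pairs, terms = "intercept", n_rounds = 12)
  emp <- matrix(0, 5, 5)
  for (i in seq_len(nrow(pairs))) {
    emp[pairs$origin[i], pairs$dest[i]] <- emp[pairs$origin[i], pairs$dest[i]] + 1
  }
  emp <- emp / rowSums(emp)
  P <- predict_matrix(fit, 6)
  seen <- rowSums(is.finite(emp)) == 5
  expect_lt(max(abs(P[seen, ] - emp[seen, ])), 1e-5)
})

test_that("the likelihood is exchangeable in the order of transitions", {
  panel <- sim_markov_panel(30, persistent_matrix(0.7), seed = 4, n_rounds = 10)
  pairs <- transition_pairs(level_sequences(panel))
  fit1 <- fit_markov_model(pairs, terms = c("round"), n_rounds = 10)
  set.seed(1)
  fit2 <- fit_markov_model(pairs[sample.int(nrow(pairs)), ],
                           terms = c("round"), n_rounds = 10)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-8)
})

test_that("predicted matrices are row-stochastic and round-constant without a round term", {
  panel <- sim_markov_panel(50, persistent_matrix(0.6), seed = 6, n_rounds = 15)
  fit0 <- fit_markov_model(panel, terms = "intercept", n_rounds = 15)
  fitr <- fit_markov_model(panel, terms = "round", n_rounds = 15)
  P1 <- predict_matrix(fit0, 1)
  for (t in c(2, 8, 15)) {
    expect_equal(predict_matrix(fit0, t), P1)
  }
  for (t in c(1, 7, 15)) {
    expect_true(all(abs(rowSums(predict_matrix(fitr, t)) - 1) < 1e-9))
  }
  expect_error(predict_matrix(fit0, 16), "1\\.\\.15")
  expect_error(predict_matrix(fit0, 0), "1\\.\\.15")
})

test_that("adding covariate terms never decreases the maximized log-likelihood", {
  panel <- rbind(
    sim_markov_panel(25, reference_matrix("homogeneous"), seed = 7, n_rounds = 12),
    sim_markov_panel(25, reference_matrix("heterogeneous_r2"), seed = 8,
                     n_rounds = 12, session_id = "S2",
                     init = mid_init)
  )
  panel$treatment[panel$session_id == "S2"] <- "heterogeneous"
  ladder <- list("intercept",
                 "round",
                 c("round", "treatment"),
                 c("round", "treatment", "round:treatment"))
  lls <- vapply(ladder, function(tm) {
    fit_markov_model(panel, terms = tm, n_rounds = 12)$logLik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("the treatment LRT behaves as a chi-square test of nested fits", {
  panel <- rbind(
    sim_markov_panel(20, reference_matrix("homogeneous"), seed = 9, n_rounds = 10),
    {
      p <- sim_markov_panel(20, reference_matrix("heterogeneous_r2"), seed = 10,
                            n_rounds = 10, session_id = "S2")
      p$treatment <- "heterogeneous"
      p
    })
  null <- fit_markov_model(panel, terms = "intercept", n_rounds = 10)
  alt <- fit_markov_model(panel, terms = "treatment", n_rounds = 10)
  res <- lrt(null, alt)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 20L)
  expect_equal(res$p_value,
               pchisq(res$statistic, res$df, lower.tail = FALSE))
  # identical models: statistic 0, p = 1
  same <- lrt(null, fit_markov_model(panel, terms = "intercept", n_rounds = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt(alt, null), "subset")
})

test_that("parametric fits agree with an independent multinomial-logit fit", {
  panel <- sim_markov_panel(80, persistent_matrix(0.5), seed = 11, n_rounds = 12)
  pairs <- transition_pairs(level_sequences(panel))
  fit <- fit_markov_model(pairs, terms = "round", n_rounds = 12)
  P <- predict_matrix(fit, 6)
  for (i in 1:5) {
    sub <- pairs[pairs$origin == i, ]
    sub$dest <- factor(sub$dest, levels = 1:5)
    sub$rc <- sub$round - 6.5
    ref <- nnet::multinom(dest ~ rc, data = sub, trace = FALSE,
                          maxit = 500, reltol = 1e-14)
    pref <- predict(ref, newdata = data.frame(rc = 6 - 6.5), type = "probs")
    expect_equal(as.numeric(P[i, as.integer(colnames(ref$fitted.values))]),
                 as.numeric(pref), tolerance = 1e-4)
  }
})

test_that("a rate-matrix view round-trips through the matrix exponential", {
  M <- reference_matrix("heterogeneous_r2")
  L <- transition_to_rate(M)
  expect_true(all(abs(rowSums(L)) < 1e-8))
  P <- rate_to_transition(L)
  expect_true(all(abs(rowSums(P) - 1) < 1e-8))
  expect_lt(max(abs(P - M)), 1e-8)
  # a genuine generator always exponentiates to a stochastic matrix
  set.seed(2)
  for (k in 1:5) {
    A <- matrix(runif(25, 0, 0.3), 5, 5)
    diag(A) <- 0
    diag(A) <- -rowSums(A)
    Pk <- rate_to_transition(A)
    expect_true(all(Pk > -1e-10))
    expect_true(all(abs(rowSums(Pk) - 1) < 1e-8))
  }
})

test_that("saturated predictions warn and fall back to uniform rows off-window", {
  panel <- sim_markov_panel(10, persistent_matrix(0.8), seed = 12, n_rounds = 10,
                            treatment = "heterogeneous")
  sat <- fit_markov_model(panel, r_filter = 2, mode = "saturated", n_rounds = 10)
  expect_warning(P <- predict_matrix(sat, 2), "no transitions observed")
  expect_true(all(P == 0.2))
  P3 <- predict_matrix(sat, 3)
  expect_true(all(abs(rowSums(P3) - 1) < 1e-9))
})

test_that("models serialize to JSON and back without loss", {
  panel <- sim_markov_panel(20, persistent_matrix(0.6), seed = 13, n_rounds = 8)
  fit <- fit_markov_model(panel, terms = "round", n_rounds = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$logLik, fit$logLik)
  expect_equal(predict_matrix(back, 4), predict_matrix(fit, 4), tolerance = 1e-12)
})
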