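toy_block <- function(choices, shown, m_O1, m_O2, condition = "direct",
                      run = 1L) {
  n <- length(choices)
  causal <- if (condition == "direct") seq_len(n)
  else c(NA_integer_, seq_len(n)[-n])
  data.frame(trial = seq_len(n), run = run, condition = condition,
             trial_in_block = seq_len(n), m_O1 = m_O1, m_O2 = m_O2,
             choice = choices, outcome_shown = shown,
             causal_choice_trial = causal, stringsAsFactors = FALSE)
}

test_that("lag design matches hand-coded cells on a toy block", {
  tb <- toy_block(choices = c("S1", "S2", "S1", "S1", "S2"),
                  shown = c("O1", "O2", "O2", "O1", "O1"),
                  m_O1 = c(50L, 50L, 50L, 80L, 20L),
                  m_O2 = c(30L, 30L, 30L, 30L, 90L))
  d <- build_lag_design(tb, "direct")
  expect_equal(nrow(d), 2)
  r4 <- d[d$trial == 4, ]
  expect_equal(r4$response, 1)
  expect_equal(unlist(r4[c("C1O1", "C2O1", "C3O1")]),
               c(C1O1 = -1, C2O1 = 1, C3O1 = -1))
  expect_equal(unlist(r4[c("C1O2", "C2O2", "C3O2")]),
               c(C1O2 = -1, C2O2 = 1, C3O2 = -1))
  expect_equal(unlist(r4[c("C1O3", "C2O3", "C3O3")]),
               c(C1O3 = 1, C2O3 = -1, C3O3 = 1))
  r5 <- d[d$trial == 5, ]
  expect_equal(r5$response, 0)
  expect_equal(unlist(r5[paste0("C", 1:3, "O1")]),
               c(C1O1 = -1, C2O1 = -1, C3O1 = 1))
  expect_equal(unlist(r5[paste0("C", 1:3, "O2")]),
               c(C1O2 = 1, C2O2 = 1, C3O2 = -1))
})

test_that("eligibility respects 3-back history and the unlinked feedback", {
  ch <- rep(c("S1", "S2"), 4)
  sh <- rep(c("O1", "O2"), 4)
  m1 <- rep(80L, 8); m2 <- rep(30L, 8)
  expect_equal(nrow(build_lag_design(toy_block(ch, sh, m1, m2, "direct"),
                                     "direct")), 5)
  # indirect: outcome lags must not touch the unlinked first display
  expect_equal(nrow(build_lag_design(toy_block(ch, sh, m1, m2, "indirect"),
                                     "indirect")), 4)
  # 4-trial direct block: exactly one row
  expect_equal(nrow(build_lag_design(toy_block(ch[1:4], sh[1:4], m1[1:4],
                                               m2[1:4], "direct"),
                                     "direct")), 1)
  expect_warning(d0 <- build_lag_design(toy_block(ch[1:3], sh[1:3], m1[1:3],
                                                  m2[1:3], "direct"),
                                        "direct"),
                 "eligible")
  expect_equal(nrow(d0), 0)
})

test_that("cell values equal an independent vectorized recoding", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 20
    ch <- sample(c("S1", "S2"), n, replace = TRUE)
    sh <- sample(c("O1", "O2"), n, replace = TRUE)
    m <- generate_magnitudes(n, seed = rep)
    tb <- toy_block(ch, sh, m$m_O1, m$m_O2)
    d <- build_lag_design(tb, "direct")
    Cc <- ifelse(ch == "S1", 1, -1)
    want <- ifelse(m$m_O1 > m$m_O2, "O1", "O2")
    for (rr in seq_len(nrow(d))) {
      t <- d$trial[rr]
      for (i in 1:3) for (j in 1:3) {
        expected <- Cc[t - i] * (if (sh[t - j] == want[t]) 1 else -1)
        expect_identical(d[rr, sprintf("C%dO%d", i, j)], expected)
      }
    }
    # sign-product symmetry: flipping choice labels and the desired-outcome
    # match together leaves every cell unchanged
    ch2 <- ifelse(ch == "S1", "S2", "S1")
    sh2 <- ifelse(sh == "O1", "O2", "O1")
    d2 <- build_lag_design(toy_block(ch2, sh2, m$m_O1, m$m_O2), "direct")
    expect_equal(as.matrix(d2[, grep("^C", names(d2))]),
                 as.matrix(d[, grep("^C", names(d))]))
  }
})

test_that("ridge logistic fit recovers planted structure and nulls", {
  set.seed(21)
  n <- 600
  X <- matrix(sample(c(-1, 1), n * 9, replace = TRUE), n, 9)
  cols <- as.vector(outer(1:3, 1:3, function(i, j) sprintf("C%dO%d", i, j)))
  colnames(X) <- cols
  # null: response independent of the design
  d0 <- data.frame(trial = 1:n, response = rbinom(n, 1, 0.5), X)
  f0 <- fit_choice_model(d0, ridge = 1)
  expect_lt(max(abs(f0$beta[-1])), 0.3)
  # deterministic responder on the first cell
  d1 <- data.frame(trial = 1:n, response = as.integer(X[, "C1O1"] == 1), X)
  f1 <- fit_choice_model(d1, ridge = 1)
  expect_equal(names(which.max(f1$beta[-1])), "C1O1")
  expect_gt(f1$beta["C1O1"], 1)
  expect_lt(max(abs(f1$beta[setdiff(cols, "C1O1")])), 0.4)
  # replication invariance (exact in the unpenalized limit; a fixed ridge
  # weakens relative to duplicated data, so the penalized fit only moves
  # toward the data)
  f0dup <- fit_choice_model(rbind(d0, d0), ridge = 1e-8)
  f0ref <- fit_choice_model(d0, ridge = 1e-8)
  expect_equal(f0dup$beta, f0ref$beta, tolerance = 1e-5)
  expect_error(fit_choice_model(d1[0, ], 1), "empty")
  expect_error(fit_choice_model(d1, ridge = -1), "ridge")
})

test_that("vanishing ridge converges to the unpenalized glm fit", {
  set.seed(33)
  n <- 800
  X <- matrix(sample(c(-1, 1), n * 9, replace = TRUE), n, 9)
  cols <- as.vector(outer(1:3, 1:3, function(i, j) sprintf("C%dO%d", i, j)))
  colnames(X) <- cols
  eta <- 0.8 * X[, 1] - 0.5 * X[, 5] + 0.2
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(trial = 1:n, response = y, X)
  ours <- fit_choice_model(d, ridge = 1e-8)$beta
  ref <- coef(glm(y ~ X, family = binomial()))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("separation without ridge is flagged and capped", {
  set.seed(3)
  n <- 60
  X <- matrix(sample(c(-1, 1), n * 9, replace = TRUE), n, 9)
  colnames(X) <- as.vector(outer(1:3, 1:3, function(i, j)
    sprintf("C%dO%d", i, j)))
  d <- data.frame(trial = 1:n, response = as.integer(X[, 1] == 1), X)
  expect_warning(f <- fit_choice_model(d, ridge = 0), "separation")
  expect_true(f$separation)
  expect_lte(max(abs(f$beta)), 20)
})

test_that("credit matrix averages runs and keeps the lag orientation", {
  ch <- rep(c("S1", "S1", "S2", "S2", "S1"), 4)
  sh <- rep(c("O1", "O2"), 10)
  m <- generate_magnitudes(20, seed = 2)
  one <- toy_block(ch, sh, m$m_O1, m$m_O2)
  two <- rbind(one, transform(one, run = 2L))
  M1 <- participant_credit_matrix(one, "direct")
  M2 <- participant_credit_matrix(two, "direct")
  expect_equal(unclass(M2)[1:3, 1:3], unclass(M1)[1:3, 1:3],
               tolerance = 1e-10)
  expect_equal(dim(M1), c(3, 3))
  expect_identical(rownames(M1)[1], "choice_lag1")
  d <- build_lag_design(one, "direct")
  f <- fit_choice_model(d, ridge = 1)
  expect_equal(M1[2, 3], unname(f$beta["C2O3"]))
  expect_error(participant_credit_matrix(one, "indirect"), "nonempty")
})

test_that("rule-following cohorts show condition-appropriate structure", {
  dmat <- imat <- list()
  for (s in 1:8) {
    sess <- build_session(quick_session_config(), seed = 700 + s)
    beh <- simulate_rule_agent(sess, lapse = 0.1, seed = 800 + s)
    dmat[[s]] <- participant_credit_matrix(beh, "direct")
    imat[[s]] <- participant_credit_matrix(beh, "indirect")
  }
  Md <- Reduce(`+`, lapply(dmat, unclass)) / 8
  Mi <- Reduce(`+`, lapply(imat, unclass)) / 8
  expect_gt(mean(diag(Md[1:3, 1:3])), mean(Md[1:3, 1:3][row(Md[1:3, 1:3]) !=
                                                          col(Md[1:3, 1:3])]))
  expect_gt(mean(c(Mi[2, 1], Mi[3, 2])),
            mean(Mi[1:3, 1:3][ideal_credit_matrix("indirect") == 0]))
  cc <- credit_contrasts(dmat, "direct")
  expect_lt(cc$p, 0.05)
  # swapping the two cell groups negates the contrast mean
  expect_equal(mean(cc$spreading - cc$appropriate),
               -mean(cc$appropriate - cc$spreading))
})

test_that("contrast degenerates gracefully on identical matrices", {
  M <- ideal_credit_matrix("direct")
  class(M) <- c("credit_matrix", "matrix")
  attr(M, "condition") <- "direct"
  out <- credit_contrasts(list(M, M, M), "direct")
  expect_true(out$degenerate)
  expect_true(is.na(out$t))
  expect_error(credit_contrasts(list(M), "direct"), "at least 2")
})

test_that("precision score is calibrated against ideal and null patterns", {
  ideal <- ideal_credit_matrix("direct")
  noisy <- ideal + matrix(rnorm(9, 0, 1e-6), 3, 3)
  expect_equal(credit_precision(noisy, "direct"), 1, tolerance = 1e-3)
  expect_equal(credit_precision(1e-6 * matrix(rnorm(9), 3, 3) - ideal,
                                "direct"), -1, tolerance = 1e-3)
  set.seed(5)
  null_scores <- replicate(3000, credit_precision(matrix(rnorm(9), 3, 3),
                                                  "direct"))
  expect_lt(abs(mean(null_scores)), 0.03)
  expect_error(credit_precision(matrix(1, 3, 3), "direct"), "zero-variance")
  # overall score averages the two conditions
  expect_equal(overall_credit_precision(
    structure(ideal, condition = "direct"),
    structure(ideal_credit_matrix("indirect"), condition = "indirect")), 1,
    tolerance = 1e-12)
})
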