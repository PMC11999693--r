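test_that("likelihood reduces to n log 2 for an insensitive chooser", {
  sess <- quick_session()
  sim <- simulate_agent(sess, "bayes", params = list(alpha = 1, b = 0.3),
                        grid_spec = small_grid(), seed = 1)
  n <- nrow(sim$trials)
  nll <- negative_log_likelihood(list(alpha = 1, b = 1e-12), "bayes",
                                 sim$trials, grid_spec = small_grid())
  expect_equal(nll, n * log(2), tolerance = 1e-6)
})

test_that("bayes likelihood matches a conjugate closed-form oracle", {
  # Frozen dynamics + direct-only block: the grid learner's belief equals
  # the Beta-Bernoulli posterior mean, so the whole likelihood can be
  # recomputed from scratch with elementary arithmetic.
  spec <- belief_grid_spec(freeze_dynamics = TRUE)
  trials <- manual_block(10, "direct",
                         m_O1 = c(80L, 30L, 90L, 40L, 70L, 25L, 85L, 60L,
                                  95L, 35L),
                         m_O2 = c(30L, 80L, 40L, 90L, 25L, 70L, 60L, 85L,
                                  35L, 95L),
                         seed = 12)
  sim <- simulate_agent(trials, "bayes", params = list(alpha = 1.3, b = 0.2),
                        grid_spec = spec, seed = 7)
  tr <- sim$trials
  params <- list(alpha = 0.9, b = 0.15)

  # oracle: independent trial loop with conjugate counts per shape
  a1 <- b1 <- a2 <- b2 <- 0
  nll <- 0
  for (t in 1:10) {
    p1 <- (1 + a1) / (2 + a1 + b1)
    p2 <- (1 + a2) / (2 + a2 + b2)
    e1 <- p1 * tr$m_O1[t] * params$alpha + (1 - p1) * tr$m_O2[t] / params$alpha
    e2 <- p2 * tr$m_O1[t] * params$alpha + (1 - p2) * tr$m_O2[t] / params$alpha
    pr1 <- 1 / (1 + exp(-params$b * (e1 - e2)))
    nll <- nll - log(if (tr$choice[t] == "S1") pr1 else 1 - pr1)
    if (tr$choice[t] == "S1") {
      if (tr$outcome_shown[t] == "O1") a1 <- a1 + 1 else b1 <- b1 + 1
    } else {
      if (tr$outcome_shown[t] == "O1") a2 <- a2 + 1 else b2 <- b2 + 1
    }
  }
  got <- negative_log_likelihood(params, "bayes", tr, grid_spec = spec)
  # tolerance covers the midpoint-grid approximation of the conjugate mean
  expect_equal(got, nll, tolerance = 1e-3)
})

test_that("rl likelihood matches an independent trial-loop recomputation", {
  trials <- manual_block(10, "direct", seed = 5)
  sim <- simulate_agent(trials, "rl",
                        params = list(alpha = 1, b = 0.1, delta = 0.5),
                        seed = 2)
  tr <- sim$trials
  params <- list(alpha = 1.4, b = 0.08, delta = 0.3)
  V1 <- V2 <- 0
  nll <- 0
  for (t in 1:10) {
    pr1 <- 1 / (1 + exp(-params$b * (V1 - V2)))
    nll <- nll - log(if (tr$choice[t] == "S1") pr1 else 1 - pr1)
    r <- if (tr$outcome_shown[t] == "O1") params$alpha * tr$m_O1[t]
    else tr$m_O2[t] / params$alpha
    if (tr$choice[t] == "S1") V1 <- V1 + params$delta * (r - V1)
    else V2 <- V2 + params$delta * (r - V2)
  }
  got <- negative_log_likelihood(params, "rl", tr)
  expect_equal(got, nll, tolerance = 1e-10)
  expect_error(negative_log_likelihood(params, "rl",
                                       tr[0, , drop = FALSE]),
               "no usable choices")
})

test_that("mcmc chain respects bounds, improves on init, and is reproducible", {
  sess <- quick_session()
  sim <- simulate_agent(sess, "bayes", params = list(alpha = 1.2, b = 0.3),
                        grid_spec = small_grid(), seed = 4)
  f1 <- fit_learner(sim$trials, "bayes", n_iter = 800, burn_in = 100,
                    seed = 6, grid_spec = small_grid())
  f2 <- fit_learner(sim$trials, "bayes", n_iter = 800, burn_in = 100,
                    seed = 6, grid_spec = small_grid())
  expect_identical(f1$par, f2$par)
  expect_identical(f1$chain, f2$chain)
  expect_true(all(f1$chain[, "alpha"] > 0 & f1$chain[, "alpha"] < 2))
  expect_true(all(f1$chain[, "b"] > 0 & f1$chain[, "b"] < 1))
  expect_gt(f1$acceptance_rate, 0)
  expect_lt(f1$acceptance_rate, 1)
  init_nll <- negative_log_likelihood(list(alpha = 1, b = 0.5), "bayes",
                                      sim$trials, grid_spec = small_grid())
  expect_lte(f1$nll, init_nll)
  expect_equal(f1$nll, min(f1$chain_nll))
  expect_equal(unname(coef(f1)), unlist(f1$par, use.names = FALSE))
})

test_that("a random chooser is fitted with near-zero sensitivity", {
  sess <- quick_session()
  sim <- simulate_agent(sess, "bayes", params = list(alpha = 1, b = 1e-9),
                        grid_spec = small_grid(), seed = 10)
  fit <- fit_learner(sim$trials, "bayes", n_iter = 1500, burn_in = 200,
                     seed = 3, grid_spec = small_grid())
  n <- nrow(sim$trials)
  expect_lt(fit$par$b, 0.05)
  expect_lt(abs(fit$nll - n * log(2)), 5)
})

test_that("noiseless greedy data pins the sensitivity at its upper bound", {
  sess <- quick_session()
  sim <- simulate_agent(sess, "bayes", params = list(alpha = 1, b = 0.5),
                        policy = "greedy", grid_spec = small_grid(), seed = 2)
  fit <- fit_learner(sim$trials, "bayes", n_iter = 1500, burn_in = 200,
                     seed = 8, grid_spec = small_grid())
  expect_gt(fit$par$b, 0.85)
})

test_that("alpha recovery correlates across a grid of generating values", {
  alphas <- seq(0.5, 1.6, length.out = 12)
  est <- vapply(seq_along(alphas), function(i) {
    s <- 500 + i
    sess <- build_session(quick_session_config(), seed = s)
    sim <- simulate_agent(sess, "bayes",
                          params = list(alpha = alphas[i], b = 0.3),
                          grid_spec = small_grid(),
                          seed = child_seed(s, "agent"))
    fit <- fit_learner(sim$trials, "bayes", n_iter = 2000, burn_in = 300,
                       seed = child_seed(s, "fit"), grid_spec = small_grid())
    fit$par$alpha
  }, numeric(1))
  expect_gt(cor(alphas, est), 0.7)
})

test_that("recovery table has one row per generating value and replicate", {
  rec <- parameter_recovery("bayes",
                            true_params = data.frame(alpha = c(0.8, 1.2),
                                                     b = c(0.3, 0.3)),
                            n_replicates = 2,
                            config = quick_session_config(),
                            grid_spec = small_grid(), seed = 99,
                            n_iter = 400)
  expect_equal(nrow(rec), 4)
  expect_setequal(names(rec),
                  c("grid_row", "replicate", "true_alpha", "true_b",
                    "est_alpha", "est_b", "nll"))
})
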