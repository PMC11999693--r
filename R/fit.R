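#' Precompute the choice-independent features needed by the likelihood
#'
#' For the Bayesian learner, the belief trajectory depends only on the
#' observed choice/outcome stream, not on (alpha, b); evaluating the
#' likelihood at many parameter values therefore requires only one belief
#' propagation. For the RL model the causal linkage structure is
#' precomputed so that each likelihood evaluation is a cheap scalar
#' recursion.
#'
#' @param trials Completed trial table (choices and outcomes observed).
#' @param model `"bayes"` or `"rl"`.
#' @param grid_spec Belief-grid specification.
#' @return An opaque list consumed by [negative_log_likelihood()].
#' @export
nll_precompute <- function(trials, model = c("bayes", "rl"),
                           grid_spec = belief_grid_spec()) {
  model <- match.arg(model)
  if (nrow(trials) == 0 || all(is.na(trials$choice)))
    stop_arg("behavior table has no usable choices")
  n <- nrow(trials)
  ct <- ifelse(trials$condition == "direct", seq_len(n),
               trials$causal_choice_trial)
  cshape <- ifelse(is.na(ct), NA_character_, trials$choice[ct])
  shown <- ifelse(is.na(cshape), NA_character_,
                  ifelse(cshape == "S1", trials$outcome_S1[ct],
                         trials$outcome_S2[ct]))
  pre <- list(model = model, n = n, choice_s1 = trials$choice == "S1",
              defined = !is.na(trials$choice),
              m_O1 = trials$m_O1, m_O2 = trials$m_O2,
              causal_trial = ct, causal_s1 = cshape == "S1",
              shown_O1 = shown == "O1")
  if (model == "bayes") {
    trace <- learner_pass(trials, model = "bayes",
                          params = list(alpha = 1, b = 0.5),
                          grid_spec = grid_spec, seed = 0L,
                          choices = trials$choice)
    pre$p1_hat <- trace$p1_hat
    pre$p2_hat <- trace$p2_hat
  }
  pre
}

#' Negative log-likelihood of observed choices under a learner model
#'
#' `-sum_t log p(choice_t)` with choice probabilities from the softmax rule,
#' beliefs/values propagated with the condition-appropriate linkage. Trials
#' with undefined choices are excluded from the sum.
#'
#' @param params List with `alpha`, `b` (and `delta` for `"rl"`).
#' @param model `"bayes"` or `"rl"`.
#' @param trials Completed trial table; ignored if `precomp` is given.
#' @param grid_spec Belief-grid specification.
#' @param precomp Output of [nll_precompute()] (recommended when evaluating
#'   repeatedly on the same data).
#' @param alpha_mode Expected-value convention, see [expected_value()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, model = c("bayes", "rl"),
                                    trials = NULL,
                                    grid_spec = belief_grid_spec(),
                                    precomp = NULL,
                                    alpha_mode = "multiplicative") {
  model <- match.arg(model)
  if (is.null(precomp)) precomp <- nll_precompute(trials, model, grid_spec)
  pre <- precomp
  if (model == "bayes") {
    Ev1 <- expected_value(pre$p1_hat, pre$m_O1, pre$m_O2, params$alpha,
                          alpha_mode)
    Ev2 <- expected_value(pre$p2_hat, pre$m_O1, pre$m_O2, params$alpha,
                          alpha_mode)
    pr1 <- choice_probability(Ev1, Ev2, params$b)
  } else {
    pr1 <- numeric(pre$n)
    V1 <- 0; V2 <- 0
    a <- params$alpha; b <- params$b; d <- params$delta
    for (t in seq_len(pre$n)) {
      pr1[t] <- choice_probability(V1, V2, b)
      ct <- pre$causal_trial[t]
      if (!is.na(ct) && !is.na(pre$causal_s1[t])) {
        r <- if (pre$shown_O1[t]) a * pre$m_O1[ct] else pre$m_O2[ct] / a
        if (pre$causal_s1[t]) V1 <- V1 + d * (r - V1)
        else V2 <- V2 + d * (r - V2)
      }
    }
  }
  p_choice <- ifelse(pre$choice_s1, pr1, 1 - pr1)
  p_choice <- pmax(p_choice, 1e-300)
  -sum(log(p_choice[pre$defined]))
}

default_bounds <- function(model) {
  if (model == "bayes") list(alpha = c(0, 2), b = c(0, 1))
  else list(alpha = c(0, 2), b = c(0, 1), delta = c(0, 1))
}

reflect <- function(x, lo, hi) {
  span <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  min(max(x, lo + 1e-9 * span), hi - 1e-9 * span)
}

#' Fit learner parameters by random-walk MCMC on the likelihood
#'
#' Random-walk Metropolis with Gaussian proposals (sd = 5% of each
#' parameter's range) reflected at the bounds, initialized at alpha = 1,
#' b = 0.5 (delta = 0.5 for the RL model). The returned point estimate is
#' the maximum-likelihood sample visited by the chain; the full chain is
#' retained for diagnostics.
#'
#' @param trials Completed trial table.
#' @param model `"bayes"` or `"rl"`.
#' @param bounds Named list of parameter ranges; defaults to alpha in
#'   (0, 2), b in (0, 1), delta in (0, 1).
#' @param n_iter,burn_in Chain length and burn-in (burn-in samples are kept
#'   in the chain but excluded from the acceptance rate).
#' @param seed Integer seed.
#' @param grid_spec Belief-grid specification.
#' @param alpha_mode Expected-value convention.
#' @return Object of class `learner_fit` with elements `par` (best
#'   parameters), `nll`, `chain`, `chain_nll`, `acceptance_rate`, `model`,
#'   `n_trials`, `seed`, `warning`.
#' @export
fit_learner <- function(trials, model = c("bayes", "rl"), bounds = NULL,
                        n_iter = 4000, burn_in = 500, seed = 1L,
                        grid_spec = belief_grid_spec(),
                        alpha_mode = "multiplicative") {
  model <- match.arg(model)
  if (is.null(bounds)) bounds <- default_bounds(model)
  pre <- nll_precompute(trials, model, grid_spec)
  par_names <- names(bounds)
  init <- c(alpha = 1, b = 0.5, delta = 0.5)[par_names]
  prop_sd <- vapply(bounds, function(bd) 0.05 * diff(bd), numeric(1))

  chain <- matrix(NA_real_, n_iter, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_nll <- numeric(n_iter)
  cur <- init
  cur_nll <- negative_log_likelihood(as.list(cur), model, precomp = pre,
                                     alpha_mode = alpha_mode)
  best <- cur; best_nll <- cur_nll
  n_accept <- 0; n_post <- 0
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      prop <- cur
      for (j in seq_along(par_names)) {
        prop[j] <- reflect(cur[j] + rnorm(1, 0, prop_sd[j]),
                           bounds[[j]][1], bounds[[j]][2])
      }
      prop_nll <- negative_log_likelihood(as.list(prop), model,
                                          precomp = pre,
                                          alpha_mode = alpha_mode)
      accept <- log(runif(1)) < (cur_nll - prop_nll)
      if (accept) { cur <- prop; cur_nll <- prop_nll }
      if (i > burn_in) { n_post <- n_post + 1; n_accept <- n_accept + accept }
      if (cur_nll < best_nll) { best <- cur; best_nll <- cur_nll }
      chain[i, ] <- cur
      chain_nll[i] <- cur_nll
    }
  })
  acc_rate <- if (n_post > 0) n_accept / n_post else NA_real_
  out <- list(par = as.list(best), nll = best_nll, chain = chain,
              chain_nll = chain_nll, acceptance_rate = acc_rate,
              model = model, n_trials = sum(pre$defined), seed = seed,
              bounds = bounds,
              warning = if (!is.na(acc_rate) && acc_rate == 0)
                "all post-burn-in proposals rejected" else NULL)
  class(out) <- "learner_fit"
  out
}

#' @export
print.learner_fit <- function(x, ...) {
  cat(sprintf("%s learner fit (%d trials, max-likelihood MCMC sample)\n",
              x$model, x$n_trials))
  cat("  ", paste(sprintf("%s = %.3f", names(x$par), unlist(x$par)),
                  collapse = ", "), "\n")
  cat(sprintf("  NLL = %.2f, acceptance rate = %.2f\n", x$nll,
              x$acceptance_rate))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' @export
coef.learner_fit <- function(object, ...) unlist(object$par)

#' @export
logLik.learner_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$par), class = "logLik")
}

#' @export
summary.learner_fit <- function(object, ...) {
  post <- object$chain
  s <- apply(post, 2, function(v) c(mean = mean(v), sd = sd(v),
                                    q05 = unname(stats::quantile(v, 0.05)),
                                    q95 = unname(stats::quantile(v, 0.95))))
  out <- list(fit = object, chain_summary = t(s))
  class(out) <- "summary.learner_fit"
  out
}

#' @export
print.summary.learner_fit <- function(x, ...) {
  print(x$fit)
  cat("chain summary (including burn-in):\n")
  print(round(x$chain_summary, 4))
  invisible(x)
}

#' @export
plot.learner_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(ncol(x$chain) + 1, 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in colnames(x$chain))
    plot(x$chain[, nm], type = "l", ylab = nm, xlab = "", ...)
  plot(-x$chain_nll, type = "l", ylab = "logLik", xlab = "iteration", ...)
  invisible(x)
}

#' Simulate-and-refit parameter recovery
#'
#' For each row of `true_params` and each replicate: build a session,
#' simulate an agent at the generating parameters (softmax sampling),
#' refit by MCMC, and tabulate recovered values.
#'
#' @param model `"bayes"` or `"rl"`.
#' @param true_params Data frame of generating parameter values (columns
#'   `alpha`, `b`, optionally `delta`).
#' @param n_replicates Replicates per generating value.
#' @param config Session configuration.
#' @param seed Master seed.
#' @param grid_spec Belief-grid specification.
#' @param n_iter MCMC chain length per fit.
#' @return Data frame with one row per (generating value, replicate):
#'   true and recovered parameters plus the fit NLL.
#' @export
parameter_recovery <- function(model = "bayes",
                               true_params = data.frame(alpha = 1.2, b = 0.3),
                               n_replicates = 10,
                               config = session_config(), seed = 1L,
                               grid_spec = belief_grid_spec(),
                               n_iter = 4000) {
  rows <- list()
  for (g in seq_len(nrow(true_params))) {
    pars <- as.list(true_params[g, , drop = FALSE])
    for (r in seq_len(n_replicates)) {
      s <- child_seed(seed, sprintf("rec-%d-%d", g, r))
      sess <- build_session(config, seed = s)
      sim <- simulate_agent(sess, model = model, params = pars,
                            policy = "sample", grid_spec = grid_spec,
                            seed = child_seed(s, "agent"))
      fit <- fit_learner(sim$trials, model = model, seed = child_seed(s, "fit"),
                         grid_spec = grid_spec, n_iter = n_iter)
      row <- data.frame(grid_row = g, replicate = r)
      for (nm in names(pars)) row[[paste0("true_", nm)]] <- pars[[nm]]
      for (nm in names(fit$par)) row[[paste0("est_", nm)]] <- fit$par[[nm]]
      row$nll <- fit$nll
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
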