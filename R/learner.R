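#' Expected value of a shape under the current belief
#'
#' Combines the posterior mean transition probability with the current
#' trial's point magnitudes, weighted by the outcome-preference parameter
#' alpha: `Ev = p_hat * m_O1 * alpha + (1 - p_hat) * m_O2 / alpha`. An
#' exponent variant (`m^alpha`, `m^(1/alpha)`) is available behind
#' `alpha_mode` as a documented deviation knob.
#'
#' @param p_hat Posterior mean probability that the shape leads to O1.
#' @param m_O1,m_O2 Point magnitudes of the two outcomes on the current
#'   trial.
#' @param alpha Outcome-preference weight in (0, 2).
#' @param alpha_mode `"multiplicative"` (default) or `"exponent"`.
#' @return Scalar expected value.
#' @export
expected_value <- function(p_hat, m_O1, m_O2, alpha,
                           alpha_mode = c("multiplicative", "exponent")) {
  if (any(alpha <= 0)) stop_arg("alpha must be positive")
  alpha_mode <- match.arg(alpha_mode)
  if (alpha_mode == "multiplicative")
    p_hat * m_O1 * alpha + (1 - p_hat) * m_O2 * (1 / alpha)
  else
    p_hat * m_O1^alpha + (1 - p_hat) * m_O2^(1 / alpha)
}

#' Softmax probability of choosing S1
#'
#' `exp(b * Ev_S1) / (exp(b * Ev_S1) + exp(b * Ev_S2))`, computed
#' overflow-safely.
#'
#' @param Ev_S1,Ev_S2 Expected values.
#' @param b Choice sensitivity (inverse temperature).
#' @return Probability of choosing S1.
#' @export
choice_probability <- function(Ev_S1, Ev_S2, b) {
  z <- b * (Ev_S1 - Ev_S2)
  1 / (1 + exp(-pmin(pmax(z, -700), 700)))
}

#' Delta-rule update of a cached shape value
#'
#' `V_chosen <- V + delta * (r - V)` where the effective reward `r` is the
#' alpha-weighted point magnitude of the obtained outcome (`alpha * R` for
#' O1, `R / alpha` for O2), giving alpha the same role as in the Bayesian
#' model's expected value. The unchosen value is unchanged.
#'
#' @param state Named list/vector with `V_S1`, `V_S2`.
#' @param chosen `"S1"` or `"S2"`.
#' @param R Point magnitude of the obtained outcome.
#' @param params List with `alpha` and `delta`.
#' @param outcome Identity of the obtained outcome (`"O1"` / `"O2"`).
#' @return Updated state.
#' @export
rl_update <- function(state, chosen, R, params, outcome = "O1") {
  r <- if (outcome == "O1") params$alpha * R else R / params$alpha
  key <- paste0("V_", chosen)
  state[[key]] <- state[[key]] + params$delta * (r - state[[key]])
  state
}

# One pass of a learner over a session's learning trials. If `choices` is
# given, the agent's choices are clamped to it (used for likelihood
# evaluation); otherwise choices are generated by `policy`. Belief updates
# are applied when an outcome is *displayed*: direct blocks link trial t's
# outcome to trial t's choice, indirect blocks link the outcome shown on
# trial t to the choice made on t-1, and the first display of an indirect
# block updates nothing. Both shapes' beliefs diffuse every trial; only the
# causal shape receives a likelihood update.
learner_pass <- function(trials, model = c("bayes", "rl"),
                         params, policy = c("sample", "greedy"),
                         grid_spec = belief_grid_spec(), seed = 1L,
                         choices = NULL,
                         alpha_mode = "multiplicative") {
  model <- match.arg(model)
  policy <- match.arg(policy)
  if (!all(c("condition", "m_O1", "m_O2", "outcome_S1", "outcome_S2",
             "causal_choice_trial") %in% names(trials)))
    stop_arg("trials table is missing required columns (causal linkage?)")
  n <- nrow(trials)
  given <- !is.null(choices)
  if (given && length(choices) != n) stop_arg("choices length mismatch")
  alpha <- params$alpha
  b <- params$b
  if (model == "bayes") {
    kern <- belief_kernels(grid_spec)
    g1 <- init_belief_grid(grid_spec, kern)
    g2 <- init_belief_grid(grid_spec, kern)
  } else {
    V1 <- 0; V2 <- 0
    delta <- params$delta
  }
  has_shown <- "outcome_shown" %in% names(trials) &&
    !all(is.na(trials$outcome_shown))
  p1h <- p2h <- Ev1 <- Ev2 <- pr1 <- rep(NA_real_, n)
  ch <- shown <- upd_shape <- rep(NA_character_, n)

  with_seed(seed, {
    for (t in seq_len(n)) {
      if (model == "bayes") {
        p1h[t] <- point_estimate(g1)
        p2h[t] <- point_estimate(g2)
        Ev1[t] <- expected_value(p1h[t], trials$m_O1[t], trials$m_O2[t],
                                  alpha, alpha_mode)
        Ev2[t] <- expected_value(p2h[t], trials$m_O1[t], trials$m_O2[t],
                                  alpha, alpha_mode)
      } else {
        Ev1[t] <- V1; Ev2[t] <- V2
      }
      pr1[t] <- choice_probability(Ev1[t], Ev2[t], b)
      ch[t] <- if (given) choices[t]
      else if (policy == "greedy") {
        if (abs(Ev1[t] - Ev2[t]) < 1e-9) sample(c("S1", "S2"), 1)
        else if (Ev1[t] > Ev2[t]) "S1" else "S2"
      } else {
        if (runif(1) < pr1[t]) "S1" else "S2"
      }

      ct <- if (trials$condition[t] == "direct") t
      else trials$causal_choice_trial[t]
      if (!is.na(ct) && !is.na(if (ct == t) ch[t] else ch[ct])) {
        cshape <- if (ct == t) ch[t] else ch[ct]
        shown[t] <- if (cshape == "S1") trials$outcome_S1[ct]
        else trials$outcome_S2[ct]
        upd_shape[t] <- cshape
        if (model == "bayes") {
          if (cshape == "S1") {
            g1 <- update_beliefs(g1, shown[t])
            g2 <- update_beliefs(g2, predict_only = TRUE)
          } else {
            g2 <- update_beliefs(g2, shown[t])
            g1 <- update_beliefs(g1, predict_only = TRUE)
          }
        } else {
          R <- if (shown[t] == "O1") trials$m_O1[ct] else trials$m_O2[ct]
          r <- if (shown[t] == "O1") alpha * R else R / alpha
          if (cshape == "S1") V1 <- V1 + delta * (r - V1)
          else V2 <- V2 + delta * (r - V2)
        }
      } else {
        # unlinked first feedback of an indirect block: an outcome is
        # displayed (random shape's predetermined outcome) but nothing
        # is learned from it
        if (is.na(ct)) {
          shown[t] <- if (given && has_shown &&
                           !is.na(trials$outcome_shown[t]))
            trials$outcome_shown[t]
          else if (runif(1) < 0.5) trials$outcome_S1[t]
          else trials$outcome_S2[t]
        }
        if (model == "bayes") {
          g1 <- update_beliefs(g1, predict_only = TRUE)
          g2 <- update_beliefs(g2, predict_only = TRUE)
        }
      }
    }
  })
  trial_id <- if (!is.null(trials$trial)) trials$trial else seq_len(n)
  trace <- data.frame(trial = trial_id, p1_hat = p1h, p2_hat = p2h,
                      Ev_S1 = Ev1, Ev_S2 = Ev2, p_choice_S1 = pr1,
                      choice = ch, outcome_shown = shown,
                      update_shape = upd_shape, stringsAsFactors = FALSE)
  trace
}

#' Simulate an agent on a task session
#'
#' Runs the Bayesian volatility learner or the value-caching RL model over a
#' session's learning trials, generating choices (softmax sampling or greedy
#' argmax) and applying belief/value updates with the condition-appropriate
#' choice-outcome linkage (see [build_session()] for the linkage rules).
#'
#' @param session A `credit_session`, or a learning-trial table.
#' @param model `"bayes"` or `"rl"`.
#' @param params List with `alpha`, `b` (and `delta` for `"rl"`).
#' @param policy `"sample"` (softmax) or `"greedy"` (argmax, ties random).
#' @param grid_spec Belief-grid specification (`"bayes"` only).
#' @param seed Integer seed for the agent's stream.
#' @param alpha_mode Expected-value convention, see [expected_value()].
#' @return Object of class `learner_sim`: list with the completed `trials`
#'   table (choice, displayed outcome filled in) and the per-trial `trace`.
#' @export
simulate_agent <- function(session, model = c("bayes", "rl"), params,
                           policy = c("sample", "greedy"),
                           grid_spec = belief_grid_spec(), seed = 1L,
                           alpha_mode = "multiplicative") {
  trials <- if (inherits(session, "credit_session")) session$trials
  else session
  trace <- learner_pass(trials, model = model, params = params,
                        policy = policy, grid_spec = grid_spec, seed = seed,
                        alpha_mode = alpha_mode)
  trials$choice <- trace$choice
  trials$outcome_shown <- trace$outcome_shown
  out <- list(trials = trials, trace = trace, model = match.arg(model),
              params = params, seed = seed)
  class(out) <- "learner_sim"
  out
}

#' @export
print.learner_sim <- function(x, ...) {
  cat(sprintf("Simulated %s agent: %d trials, S1 share %.1f%%\n",
              x$model, nrow(x$trials), 100 * mean(x$trials$choice == "S1")))
  invisible(x)
}

#' Total alpha-weighted points earned by a completed behavior table
#'
#' @param trials Completed trial table (choices and shown outcomes filled).
#' @param alpha Outcome-preference weight.
#' @return Scalar sum of weighted points over linked outcomes.
#' @export
earned_points <- function(trials, alpha = 1) {
  ct <- ifelse(trials$condition == "direct", trials$trial,
               trials$causal_choice_trial)
  ok <- !is.na(ct) & !is.na(trials$outcome_shown)
  sum(ifelse(trials$outcome_shown[ok] == "O1",
             alpha * trials$m_O1[ct[ok]],
             (1 / alpha) * trials$m_O2[ct[ok]]))
}
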