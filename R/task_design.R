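#' Gaussian random walk on the log-odds scale, clipped to bounds
#'
#' Generates a slowly drifting transition-probability trajectory for one
#' shape. The walk lives on the log-odds scale (steps are Gaussian with sd
#' `step_sd`) and is clipped to `bounds` on the probability scale, so the
#' contingency can never become deterministic.
#'
#' @param n_trials Number of trials (positive integer).
#' @param step_sd Standard deviation of the log-odds step. Default 0.15.
#' @param bounds Length-2 probability bounds within (0, 1). Default
#'   `c(0.1, 0.9)`.
#' @param start Starting probability; if `NULL`, drawn uniformly from
#'   `bounds`.
#' @param seed Optional integer seed for this walk's stream.
#' @return Numeric vector of length `n_trials` with values in `bounds`.
#' @export
generate_probability_walk <- function(n_trials, step_sd = 0.15,
                                      bounds = c(0.1, 0.9), start = NULL,
                                      seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1)
    stop_arg("n_trials must be a positive integer")
  if (step_sd < 0) stop_arg("step_sd must be non-negative")
  if (length(bounds) != 2 || bounds[1] <= 0 || bounds[2] >= 1 ||
      bounds[1] >= bounds[2])
    stop_arg("bounds must be an increasing pair within (0, 1)")
  run <- function() {
    p0 <- if (is.null(start)) runif(1, bounds[1], bounds[2]) else start
    x <- qlogis(min(max(p0, bounds[1]), bounds[2]))
    lo <- qlogis(bounds[1]); hi <- qlogis(bounds[2])
    out <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      if (t > 1) x <- x + rnorm(1, 0, step_sd)
      x <- min(max(x, lo), hi)
      out[t] <- plogis(x)
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Per-trial outcome point magnitudes
#'
#' Draws integer point values in \[20, 100\] for the two outcome identities,
#' with a minimum per-trial difference of 15 points. Whole sequences are
#' rejected and regenerated until the lag-1 autocorrelation of each outcome's
#' magnitude series is below 0.2 in absolute value, so that magnitude history
#' carries no exploitable structure.
#'
#' @param n_trials Number of trials (at least 2).
#' @param seed Optional integer seed.
#' @param max_attempts Rejection budget for the whole-sequence constraint.
#' @return Data frame with integer columns `m_O1`, `m_O2`.
#' @export
generate_magnitudes <- function(n_trials, seed = NULL, max_attempts = 1000) {
  if (!is.numeric(n_trials) || n_trials < 2)
    stop_arg("n_trials must be at least 2")
  if (max_attempts < 1) stop_arg("max_attempts must be at least 1")
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      m1 <- sample(20:100, n_trials, replace = TRUE)
      m2 <- integer(n_trials)
      for (t in seq_len(n_trials)) {
        allowed <- setdiff(20:100, (m1[t] - 14):(m1[t] + 14))
        m2[t] <- if (length(allowed) == 1) allowed else sample(allowed, 1)
      }
      if (n_trials < 3) {
        r1 <- r2 <- 0  # lag-1 correlation is vacuous below 3 trials
      } else {
        r1 <- cor(m1[-n_trials], m1[-1])
        r2 <- cor(m2[-n_trials], m2[-1])
        if (is.na(r1)) r1 <- 0
        if (is.na(r2)) r2 <- 0
      }
      if (abs(r1) < 0.2 && abs(r2) < 0.2)
        return(data.frame(m_O1 = m1, m_O2 = m2))
    }
    stop(sprintf(paste0("magnitude generation failed after %d attempts ",
                        "(last lag-1 r: %.3f, %.3f)"),
                 max_attempts, r1, r2), call. = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Realize the predetermined outcome schedule
#'
#' For each trial and each shape, draws the outcome identity (O1 with the
#' shape's current transition probability, O2 otherwise). The two shapes use
#' independent RNG substreams so neither schedule is informative about the
#' other.
#'
#' @param p1_traj,p2_traj Per-trial probability trajectories for S1 and S2.
#' @param seed Optional integer seed.
#' @return Data frame with character columns `outcome_S1`, `outcome_S2`
#'   (values `"O1"` / `"O2"`).
#' @export
realize_outcome_schedule <- function(p1_traj, p2_traj, seed = NULL) {
  if (length(p1_traj) != length(p2_traj))
    stop_arg("trajectories must have the same length")
  n <- length(p1_traj)
  draw <- function(p, s) {
    u <- if (is.null(seed)) runif(n) else with_seed(child_seed(seed, s),
                                                    runif(n))
    ifelse(u < p, "O1", "O2")
  }
  data.frame(outcome_S1 = draw(p1_traj, "S1"),
             outcome_S2 = draw(p2_traj, "S2"),
             stringsAsFactors = FALSE)
}

#' Default session configuration
#'
#' @param n_runs Number of scanning runs (the last is template-only).
#' @param trials_per_block Learning trials per condition block per run.
#' @param step_sd Probability-walk step sd on the log-odds scale.
#' @param bounds Probability-walk bounds.
#' @param template_reps Template presentations per stimulus per template
#'   block.
#' @param n_catch Catch trials per template block.
#' @param accept_budget Schedule-regeneration budget for ideal-learner
#'   acceptance.
#' @param grid_spec Belief-grid specification for the ideal learner (see
#'   [belief_grid_spec()]).
#' @return A named list, usable as `config` in [build_session()].
#' @export
session_config <- function(n_runs = 3, trials_per_block = 37, step_sd = 0.15,
                           bounds = c(0.1, 0.9), template_reps = 12,
                           n_catch = 4, accept_budget = 500,
                           grid_spec = belief_grid_spec()) {
  list(n_runs = n_runs, trials_per_block = trials_per_block,
       step_sd = step_sd, bounds = bounds, template_reps = template_reps,
       n_catch = n_catch, accept_budget = accept_budget,
       grid_spec = grid_spec)
}

#' Ideal-learner acceptance check for a candidate schedule
#'
#' Simulates an ideal Bayesian learner (outcome-preference weight alpha = 1,
#' greedy argmax choice, ties broken at random) across all learning trials of
#' the candidate session, and accepts the schedule iff the percentage of
#' trials on which S1 was chosen lies in \[42, 57\]. This filter keeps choice
#' and outcome frequencies near-balanced for downstream multivariate
#' analyses.
#'
#' @param trials Candidate learning-trial table (see [build_session()]).
#' @param grid_spec Belief-grid specification for the ideal learner.
#' @param seed Seed for the ideal agent's tie-breaking stream.
#' @return List with `accept` (logical), `s1_share` (proportion), and choice
#'   / outcome frequency tables.
#' @export
accept_schedule <- function(trials, grid_spec = belief_grid_spec(),
                            seed = 1L) {
  sim <- simulate_agent(trials, model = "bayes",
                        params = list(alpha = 1, b = 0.5),
                        policy = "greedy", grid_spec = grid_spec, seed = seed)
  ch <- sim$trials$choice
  s1_share <- mean(ch == "S1")
  list(accept = s1_share >= 0.42 && s1_share <= 0.57,
       s1_share = s1_share,
       choice_freq = table(ch),
       outcome_freq = table(sim$trials$outcome_shown))
}

# Lay out one template block: stimuli in random order plus catch positions.
template_block <- function(run, reps, n_catch) {
  stims <- sample(rep(c("S1", "S2", "O1", "O2"), reps))
  n <- length(stims)
  catch_after <- sort(sample(seq_len(n), n_catch))
  data.frame(run = run, position = seq_len(n), stimulus = stims,
             catch_after = seq_len(n) %in% catch_after,
             stringsAsFactors = FALSE)
}

#' Build a complete task session
#'
#' Generates candidate transition schedules (independent log-odds random
#' walks per shape), point magnitudes and predetermined outcomes, and keeps
#' regenerating until the ideal-learner acceptance filter passes. Each of the
#' first `n_runs - 1` runs contains a template block followed by a direct
#' block and an indirect block of `trials_per_block` trials each; the final
#' run is template-only. The `causal_choice_trial` column links each
#' displayed outcome to the trial whose choice caused it: the same trial in
#' direct blocks, the previous trial in indirect blocks, and `NA` for the
#' unlinked first feedback of each indirect block.
#'
#' @param config Session configuration from [session_config()].
#' @param seed Integer master seed for the session.
#' @return An object of class `credit_session`: list with `trials` (learning
#'   trial table), `layout` (template-block table), `schedule`, `acceptance`,
#'   `config`, `seed`, `attempts`.
#' @export
build_session <- function(config = session_config(), seed = 1L) {
  n_learn <- (config$n_runs - 1) * 2 * config$trials_per_block
  for (attempt in seq_len(config$accept_budget)) {
    aseed <- child_seed(seed, paste0("attempt", attempt))
    p1 <- generate_probability_walk(n_learn, config$step_sd, config$bounds,
                                    seed = child_seed(aseed, "p1"))
    p2 <- generate_probability_walk(n_learn, config$step_sd, config$bounds,
                                    seed = child_seed(aseed, "p2"))
    mags <- generate_magnitudes(n_learn, seed = child_seed(aseed, "mag"))
    outs <- realize_outcome_schedule(p1, p2, seed = child_seed(aseed, "out"))

    tpb <- config$trials_per_block
    run <- rep(seq_len(config$n_runs - 1), each = 2 * tpb)
    condition <- rep(rep(c("direct", "indirect"), each = tpb),
                     config$n_runs - 1)
    idx <- seq_len(n_learn)
    block_start <- idx - (idx - 1) %% tpb
    causal <- ifelse(condition == "direct", idx,
                     ifelse(idx == block_start, NA_integer_, idx - 1L))
    bonus <- with_seed(child_seed(aseed, "bonus"), {
      b <- logical(n_learn)
      for (r in seq_len(config$n_runs - 1)) {
        dblock <- which(run == r & condition == "direct")
        iblock <- which(run == r & condition == "indirect")
        b[sample(dblock, 2)] <- TRUE
        b[sample(iblock, 1)] <- TRUE
      }
      b
    })
    trials <- data.frame(trial = idx, run = run, condition = condition,
                         trial_in_block = (idx - 1) %% tpb + 1L,
                         p1 = p1, p2 = p2,
                         outcome_S1 = outs$outcome_S1,
                         outcome_S2 = outs$outcome_S2,
                         m_O1 = mags$m_O1, m_O2 = mags$m_O2,
                         choice = NA_character_,
                         outcome_shown = NA_character_,
                         causal_choice_trial = causal,
                         bonus = bonus, stringsAsFactors = FALSE)
    acc <- accept_schedule(trials, config$grid_spec,
                           seed = child_seed(aseed, "ideal"))
    if (acc$accept) {
      layout <- with_seed(child_seed(aseed, "template"), {
        do.call(rbind, lapply(seq_len(config$n_runs), function(r)
          template_block(r, config$template_reps, config$n_catch)))
      })
      out <- list(trials = trials, layout = layout,
                  schedule = list(p1 = p1, p2 = p2,
                                  outcome_S1 = outs$outcome_S1,
                                  outcome_S2 = outs$outcome_S2),
                  acceptance = acc, config = config, seed = seed,
                  attempts = attempt)
      class(out) <- "credit_session"
      return(out)
    }
  }
  stop(sprintf("no schedule accepted within %d attempts (last S1 share %.3f)",
               config$accept_budget, acc$s1_share), call. = FALSE)
}

#' @export
print.credit_session <- function(x, ...) {
  cat("Contingent-learning task session\n")
  cat(sprintf("  runs: %d (last template-only); %d learning trials\n",
              x$config$n_runs, nrow(x$trials)))
  cat(sprintf("  ideal-learner S1 share: %.1f%% (accepted after %d attempt%s)\n",
              100 * x$acceptance$s1_share, x$attempts,
              if (x$attempts == 1) "" else "s"))
  invisible(x)
}

#' Serialize a session to TSV event files plus a JSON sidecar
#'
#' @param session A `credit_session`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_events(session$trials, file.path(dir, "trials.tsv"),
                   sidecar = list(seed = session$seed,
                                  attempts = session$attempts,
                                  config = session$config[
                                    setdiff(names(session$config),
                                            "grid_spec")]))
  write_tsv_events(session$layout, file.path(dir, "template_layout.tsv"))
  invisible(dir)
}
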