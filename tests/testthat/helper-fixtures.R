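# Shared fixtures, built once per test run and cached.

.fixtures <- new.env()

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A coarse belief grid: much faster than the default and sufficient wherever
# grid resolution itself is not under test.
small_grid <- function() belief_grid_spec(n_p = 20, n_v = 8, n_k = 5)

quick_session_config <- function(...) {
  session_config(grid_spec = small_grid(), ...)
}

default_session <- function() {
  get_fixture("default_session", function() build_session(seed = 42))
}

quick_session <- function() {
  get_fixture("quick_session",
              function() build_session(quick_session_config(), seed = 42))
}

# Small-volume cohort configuration used by the neural tests.
quick_cohort_config <- function(...) {
  cohort_config(dim = c(12, 12, 8), roi_dim = c(4, 4, 4),
                session = quick_session_config(), ...)
}

# Hand-rolled learning block: fixed probabilities and magnitudes, no
# acceptance filtering, for targeted behavioral checks.
manual_block <- function(n, condition = "direct", run = 1L,
                         p1 = 0.8, p2 = 0.2, m_O1 = NULL, m_O2 = NULL,
                         seed = 1L) {
  if (is.null(m_O1)) m_O1 <- rep(80L, n)
  if (is.null(m_O2)) m_O2 <- rep(30L, n)
  outs <- realize_outcome_schedule(rep(p1, n), rep(p2, n), seed = seed)
  idx <- seq_len(n)
  causal <- if (condition == "direct") idx
  else c(NA_integer_, idx[-n])
  data.frame(trial = idx, run = run, condition = condition,
             trial_in_block = idx, p1 = p1, p2 = p2,
             outcome_S1 = outs$outcome_S1, outcome_S2 = outs$outcome_S2,
             m_O1 = m_O1, m_O2 = m_O2,
             choice = NA_character_, outcome_shown = NA_character_,
             causal_choice_trial = causal, bonus = FALSE,
             stringsAsFactors = FALSE)
}
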