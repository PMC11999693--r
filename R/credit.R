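#' Build the lagged choice-by-outcome design for one condition
#'
#' For each eligible trial t, constructs nine regressors
#' `C{i}O{j}` for choice lag i and outcome lag j in 1..3. The lagged choice
#' code C is +1 if the choice at t-i was S1 and -1 otherwise; the lagged
#' outcome code O is +1 if the outcome displayed at t-j matches the
#' currently desired outcome (the identity carrying the larger point value
#' on trial t) and -1 otherwise; the cell value is the product C*O. The
#' response is the current choice (S1 -> 1, S2 -> 0).
#'
#' Rows with incomplete 3-back history within a run-by-condition block are
#' excluded, as are indirect-block rows whose outcome lags touch the
#' unlinked first feedback of the block.
#'
#' @param trials Completed trial table.
#' @param condition `"direct"` or `"indirect"`.
#' @param run Optional run id to restrict to.
#' @return Data frame with columns `response`, `C1O1`, `C2O1`, `C3O1`,
#'   `C1O2`, ..., `C3O3`, plus `trial`; zero rows (with a warning) if every
#'   block is shorter than 4 trials.
#' @export
build_lag_design <- function(trials, condition = c("direct", "indirect"),
                             run = NULL) {
  condition <- match.arg(condition)
  if (!is.null(run)) trials <- trials[trials$run == run, , drop = FALSE]
  trials <- trials[trials$condition == condition, , drop = FALSE]
  cols <- as.vector(outer(1:3, 1:3, function(i, j)
    sprintf("C%dO%d", i, j)))
  empty <- stats::setNames(
    as.data.frame(matrix(numeric(0), 0, length(cols) + 2)),
    c("trial", "response", cols))
  if (nrow(trials) == 0) return(empty)

  rows <- list()
  for (r in unique(trials$run)) {
    blk <- trials[trials$run == r, , drop = FALSE]
    nb <- nrow(blk)
    if (nb < 4) next
    desired_O1 <- blk$m_O1 > blk$m_O2  # desired outcome on trial t
    unlinked <- blk$condition == "indirect" & is.na(blk$causal_choice_trial)
    for (t in 4:nb) {
      if (is.na(blk$choice[t])) next
      lag_ok <- TRUE
      x <- numeric(9)
      nmix <- 0
      for (j in 1:3) {
        for (i in 1:3) {
          nmix <- nmix + 1
          tc <- t - i; to <- t - j
          if (is.na(blk$choice[tc]) || is.na(blk$outcome_shown[to]) ||
              unlinked[to]) { lag_ok <- FALSE; break }
          C <- if (blk$choice[tc] == "S1") 1 else -1
          want <- if (desired_O1[t]) "O1" else "O2"
          O <- if (blk$outcome_shown[to] == want) 1 else -1
          x[nmix] <- C * O
        }
        if (!lag_ok) break
      }
      if (!lag_ok) next
      row <- as.data.frame(as.list(x))
      names(row) <- as.vector(outer(1:3, 1:3, function(i, j)
        sprintf("C%dO%d", i, j)))
      row$trial <- blk$trial[t]
      row$response <- as.integer(blk$choice[t] == "S1")
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    warning("no eligible rows (blocks shorter than 4 trials?)")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out[, c("trial", "response", cols)]
}

#' Ridge-penalized logistic regression of choice on the lag design
#'
#' Iteratively reweighted least squares with an L2 penalty on the nine
#' slopes (the intercept is unpenalized). The penalty stabilizes the fit
#' against separation at the block lengths this task produces; with
#' `ridge = 0` and separable data the coefficients are capped and flagged.
#'
#' @param design Output of [build_lag_design()].
#' @param ridge Penalty weight lambda (>= 0). Default 1.
#' @param max_iter,tol IRLS controls.
#' @param cap Absolute coefficient cap applied when an unpenalized fit
#'   diverges.
#' @return List with `beta` (named vector `beta0`, `C1O1`, ...),
#'   `separation` flag, and `converged`.
#' @export
fit_choice_model <- function(design, ridge = 1, max_iter = 100, tol = 1e-8,
                             cap = 20) {
  if (nrow(design) == 0) stop_arg("empty design")
  if (ridge < 0) stop_arg("ridge must be >= 0")
  cols <- setdiff(names(design), c("trial", "response"))
  X <- cbind(1, as.matrix(design[, cols, drop = FALSE]))
  y <- design$response
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1)))
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new_beta <- tryCatch(
      drop(solve(XtW %*% X + pen, XtW %*% z)),
      error = function(e) beta)
    if (max(abs(new_beta)) > 1e6) { beta <- new_beta; break }
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  separation <- ridge == 0 && max(abs(beta)) > cap
  if (separation) {
    warning("perfect separation with ridge = 0; coefficients capped")
    beta <- pmin(pmax(beta, -cap), cap)
  }
  names(beta) <- c("beta0", cols)
  list(beta = beta, separation = separation, converged = converged)
}

#' Participant-level credit matrix
#'
#' Fits the lagged choice model separately per run, averages the slope
#' coefficients across runs, and arranges them as a 3x3 matrix with rows =
#' choice lag (1..3) and columns = outcome lag (1..3).
#'
#' @param trials Completed trial table (all runs).
#' @param condition `"direct"` or `"indirect"`.
#' @param ridge Penalty weight passed to [fit_choice_model()].
#' @return Object of class `credit_matrix`: the 3x3 beta matrix with
#'   attributes `intercept` and `condition`.
#' @export
participant_credit_matrix <- function(trials,
                                      condition = c("direct", "indirect"),
                                      ridge = 1) {
  condition <- match.arg(condition)
  runs <- unique(trials$run[trials$condition == condition])
  fits <- list()
  for (r in runs) {
    d <- build_lag_design(trials, condition, run = r)
    if (nrow(d) == 0) next
    fits[[length(fits) + 1]] <- fit_choice_model(d, ridge = ridge)$beta
  }
  if (length(fits) == 0) stop_arg("no run produced a nonempty design")
  avg <- Reduce(`+`, fits) / length(fits)
  M <- matrix(NA_real_, 3, 3,
              dimnames = list(paste0("choice_lag", 1:3),
                              paste0("outcome_lag", 1:3)))
  for (i in 1:3) for (j in 1:3) M[i, j] <- avg[sprintf("C%dO%d", i, j)]
  attr(M, "intercept") <- unname(avg["beta0"])
  attr(M, "condition") <- condition
  class(M) <- c("credit_matrix", "matrix")
  M
}

#' @export
print.credit_matrix <- function(x, ...) {
  cat(sprintf("Credit matrix (%s condition), rows = choice lag, cols = outcome lag\n",
              attr(x, "condition")))
  print(round(unclass(x)[1:3, 1:3], 3))
  invisible(x)
}

#' @export
plot.credit_matrix <- function(x, ...) {
  M <- unclass(x)[1:3, 1:3]
  graphics::image(1:3, 1:3, t(M[3:1, ]), xlab = "outcome lag",
                  ylab = "choice lag", axes = FALSE,
                  main = paste(attr(x, "condition"), "credit matrix"), ...)
  graphics::axis(1, 1:3); graphics::axis(2, 1:3, labels = 3:1)
  invisible(x)
}

#' Ideal binary credit matrix for a condition
#'
#' 1 in each cell representing appropriate credit assignment given the
#' condition's causal structure (the diagonal for direct transitions;
#' choice lag = outcome lag + 1 for indirect transitions), 0 elsewhere.
#'
#' @param condition `"direct"` or `"indirect"`.
#' @return 3x3 binary matrix (rows = choice lag, cols = outcome lag).
#' @export
ideal_credit_matrix <- function(condition = c("direct", "indirect")) {
  condition <- match.arg(condition)
  M <- matrix(0, 3, 3, dimnames = list(paste0("choice_lag", 1:3),
                                       paste0("outcome_lag", 1:3)))
  if (condition == "direct") diag(M) <- 1
  else { M[2, 1] <- 1; M[3, 2] <- 1 }
  M
}

#' Appropriate-versus-spreading contrast across participants
#'
#' Splits each participant's 3x3 matrix into cells reflecting appropriate
#' credit assignment for the condition and the remaining (credit-spreading)
#' cells, and tests appropriate > spreading with a one-tailed paired t-test.
#'
#' @param matrices List of `credit_matrix` objects, one per participant,
#'   all from the same condition.
#' @param condition `"direct"` or `"indirect"`; defaults to the condition
#'   tag of the first matrix.
#' @return List with per-participant `appropriate` and `spreading` means,
#'   the contrast `t`, `df`, one-tailed `p`, and a `degenerate` flag set
#'   when the contrast has zero variance.
#' @export
credit_contrasts <- function(matrices, condition = NULL) {
  if (length(matrices) < 2) stop_arg("need at least 2 participants")
  if (is.null(condition)) condition <- attr(matrices[[1]], "condition")
  ideal <- ideal_credit_matrix(condition)
  app <- vapply(matrices, function(M) mean(unclass(M)[ideal == 1]),
                numeric(1))
  spr <- vapply(matrices, function(M) mean(unclass(M)[ideal == 0]),
                numeric(1))
  d <- app - spr
  if (sd(d) < 1e-12) {
    return(list(appropriate = app, spreading = spr, t = NA_real_,
                df = length(d) - 1, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(app, spr, paired = TRUE, alternative = "greater")
  list(appropriate = app, spreading = spr,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Cross-condition comparison of appropriate-cell means
#'
#' One-tailed paired t-test that appropriate-cell means are higher in the
#' direct than the indirect condition (credit assignment more precise when
#' transitions are direct).
#'
#' @param direct_matrices,indirect_matrices Per-participant matrices for
#'   the two conditions (same participant order).
#' @return List with `t`, `df`, one-tailed `p`, and the per-condition
#'   means.
#' @export
condition_comparison <- function(direct_matrices, indirect_matrices) {
  if (length(direct_matrices) != length(indirect_matrices))
    stop_arg("mismatched participant sets")
  ad <- vapply(direct_matrices, function(M)
    mean(unclass(M)[ideal_credit_matrix("direct") == 1]), numeric(1))
  ai <- vapply(indirect_matrices, function(M)
    mean(unclass(M)[ideal_credit_matrix("indirect") == 1]), numeric(1))
  tt <- t.test(ad, ai, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_direct = mean(ad), mean_indirect = mean(ai))
}

#' Credit-assignment precision of one matrix
#'
#' Pearson correlation between the nine beta values and the condition's
#' binary ideal matrix.
#'
#' @param matrix A `credit_matrix` (or plain 3x3 matrix).
#' @param condition `"direct"` or `"indirect"`.
#' @return Scalar correlation in \[-1, 1\].
#' @export
credit_precision <- function(matrix, condition = NULL) {
  if (is.null(condition)) condition <- attr(matrix, "condition")
  v <- as.vector(unclass(matrix)[1:3, 1:3])
  if (sd(v) < 1e-12)
    stop_arg("zero-variance matrix: precision undefined")
  cor(v, as.vector(ideal_credit_matrix(condition)))
}

#' Overall credit precision across conditions
#'
#' @param direct_matrix,indirect_matrix Per-condition credit matrices for
#'   one participant.
#' @return Mean of the two per-condition precision correlations.
#' @export
overall_credit_precision <- function(direct_matrix, indirect_matrix) {
  mean(c(credit_precision(direct_matrix, "direct"),
         credit_precision(indirect_matrix, "indirect")))
}

#' Rule-following reference agent
#'
#' A deterministic credit-assignment rule used in recovery checks: repeat a
#' shape iff the most recently displayed *causally linked* outcome of that
#' shape matched the currently desired outcome -- i.e. in direct blocks the
#' agent repeats its last choice iff that choice just produced the desired
#' outcome, and in indirect blocks it applies the same rule to the choice
#' made before the outcome now displayed. A lapse rate makes the agent
#' stochastic so that downstream logistic fits are non-degenerate.
#'
#' @param session A `credit_session` or trial table.
#' @param lapse Probability of a uniform-random choice on each trial.
#' @param seed Integer seed.
#' @return Completed trial table.
#' @export
simulate_rule_agent <- function(session, lapse = 0.1, seed = 1L) {
  trials <- if (inherits(session, "credit_session")) session$trials
  else session
  n <- nrow(trials)
  ch <- shown <- rep(NA_character_, n)
  with_seed(seed, {
    for (t in seq_len(n)) {
      prev_disp <- if (t > 1 &&
                       trials$run[t - 1] == trials$run[t] &&
                       trials$condition[t - 1] == trials$condition[t])
        t - 1 else NA_integer_
      want <- if (trials$m_O1[t] > trials$m_O2[t]) "O1" else "O2"
      base <- if (!is.na(prev_disp) && !is.na(shown[prev_disp])) {
        ct <- if (trials$condition[prev_disp] == "direct") prev_disp
        else trials$causal_choice_trial[prev_disp]
        if (!is.na(ct) && !is.na(ch[ct])) {
          if (shown[prev_disp] == want) ch[ct]
          else setdiff(c("S1", "S2"), ch[ct])
        } else NA_character_
      } else NA_character_
      ch[t] <- if (is.na(base) || runif(1) < lapse)
        sample(c("S1", "S2"), 1) else base
      ct <- if (trials$condition[t] == "direct") t
      else trials$causal_choice_trial[t]
      shown[t] <- if (!is.na(ct) && !is.na(ch[ct])) {
        if (ch[ct] == "S1") trials$outcome_S1[ct] else trials$outcome_S2[ct]
      } else {
        if (runif(1) < 0.5) trials$outcome_S1[t] else trials$outcome_S2[t]
      }
    }
  })
  trials$choice <- ch
  trials$outcome_shown <- shown
  trials
}
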