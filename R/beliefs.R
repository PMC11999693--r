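#' Belief-grid specification for the Bayesian volatility learner
#'
#' The learner maintains, per shape, a joint density over the transition
#' probability p (that the shape leads to outcome O1), the log-volatility v
#' (how quickly p is believed to change; the transition kernel for p has
#' concentration `exp(-v)`, so larger v means faster change), and the
#' volatility-change scale k (variance of the Gaussian random walk on v).
#' All belief computations are numerical grid integrations over this lattice.
#'
#' Defaults: 50 midpoints of (0, 1) for p; 30 uniform points in \[-8, 2\] for
#' v; 14 log-spaced points in \[e^-5, e^0.5\] for k.
#'
#' @param n_p,n_v,n_k Grid sizes (each at least 2).
#' @param v_range Range of the v grid.
#' @param k_range Range of the k grid (positive; points log-spaced).
#' @param freeze_dynamics If `TRUE`, the v- and p-diffusion steps are
#'   disabled, reducing the learner to a static Beta-Bernoulli estimator
#'   (used for oracle checks).
#' @return A named list of class `belief_grid_spec`.
#' @export
belief_grid_spec <- function(n_p = 50, n_v = 30, n_k = 14,
                             v_range = c(-8, 2),
                             k_range = c(exp(-5), exp(0.5)),
                             freeze_dynamics = FALSE) {
  if (n_p < 2 || n_v < 2 || n_k < 2) stop_arg("grid sizes must be >= 2")
  if (k_range[1] <= 0 || diff(k_range) <= 0 || diff(v_range) <= 0)
    stop_arg("invalid axis bounds")
  spec <- list(p = (seq_len(n_p) - 0.5) / n_p,
               v = seq(v_range[1], v_range[2], length.out = n_v),
               k = exp(seq(log(k_range[1]), log(k_range[2]),
                           length.out = n_k)),
               freeze_dynamics = freeze_dynamics)
  class(spec) <- "belief_grid_spec"
  spec
}

# Precompute row-stochastic transition kernels on the grid.
# Tv[[ik]] : n_v x n_v, row v_{t-1} -> col v_t, Gaussian with variance k.
# Tp[[iv]] : n_p x n_p, row p_{t-1} -> col p_t, Beta(mu*s, (1-mu)*s) with
#            concentration s = exp(-v_t); one kernel per *new* v index.
belief_kernels <- function(spec) {
  if (spec$freeze_dynamics) return(list(frozen = TRUE))
  nv <- length(spec$v); np <- length(spec$p)
  Tv <- lapply(spec$k, function(k) {
    M <- outer(spec$v, spec$v, function(a, b) dnorm(b, a, sqrt(k)))
    M / rowSums(M)
  })
  Tp <- lapply(spec$v, function(v) {
    s <- exp(-v)
    M <- outer(spec$p, spec$p, function(mu, p) dbeta(p, mu * s, (1 - mu) * s))
    M / rowSums(M)
  })
  list(frozen = FALSE, Tv = Tv, Tp = Tp)
}

#' Initialize a uniform belief grid
#'
#' @param spec Grid specification from [belief_grid_spec()].
#' @param kernels Optional precomputed kernels (shared between the two
#'   shapes' grids); computed if missing.
#' @return An object of class `belief_grid`: the joint density (p x v x k
#'   array summing to 1) plus axes and kernels.
#' @export
init_belief_grid <- function(spec = belief_grid_spec(), kernels = NULL) {
  np <- length(spec$p); nv <- length(spec$v); nk <- length(spec$k)
  dens <- array(1 / (np * nv * nk), dim = c(np, nv, nk))
  if (is.null(kernels)) kernels <- belief_kernels(spec)
  out <- list(spec = spec, density = dens, kernels = kernels)
  class(out) <- "belief_grid"
  out
}

#' One belief update: diffusion then (optionally) Bernoulli likelihood
#'
#' Applies the learner's one-trial prediction step -- volatility diffusion
#' (Gaussian with variance k, per k-slice) followed by probability diffusion
#' (beta kernel with concentration `exp(-v_t)`) -- and then, unless
#' `predict_only`, multiplies in the Bernoulli likelihood of the observed
#' outcome (`p` for O1, `1 - p` for O2) and renormalizes. The prediction-only
#' variant is what the unchosen / non-causal shape receives each trial:
#' contingencies drift in real time whether or not they are sampled.
#'
#' @param grid A `belief_grid`.
#' @param y Observed outcome, `"O1"` or `"O2"`; ignored when `predict_only`.
#' @param predict_only Apply diffusion only.
#' @return The updated `belief_grid`.
#' @export
update_beliefs <- function(grid, y = NULL, predict_only = FALSE) {
  D <- grid$density
  kern <- grid$kernels
  if (!isTRUE(kern$frozen)) {
    nk <- length(grid$spec$k); nv <- length(grid$spec$v)
    for (ik in seq_len(nk)) D[, , ik] <- D[, , ik] %*% kern$Tv[[ik]]
    for (iv in seq_len(nv)) D[, iv, ] <- crossprod(kern$Tp[[iv]], D[, iv, ])
  }
  if (!predict_only) {
    if (!y %in% c("O1", "O2")) stop_arg("y must be 'O1' or 'O2'")
    lik <- if (y == "O1") grid$spec$p else 1 - grid$spec$p
    D <- D * lik
  }
  tot <- sum(D)
  if (!is.finite(tot) || tot <= 0)
    stop("belief update produced a non-normalizable posterior", call. = FALSE)
  grid$density <- D / tot
  grid
}

#' Posterior point estimate of the transition probability
#'
#' Marginalizes the joint density over v and k and returns the mean of the
#' resulting distribution over p.
#'
#' @param grid A `belief_grid`.
#' @return Scalar estimate in (0, 1).
#' @export
point_estimate <- function(grid) {
  marg <- apply(grid$density, 1, sum)
  sum(grid$spec$p * marg)
}
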