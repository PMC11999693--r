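#' Gaussian smoothing of a statistic volume
#'
#' Separable discrete Gaussian convolution with reflective boundary
#' handling at the volume faces, which preserves both constants and the
#' total sum. When a mask is supplied, out-of-mask voxels (and `NA`s) are
#' zeroed before smoothing and the result is re-masked. `fwhm = 0` returns
#' the input unchanged.
#'
#' @param vol 3-D numeric array.
#' @param fwhm Full width at half maximum of the kernel, in voxels.
#' @param mask Optional logical array.
#' @return Smoothed 3-D array (0 outside the mask).
#' @export
smooth_volume <- function(vol, fwhm, mask = NULL) {
  if (fwhm < 0) stop_arg("fwhm must be >= 0")
  if (fwhm == 0) return(vol)
  d <- dim(vol)
  f <- vol
  f[is.na(f)] <- 0
  if (!is.null(mask)) f[!mask] <- 0
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)

  reflect_idx <- function(idx, n) {
    # reflect about the half-sample boundary: ..., 2, 1 | 1, 2, ...
    idx <- ifelse(idx < 1, 1 - idx, idx)
    ifelse(idx > n, 2 * n + 1 - idx, idx)
  }
  conv_axis <- function(x, axis) {
    n <- d[axis]
    out <- array(0, d)
    for (o in -r:r) {
      src <- reflect_idx(seq_len(n) + o, n)
      idx <- switch(axis,
                    `1` = x[src, , , drop = FALSE],
                    `2` = x[, src, , drop = FALSE],
                    `3` = x[, , src, drop = FALSE])
      out <- out + w[o + r + 1] * idx
    }
    out
  }
  for (axis in 1:3) f <- conv_axis(f, axis)
  if (!is.null(mask)) f[!mask] <- 0
  f
}

#' Per-voxel one-sample t-test across subjects
#'
#' @param subject_vols List of 3-D arrays (one per subject) or a subjects x
#'   voxels matrix with a `dim` attribute supplied via `vol_dim`.
#' @param vol_dim Volume dimensions when a matrix is supplied.
#' @return 3-D t-statistic array (df = n - 1); voxels with zero variance or
#'   any missing subject value are `NA`.
#' @export
group_onesample_t <- function(subject_vols, vol_dim = NULL) {
  if (is.list(subject_vols)) {
    vol_dim <- dim(subject_vols[[1]])
    M <- do.call(rbind, lapply(subject_vols, as.vector))
  } else M <- subject_vols
  n <- nrow(M)
  if (n < 2) stop_arg("need at least 2 subjects")
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  t <- mu / (sdv / sqrt(n))
  t[!is.finite(t)] <- NA_real_
  array(t, vol_dim)
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H * dh` over thresholds h,
#' where `extent(h)` is the size of the suprathreshold cluster containing
#' the voxel. One-sided: non-positive statistics receive 0.
#'
#' @param stat 3-D statistic array (`NA` treated as 0).
#' @param H Height exponent (default 2).
#' @param E Extent exponent (default 0.5).
#' @param dh Threshold step; default `max(stat) / 100`.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return 3-D TFCE array.
#' @export
tfce_enhance <- function(stat, H = 2, E = 0.5, dh = NULL,
                         connectivity = 6) {
  if (!is.null(dh) && dh <= 0) stop_arg("dh must be positive")
  d <- dim(stat)
  s <- as.numeric(stat)
  s[is.na(s)] <- 0
  out <- .tfce_cpp(s, as.integer(d), H = H, E = E,
                   dh = if (is.null(dh)) 0 else dh,
                   connectivity = as.integer(connectivity))
  array(out, d)
}

#' TFCE permutation p-values within an ROI mask
#'
#' Sign-flip permutation test for the one-sample design: each permutation
#' flips the sign of every subject's map independently, recomputes the
#' group t-map and its TFCE enhancement within the ROI, and records the
#' maximum TFCE. Per-voxel p = (1 + #\{null maxima >= observed\}) /
#' (n_perm + 1), giving family-wise control by the max-statistic argument.
#'
#' @param subject_vols List of per-subject 3-D arrays.
#' @param roi_mask Logical array restricting the analysis.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed Integer seed.
#' @param H,E,dh,connectivity TFCE parameters.
#' @param fwhm Optional smoothing applied to each subject map first.
#' @return Object of class `group_stat`: list with `t` (3-D), `tfce`,
#'   `p_tfce` (NA outside the ROI), `n_perm`, `roi_mask`.
#' @export
tfce_permutation_pvalues <- function(subject_vols, roi_mask, n_perm = 5000,
                                     seed = 1L, H = 2, E = 0.5, dh = NULL,
                                     connectivity = 6, fwhm = 0) {
  if (!any(roi_mask)) stop_arg("empty ROI mask")
  if (n_perm < 100) stop_arg("n_perm must be >= 100")
  if (fwhm > 0)
    subject_vols <- lapply(subject_vols, smooth_volume, fwhm = fwhm)
  d <- dim(subject_vols[[1]])
  roi <- which(roi_mask)
  M <- do.call(rbind, lapply(subject_vols, function(v) as.vector(v)[roi]))
  M[is.na(M)] <- 0
  n <- nrow(M)

  tstat_vec <- function(X) {
    mu <- colMeans(X)
    s2 <- pmax(colSums(X * X) / n - mu^2, 0) * n / (n - 1)
    t <- mu / sqrt(s2 / n); t[!is.finite(t)] <- 0; t
  }
  to_vol <- function(v) { vol <- array(0, d); vol[roi] <- v; vol }
  t_obs <- tstat_vec(M)
  tfce_obs <- tfce_enhance(to_vol(t_obs), H, E, dh, connectivity)
  obs <- as.vector(tfce_obs)[roi]
  null_max <- numeric(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      tp <- tstat_vec(M * flips)
      null_max[p] <- max(as.vector(
        tfce_enhance(to_vol(tp), H, E, dh, connectivity))[roi])
    }
  })
  pvals <- vapply(obs, function(o) (1 + sum(null_max >= o)) / (n_perm + 1),
                  numeric(1))
  t_vol <- array(NA_real_, d); t_vol[roi] <- t_obs
  p_vol <- array(NA_real_, d); p_vol[roi] <- pvals
  out <- list(t = t_vol, tfce = tfce_obs, p_tfce = p_vol,
              null_max = null_max, n_perm = n_perm, roi_mask = roi_mask,
              df = n - 1)
  class(out) <- "group_stat"
  out
}

#' @export
print.group_stat <- function(x, ...) {
  roi <- which(x$roi_mask)
  cat(sprintf("Group TFCE stat (df = %d, %d permutations): peak t = %.2f, min pTFCE = %.4f\n",
              x$df, x$n_perm, max(x$t[roi], na.rm = TRUE),
              min(x$p_tfce[roi], na.rm = TRUE)))
  invisible(x)
}

#' Across-subject association between decoding and credit precision
#'
#' Per voxel, Pearson correlation across subjects between the decoding
#' value and the behavioral credit-precision score, converted to
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`; TFCE permutation correction
#' (subject scores shuffled) within the ROI mask.
#'
#' @param subject_vols List of per-subject decoding volumes.
#' @param scores Numeric vector of per-subject precision scores.
#' @param roi_mask Logical ROI array.
#' @param n_perm Score permutations.
#' @param seed Integer seed.
#' @param H,E,dh,connectivity TFCE parameters.
#' @return `group_stat`-like list with `t`, `tfce`, `p_tfce`, `r`.
#' @export
precision_decoding_association <- function(subject_vols, scores, roi_mask,
                                           n_perm = 1000, seed = 1L,
                                           H = 2, E = 0.5, dh = NULL,
                                           connectivity = 6) {
  n <- length(scores)
  if (length(subject_vols) != n) stop_arg("one map per subject required")
  if (sd(scores) < 1e-12) stop_arg("zero variance in precision scores")
  if (!any(roi_mask)) stop_arg("empty ROI mask")
  d <- dim(subject_vols[[1]])
  roi <- which(roi_mask)
  M <- do.call(rbind, lapply(subject_vols, function(v) as.vector(v)[roi]))
  M[is.na(M)] <- 0

  r_to_t <- function(r) r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-12))
  assoc_t <- function(sc) {
    r <- suppressWarnings(as.vector(cor(sc, M)))
    r[is.na(r)] <- 0
    r_to_t(r)
  }
  to_vol <- function(v) { vol <- array(0, d); vol[roi] <- v; vol }
  r_obs <- suppressWarnings(as.vector(cor(scores, M)))
  t_obs <- assoc_t(scores)
  tfce_obs <- tfce_enhance(to_vol(t_obs), H, E, dh, connectivity)
  obs <- as.vector(tfce_obs)[roi]
  null_max <- numeric(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      tp <- assoc_t(sample(scores))
      null_max[p] <- max(as.vector(
        tfce_enhance(to_vol(tp), H, E, dh, connectivity))[roi])
    }
  })
  pvals <- vapply(obs, function(o) (1 + sum(null_max >= o)) / (n_perm + 1),
                  numeric(1))
  t_vol <- array(NA_real_, d); t_vol[roi] <- t_obs
  r_vol <- array(NA_real_, d); r_vol[roi] <- r_obs
  p_vol <- array(NA_real_, d); p_vol[roi] <- pvals
  list(t = t_vol, r = r_vol, tfce = tfce_obs, p_tfce = p_vol,
       null_max = null_max, n_perm = n_perm, roi_mask = roi_mask)
}
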