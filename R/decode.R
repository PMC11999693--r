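#' Searchlight specification
#'
#' @param half_width Cube half-width in voxels (2 gives the 5x5x5 cube).
#' @param min_neighbors Minimum number of valid surrounding voxels for a
#'   centroid to be retained.
#' @return Named list of class `searchlight_spec`.
#' @export
searchlight_spec <- function(half_width = 2, min_neighbors = 10) {
  structure(list(half_width = half_width, min_neighbors = min_neighbors),
            class = "searchlight_spec")
}

#' Enumerate valid searchlight centroids
#'
#' A centroid is any in-mask voxel whose surrounding cube (side
#' `2 * half_width + 1`) contains at least `min_neighbors` other in-mask
#' voxels.
#'
#' @param mask Logical 3-D array (brain mask).
#' @param spec A [searchlight_spec()].
#' @param candidates Optional logical array or linear-index vector
#'   restricting the candidate centroids (e.g. an ROI mask, or a strided
#'   subsample).
#' @return List with `centroids` (volume linear indices), `neighbors`
#'   (list of in-mask volume linear indices per centroid, centroid
#'   included), `dim`, and `spec`. Warns if no centroid qualifies.
#' @export
searchlight_centroids <- function(mask, spec = searchlight_spec(),
                                  candidates = NULL) {
  if (!any(mask)) stop_arg("empty mask")
  d <- dim(mask)
  cand <- if (is.null(candidates)) which(mask)
  else if (is.logical(candidates)) which(candidates & mask)
  else intersect(candidates, which(mask))
  hw <- spec$half_width
  offs <- as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw))
  coords <- arrayInd(cand, d)
  centroids <- integer(0)
  neighbors <- list()
  for (i in seq_along(cand)) {
    xyz <- coords[i, ]
    nb <- sweep(offs, 2, xyz, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    lin <- lin[mask[lin]]
    if (length(lin) - 1 >= spec$min_neighbors) {
      centroids <- c(centroids, cand[i])
      neighbors[[length(neighbors) + 1]] <- lin
    }
  }
  if (length(centroids) == 0) warning("no valid centroids")
  list(centroids = centroids, neighbors = neighbors, dim = d, spec = spec)
}

# Select patterns of one phase (optionally one condition) and return the
# design pieces used by the decoders.
select_patterns <- function(pset, phase, condition = NULL) {
  info <- pset$info
  keep <- info$phase %in% phase & !is.na(info$label)
  if (!is.null(condition) && "condition" %in% names(info))
    keep <- keep & !is.na(info$condition) & info$condition %in% condition
  list(X = pset$patterns[keep, , drop = FALSE],
       labels = info$label[keep], runs = info$run[keep],
       trial = info$trial[keep], idx = which(keep))
}

# Map volume linear indices to pattern-matrix columns.
vol_to_col <- function(geometry) {
  v2c <- array(NA_integer_, geometry$dim)
  v2c[which(geometry$brain_mask)] <- seq_len(sum(geometry$brain_mask))
  v2c
}

# Row-wise z-scoring across the searchlight's voxels ("z-scoring the
# beta-values across voxels").
zscore_rows <- function(M) {
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowMeans((M - mu)^2), 1e-24))
  (M - mu) / sdv
}

#' Searchlight decoding with a permutation null
#'
#' For every searchlight: z-score each trial's values across the
#' searchlight's voxels, train a linear soft-margin SVM (cost 1) on all
#' runs but one, test on the held-out run, and average accuracy over the
#' leave-one-run-out folds. A voxel-specific null is built by re-running
#' with shuffled training labels `n_perm` times; the reported value is
#' accuracy minus the null mean.
#'
#' @param pset A `pattern_set`.
#' @param phase Phase to decode (`"feedback"`, `"interim_feedback"`).
#' @param condition Optional condition restriction (`"direct"` /
#'   `"indirect"`).
#' @param sl Output of [searchlight_centroids()]; computed over the brain
#'   mask if missing.
#' @param n_perm Number of training-label permutations for the null.
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `decoding_map`: data frame `map` with per-
#'   centroid `accuracy`, `null_mean`, `value`, plus `sl` and `dim`.
#' @export
decode_searchlight <- function(pset, phase = "feedback", condition = NULL,
                               sl = NULL, n_perm = 100, seed = 1L) {
  g <- pset$geometry
  if (is.null(sl)) sl <- searchlight_centroids(g$brain_mask)
  sel <- select_patterns(pset, phase, condition)
  if (length(unique(sel$runs)) < 2) stop_arg("need >= 2 runs for run-wise CV")
  v2c <- vol_to_col(g)
  y <- ifelse(sel$labels == sort(unique(sel$labels))[1], 1, -1)
  runs <- sel$runs
  nC <- length(sl$centroids)
  acc <- nullm <- rep(NA_real_, nC)
  with_seed(seed, {
    for (ci in seq_len(nC)) {
      cols <- v2c[sl$neighbors[[ci]]]
      Z <- zscore_rows(sel$X[, cols, drop = FALSE])
      fa <- fn <- c(); valid <- TRUE
      for (r in unique(runs)) {
        tr <- runs != r; te <- !tr
        if (length(unique(y[tr])) < 2 || !any(te)) { valid <- FALSE; break }
        res <- .svm_fold_cpp(cbind(Z[tr, , drop = FALSE], 1), y[tr],
                             cbind(Z[te, , drop = FALSE], 1), y[te],
                             C = 1, n_perm = n_perm)
        fa <- c(fa, res$accuracy)
        fn <- c(fn, mean(res$null_acc))
      }
      if (valid) { acc[ci] <- mean(fa); nullm[ci] <- mean(fn) }
    }
  })
  out <- list(map = data.frame(centroid = sl$centroids, accuracy = acc,
                               null_mean = nullm, value = acc - nullm),
              sl = sl, dim = g$dim, phase = phase, condition = condition)
  class(out) <- "decoding_map"
  out
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf("Decoding map: %d centroids, mean null-subtracted accuracy %.3f\n",
              nrow(x$map), mean(x$map$value, na.rm = TRUE)))
  invisible(x)
}

#' Convert a per-centroid map to a statistic volume
#'
#' @param dm A `decoding_map` (or any list with `map$centroid` and the
#'   requested column plus `dim`).
#' @param what Column of `map` to place in the volume.
#' @return 3-D array, `NA` outside the centroids.
#' @export
map_volume <- function(dm, what = "value") {
  vol <- array(NA_real_, dm$dim)
  vol[dm$map$centroid] <- dm$map[[what]]
  vol
}

#' Per-trial signed hyperplane distances per searchlight
#'
#' Distances are decision values divided by the weight-vector norm, signed
#' positive when the predicted label is correct and negative when
#' incorrect. Each trial's distance comes from the fold in which its run
#' was the test set.
#'
#' @inheritParams decode_searchlight
#' @return List with `dist` (trials x centroids matrix, rows in the order
#'   of the selected patterns), `trial` (trial ids), `labels`, `runs`,
#'   `centroids`.
#' @export
signed_distance_series <- function(pset, phase = "feedback",
                                   condition = NULL, sl = NULL) {
  g <- pset$geometry
  if (is.null(sl)) sl <- searchlight_centroids(g$brain_mask)
  sel <- select_patterns(pset, phase, condition)
  if (length(unique(sel$runs)) < 2) stop_arg("need >= 2 runs for run-wise CV")
  v2c <- vol_to_col(g)
  y <- ifelse(sel$labels == sort(unique(sel$labels))[1], 1, -1)
  runs <- sel$runs
  nC <- length(sl$centroids)
  D <- matrix(NA_real_, length(y), nC)
  for (ci in seq_len(nC)) {
    cols <- v2c[sl$neighbors[[ci]]]
    Z <- zscore_rows(sel$X[, cols, drop = FALSE])
    for (r in unique(runs)) {
      tr <- runs != r; te <- !tr
      if (length(unique(y[tr])) < 2 || !any(te)) next
      res <- .svm_fold_cpp(cbind(Z[tr, , drop = FALSE], 1), y[tr],
                           cbind(Z[te, , drop = FALSE], 1), y[te],
                           C = 1, n_perm = 0)
      wn <- max(res$w_norm, 1e-12)
      D[te, ci] <- y[te] * res$decision / wn
    }
  }
  list(dist = D, trial = sel$trial, labels = sel$labels, runs = runs,
       centroids = sl$centroids)
}

#' Seed region trial series of signed distances
#'
#' Mean signed distance over the seed's searchlights per trial, computed
#' on the interim-feedback phase (pending-choice labels).
#'
#' @param pset A `pattern_set`.
#' @param seed_mask Logical array selecting seed voxels, or a numeric
#'   t-statistic volume to be thresholded.
#' @param threshold Threshold applied when `seed_mask` is numeric
#'   (default 2.54, i.e. p < 0.01 at 19 df).
#' @param spec Searchlight specification.
#' @param phase Phase from which the series is computed.
#' @return List with `series` (per-trial mean signed distance), `trial`,
#'   `n_seed` (number of seed searchlights).
#' @export
seed_distance_series <- function(pset, seed_mask, threshold = 2.54,
                                 spec = searchlight_spec(),
                                 phase = "interim_feedback") {
  g <- pset$geometry
  if (is.numeric(seed_mask) && !is.logical(seed_mask))
    seed_mask <- !is.na(seed_mask) & seed_mask >= threshold
  if (!any(seed_mask)) stop_arg("empty seed")
  sl <- searchlight_centroids(g$brain_mask, spec, candidates = seed_mask)
  if (length(sl$centroids) == 0) stop_arg("empty seed")
  ds <- signed_distance_series(pset, phase = phase, sl = sl)
  list(series = rowMeans(ds$dist), trial = ds$trial, runs = ds$runs,
       labels = ds$labels, n_seed = length(sl$centroids))
}

#' Information connectivity between a seed series and target searchlights
#'
#' Correlates the fidelity (signed distance) of the pending-choice
#' representation at the interim feedback of trial t with the fidelity of
#' the same causal choice's representation at the next trial's feedback,
#' per target searchlight; correlations are Fisher-z transformed (r
#' clipped to +/-(1 - 1e-7)). Pairs are aligned by causal-choice trial,
#' which automatically drops pairs crossing block boundaries.
#'
#' @param pset A `pattern_set`.
#' @param seed_mask Seed voxels (logical array or thresholdable t volume).
#' @param sl Target searchlights (defaults to the whole brain mask).
#' @param spec Searchlight specification for the seed.
#' @return Object of class `ic_map`: data frame `map` with per-centroid
#'   `r` and Fisher `z`, plus `n_pairs`, `dim`.
#' @export
information_connectivity <- function(pset, seed_mask, sl = NULL,
                                     spec = searchlight_spec()) {
  g <- pset$geometry
  if (is.null(sl)) sl <- searchlight_centroids(g$brain_mask)
  seed <- seed_distance_series(pset, seed_mask, spec = spec)
  targ <- signed_distance_series(pset, phase = "feedback",
                                 condition = "indirect", sl = sl)
  m <- match(seed$trial, targ$trial)
  ok <- !is.na(m)
  if (sum(ok) < 3) stop_arg("fewer than 3 aligned trial pairs")
  s <- seed$series[ok]
  Td <- targ$dist[m[ok], , drop = FALSE]
  # center both series within CV fold x class: the runs' classifiers
  # differ in overall fidelity, and training-class imbalance biases every
  # region's classifier in the same direction relative to the shared label
  # sequence -- pooling uncentered series would turn both shared effects
  # into spurious seed-target correlation under an uncoupled null
  grp <- interaction(seed$runs[ok], seed$labels[ok], drop = TRUE)
  for (gi in levels(grp)) {
    idx <- grp == gi
    s[idx] <- s[idx] - mean(s[idx])
    Td[idx, ] <- sweep(Td[idx, , drop = FALSE], 2,
                       colMeans(Td[idx, , drop = FALSE]))
  }
  r <- suppressWarnings(as.vector(cor(s, Td)))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  out <- list(map = data.frame(centroid = sl$centroids, r = r,
                               value = atanh(r)),
              n_pairs = sum(ok), sl = sl, dim = g$dim)
  class(out) <- c("ic_map", "decoding_map")
  out
}

#' Control analyses for information connectivity
#'
#' `conditional_accuracy`: per target searchlight, the proportion of
#' correct classifications among trials where the seed classified
#' correctly, minus the mean over `baseline_perms` random equal-size trial
#' draws. `conditional_refit`: the classifier is retrained and retested
#' using only seed-correct trials, and its accuracy is compared to a
#' shuffled-training-label baseline.
#'
#' @param pset A `pattern_set`.
#' @param seed_mask Seed voxels.
#' @param mode `"conditional_accuracy"` or `"conditional_refit"`.
#' @param sl Target searchlights.
#' @param spec Seed searchlight specification.
#' @param baseline_perms Random draws / label shuffles for the baseline
#'   (must be positive).
#' @param seed Integer seed.
#' @return `decoding_map`-like object with per-centroid `value`.
#' @export
ic_control <- function(pset, seed_mask,
                       mode = c("conditional_accuracy", "conditional_refit"),
                       sl = NULL, spec = searchlight_spec(),
                       baseline_perms = 1000, seed = 1L) {
  mode <- match.arg(mode)
  if (baseline_perms < 1) stop_arg("baseline_perms must be positive")
  g <- pset$geometry
  if (is.null(sl)) sl <- searchlight_centroids(g$brain_mask)
  sseed <- seed_distance_series(pset, seed_mask, spec = spec)
  targ <- signed_distance_series(pset, phase = "feedback",
                                 condition = "indirect", sl = sl)
  m <- match(sseed$trial, targ$trial)
  ok <- !is.na(m)
  seed_correct <- sseed$series[ok] > 0
  if (sum(seed_correct) < 6) stop_arg("fewer than 6 seed-correct trials")
  rows <- m[ok]
  nC <- length(sl$centroids)
  val <- rep(NA_real_, nC)
  with_seed(seed, {
    if (mode == "conditional_accuracy") {
      Td <- targ$dist[rows, , drop = FALSE] > 0
      nsub <- sum(seed_correct)
      draws <- replicate(baseline_perms, sample(nrow(Td), nsub))
      for (ci in seq_len(nC)) {
        obs <- mean(Td[seed_correct, ci])
        base <- mean(Td[as.vector(draws), ci])
        val[ci] <- obs - base
      }
    } else {
      keep_trials <- targ$trial %in% sseed$trial[ok][seed_correct]
      v2c <- vol_to_col(g)
      sel <- select_patterns(pset, "feedback", "indirect")
      y <- ifelse(targ$labels == sort(unique(targ$labels))[1], 1, -1)
      runs <- targ$runs
      for (ci in seq_len(nC)) {
        cols <- v2c[sl$neighbors[[ci]]]
        Z <- zscore_rows(sel$X[, cols, drop = FALSE])
        fa <- fn <- c()
        for (r in unique(runs)) {
          tr <- runs != r & keep_trials; te <- runs == r & keep_trials
          if (length(unique(y[tr])) < 2 || !any(te)) next
          res <- .svm_fold_cpp(cbind(Z[tr, , drop = FALSE], 1), y[tr],
                               cbind(Z[te, , drop = FALSE], 1), y[te],
                               C = 1, n_perm = baseline_perms)
          fa <- c(fa, res$accuracy); fn <- c(fn, mean(res$null_acc))
        }
        if (length(fa)) val[ci] <- mean(fa) - mean(fn)
      }
    }
  })
  out <- list(map = data.frame(centroid = sl$centroids, value = val),
              mode = mode, sl = sl, dim = g$dim)
  class(out) <- "decoding_map"
  out
}

#' Template-to-feedback cross-decoding of stimulus identity
#'
#' Trains on all template-phase patterns (all runs) and tests on
#' feedback-phase patterns labeled by the causal stimulus identity, with a
#' training-label permutation null as in [decode_searchlight()].
#'
#' @param pset A `pattern_set`.
#' @param condition Optional condition restriction for the test trials;
#'   `NULL` pools both conditions.
#' @param sl Searchlights.
#' @param n_perm Training-label permutations for the null.
#' @param seed Integer seed.
#' @return A `decoding_map` (accuracy minus null mean per centroid).
#' @export
template_cross_decode <- function(pset, condition = NULL, sl = NULL,
                                  n_perm = 100, seed = 1L) {
  g <- pset$geometry
  if (is.null(sl)) sl <- searchlight_centroids(g$brain_mask)
  tr_sel <- select_patterns(pset, "template")
  te_sel <- select_patterns(pset, "feedback", condition)
  v2c <- vol_to_col(g)
  lev <- sort(unique(tr_sel$labels))
  ytr <- ifelse(tr_sel$labels == lev[1], 1, -1)
  yte <- ifelse(te_sel$labels == lev[1], 1, -1)
  nC <- length(sl$centroids)
  acc <- nullm <- rep(NA_real_, nC)
  with_seed(seed, {
    for (ci in seq_len(nC)) {
      cols <- v2c[sl$neighbors[[ci]]]
      Ztr <- zscore_rows(tr_sel$X[, cols, drop = FALSE])
      Zte <- zscore_rows(te_sel$X[, cols, drop = FALSE])
      res <- .svm_fold_cpp(cbind(Ztr, 1), ytr, cbind(Zte, 1), yte,
                           C = 1, n_perm = n_perm)
      acc[ci] <- res$accuracy
      nullm[ci] <- if (n_perm > 0) mean(res$null_acc) else 0
    }
  })
  out <- list(map = data.frame(centroid = sl$centroids, accuracy = acc,
                               null_mean = nullm, value = acc - nullm),
              sl = sl, dim = g$dim, phase = "template->feedback",
              condition = condition)
  class(out) <- "decoding_map"
  out
}
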