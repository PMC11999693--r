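sig_fixture <- function() {
  get_fixture("decode_sig", function() {
    cc <- quick_cohort_config(amplitude = 3, seed = 5)
    g <- make_geometry(cc$dim, cc$roi_dim, seed = 1)
    sess <- build_session(cc$session, seed = 11)
    sim <- simulate_agent(sess, "bayes", params = cc$agent_params,
                          grid_spec = small_grid(), seed = 12)
    list(pset = generate_subject(sim$trials, sess$layout, g, cc, seed = 5),
         geometry = g)
  })
}

test_that("centroid enumeration matches brute-force neighbor counting", {
  mask <- array(TRUE, c(10, 10, 10))
  sl <- searchlight_centroids(mask)
  expect_equal(length(sl$centroids), 1000)

  single <- array(FALSE, c(10, 10, 10)); single[5, 5, 5] <- TRUE
  expect_warning(sl1 <- searchlight_centroids(single), "no valid centroids")
  expect_length(sl1$centroids, 0)

  set.seed(4)
  rmask <- array(runif(8 * 8 * 8) < 0.3, c(8, 8, 8))
  sl2 <- searchlight_centroids(rmask)
  # oracle: exhaustive enumeration over all offsets
  expected <- integer(0)
  for (v in which(rmask)) {
    xyz <- arrayInd(v, c(8, 8, 8))
    cnt <- -1  # exclude the centroid itself
    for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
      x <- xyz[1] + dx; y <- xyz[2] + dy; z <- xyz[3] + dz
      if (x >= 1 && x <= 8 && y >= 1 && y <= 8 && z >= 1 && z <= 8 &&
          rmask[x, y, z]) cnt <- cnt + 1
    }
    if (cnt >= 10) expected <- c(expected, v)
  }
  expect_identical(sl2$centroids, expected)
  expect_error(searchlight_centroids(array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("compiled svm agrees with libsvm on common test data", {
  skip_if_not_installed("e1071")
  set.seed(10)
  n <- 60; d <- 20
  X <- rbind(matrix(rnorm(n / 2 * d, 1.0), n / 2, d),
             matrix(rnorm(n / 2 * d, -1.0), n / 2, d))
  y <- rep(c(1, -1), each = n / 2)
  Xte <- rbind(matrix(rnorm(20 * d, 1.0), 20, d),
               matrix(rnorm(20 * d, -1.0), 20, d))
  yte <- rep(c(1, -1), each = 20)
  res <- creditlearn:::.svm_fold_cpp(cbind(X, 1), y, cbind(Xte, 1), yte,
                                     C = 1, n_perm = 0)
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  pred <- as.numeric(as.character(predict(ref, Xte)))
  ref_acc <- mean(pred == yte)
  expect_lt(abs(res$accuracy - ref_acc), 0.051)
  dec <- attr(predict(ref, Xte, decision.values = TRUE), "decision.values")
  # decision-value orientation is arbitrary in libsvm; compare magnitudes
  expect_gt(abs(cor(as.vector(dec), res$decision)), 0.98)
})

test_that("a point on the hyperplane has zero signed distance", {
  Xtr <- cbind(c(1, -1, 2, -2), 0, 1)
  ytr <- c(1, -1, 1, -1)
  Xte <- cbind(0, 0, 1)
  res <- creditlearn:::.svm_fold_cpp(Xtr, ytr, Xte, 1, C = 1, n_perm = 0)
  expect_lt(abs(res$decision), 1e-6)
})

test_that("searchlight decode equals a brute-force single-cube classifier", {
  fx <- sig_fixture()
  g <- fx$geometry
  centroid <- which(g$rois$lOFC)[30]
  sl <- searchlight_centroids(g$brain_mask,
                              candidates = centroid)
  dm <- decode_searchlight(fx$pset, "feedback", "direct", sl = sl,
                           n_perm = 20, seed = 99)
  # brute force: same voxels, same folds, same z-scoring, same RNG stream
  sel <- creditlearn:::select_patterns(fx$pset, "feedback", "direct")
  v2c <- creditlearn:::vol_to_col(g)
  cols <- v2c[sl$neighbors[[1]]]
  Z <- creditlearn:::zscore_rows(sel$X[, cols])
  y <- ifelse(sel$labels == "S1", 1, -1)
  accs <- nulls <- c()
  set.seed(99)
  for (r in unique(sel$runs)) {
    tr <- sel$runs != r
    res <- creditlearn:::.svm_fold_cpp(cbind(Z[tr, ], 1), y[tr],
                                       cbind(Z[!tr, ], 1), y[!tr],
                                       C = 1, n_perm = 20)
    accs <- c(accs, res$accuracy); nulls <- c(nulls, mean(res$null_acc))
  }
  expect_equal(dm$map$accuracy, mean(accs), tolerance = 1e-12)
  expect_equal(dm$map$null_mean, mean(nulls), tolerance = 1e-12)
})

test_that("near-noiseless signal decodes perfectly inside its ROI", {
  cc <- quick_cohort_config(amplitude = 1, noise_sd = 1e-4, seed = 6)
  g <- make_geometry(cc$dim, cc$roi_dim, seed = 1)
  sess <- build_session(cc$session, seed = 11)
  sim <- simulate_agent(sess, "bayes", params = cc$agent_params,
                        grid_spec = small_grid(), seed = 12)
  ps <- generate_subject(sim$trials, sess$layout, g, cc, seed = 7)
  some <- which(g$rois$lOFC)[c(22, 30, 41)]
  sl <- searchlight_centroids(g$brain_mask, candidates = some)
  dm <- decode_searchlight(ps, "feedback", "direct", sl = sl, n_perm = 5,
                           seed = 2)
  expect_true(all(dm$map$accuracy == 1))
})

test_that("signed distances carry the correctness sign convention", {
  fx <- sig_fixture()
  g <- fx$geometry
  some <- which(g$rois$lOFC)[c(22, 30)]
  sl <- searchlight_centroids(g$brain_mask, candidates = some)
  ds <- signed_distance_series(fx$pset, "feedback", "direct", sl = sl)
  dm <- decode_searchlight(fx$pset, "feedback", "direct", sl = sl,
                           n_perm = 0, seed = 1)
  for (ci in 1:2) {
    # fraction of positive distances equals the accuracy
    expect_equal(mean(ds$dist[, ci] > 0), dm$map$accuracy[ci],
                 tolerance = 1e-10)
    expect_equal(sign(mean(ds$dist[, ci] > 0) - 0.5 + 1e-12),
                 sign(2 * dm$map$accuracy[ci] - 1 + 1e-12))
  }
})

test_that("seed series reduces to the single-searchlight case", {
  fx <- sig_fixture()
  g <- fx$geometry
  one <- which(g$rois$lFPC)[30]
  mask1 <- array(FALSE, g$dim); mask1[one] <- TRUE
  s1 <- seed_distance_series(fx$pset, mask1)
  sl <- searchlight_centroids(g$brain_mask, candidates = one)
  ref <- signed_distance_series(fx$pset, "interim_feedback", sl = sl)
  expect_equal(s1$series, as.vector(ref$dist), tolerance = 1e-12)
  expect_equal(s1$n_seed, 1)

  # thresholded numeric map with nothing above threshold errors
  tmap <- array(0, g$dim)
  expect_error(seed_distance_series(fx$pset, tmap), "empty seed")
})

mid_cohort_config <- function(...) {
  # slightly larger volume than the quick geometry so that ROI searchlights
  # are not dominated by edge clipping
  cohort_config(dim = c(14, 14, 10), roi_dim = c(4, 4, 4),
                session = quick_session_config(), ...)
}

test_that("information connectivity recovers coupling and respects edges", {
  cc0 <- mid_cohort_config(amplitude = 8, rho = 0, n_subjects = 4, seed = 9)
  coh0 <- generate_cohort(cc0)
  g <- coh0$geometry
  targets <- searchlight_centroids(g$brain_mask,
                                   candidates = g$rois$lOFC | g$rois$HC)
  z0 <- vapply(coh0$subjects, function(s)
    mean(information_connectivity(s$patterns, g$rois$lFPC,
                                  sl = targets)$map$value), numeric(1))
  # per-subject searchlight-mean z has sd ~0.08 under the null, so a
  # 4-subject mean is checked at 3 standard errors
  expect_lt(abs(mean(z0)), 0.12)

  cc8 <- mid_cohort_config(amplitude = 8, rho = 0.8, n_subjects = 4,
                           seed = 9)
  coh8 <- generate_cohort(cc8)
  r8 <- vapply(coh8$subjects, function(s)
    mean(information_connectivity(s$patterns, g$rois$lFPC,
                                  sl = targets)$map$r), numeric(1))
  # high-fidelity regime: recovered correlation lands in the attenuation
  # band [0.4 * rho, rho]
  expect_gte(mean(r8), 0.4 * 0.8)
  expect_lte(mean(r8), 0.8)
})

test_that("ic controls detect coupling and stay null without it", {
  # The conditional-accuracy enrichment is a small sign-level effect, so it
  # is tested as a paired contrast: two cohorts sharing seed (identical
  # noise and pending-phase latents) differing only in the coupling.
  run_ca <- function(rho) {
    cc <- mid_cohort_config(amplitude = 3, rho = rho, n_subjects = 6,
                            seed = 31)
    coh <- generate_cohort(cc)
    g <- coh$geometry
    sl <- searchlight_centroids(g$brain_mask,
                                candidates = g$rois$lOFC | g$rois$HC)
    list(coh = coh, g = g, sl = sl,
         ca = vapply(coh$subjects, function(s)
           mean(ic_control(s$patterns, g$rois$lFPC, "conditional_accuracy",
                           sl = sl, baseline_perms = 300,
                           seed = 3)$map$value), numeric(1)))
  }
  hi <- run_ca(0.9)
  lo <- run_ca(0)
  expect_gt(mean(hi$ca), 0)
  expect_gt(mean(hi$ca - lo$ca), 0)
  expect_lt(abs(mean(lo$ca)), 0.02)

  # refit control: decodable on seed-correct trials when signal exists,
  # null when the amplitude is zero
  ps <- hi$coh$subjects[[1]]$patterns
  some <- which(hi$g$rois$lOFC)[c(22, 30, 41)]
  sl3 <- searchlight_centroids(hi$g$brain_mask, candidates = some)
  cr <- ic_control(ps, hi$g$rois$lFPC, "conditional_refit", sl = sl3,
                   baseline_perms = 30, seed = 3)
  expect_gt(mean(cr$map$value), 0.1)
  expect_error(ic_control(ps, hi$g$rois$lFPC, "conditional_accuracy",
                          sl = sl3, baseline_perms = 0), "positive")
})

test_that("template cross-decoding is specific to the shared identity code", {
  fx <- sig_fixture()  # share = 1 in HC
  g <- fx$geometry
  hc <- which(g$rois$HC)[c(22, 30, 41)]
  lofc <- which(g$rois$lOFC)[c(22, 30, 41)]
  sl <- searchlight_centroids(g$brain_mask, candidates = c(hc, lofc))
  xd <- template_cross_decode(fx$pset, sl = sl, n_perm = 20, seed = 4)
  in_hc <- xd$map$centroid %in% hc
  expect_gt(mean(xd$map$value[in_hc]), 0.15)
  expect_lt(abs(mean(xd$map$value[!in_hc])), 0.12)

  # no sharing: no transfer anywhere
  cc <- quick_cohort_config(amplitude = 3, share = 0, seed = 5)
  sess <- build_session(cc$session, seed = 11)
  sim <- simulate_agent(sess, "bayes", params = cc$agent_params,
                        grid_spec = small_grid(), seed = 12)
  ps0 <- generate_subject(sim$trials, sess$layout, g, cc, seed = 5)
  xd0 <- template_cross_decode(ps0, sl = sl, n_perm = 20, seed = 4)
  expect_lt(abs(mean(xd0$map$value)), 0.12)

  # ceiling sanity: testing the classifier on its own training patterns
  tpl <- which(fx$pset$info$phase == "template")
  extra <- fx$pset$info[tpl, ]
  extra$phase <- "feedback"; extra$condition <- "direct"
  ps_ceiling <- structure(
    list(patterns = fx$pset$patterns[c(tpl, tpl), ],
         info = rbind(fx$pset$info[tpl, ], extra),
         geometry = fx$pset$geometry),
    class = "pattern_set")
  sl1 <- searchlight_centroids(g$brain_mask, candidates = hc[1])
  xc <- template_cross_decode(ps_ceiling, condition = "direct", sl = sl1,
                              n_perm = 0, seed = 1)
  expect_gt(xc$map$accuracy, 0.95)
})
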