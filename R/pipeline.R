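#' Default pipeline configuration
#'
#' A single configuration object driving every stage of the simulate ->
#' model -> decode -> infer pipeline. Every stochastic stage draws its seed
#' as a named substream of `seed`, so identical configs give identical
#' artifacts.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param cohort Cohort configuration overrides (named list merged into
#'   [cohort_config()]).
#' @param n_perm Decoding-null permutations.
#' @param group_n_perm Group-level TFCE permutations.
#' @param fit_model Learner model fitted in the `fit` stage.
#' @param ridge Ridge penalty for the credit regression.
#' @param quick If `TRUE`, desk-scale settings (small volume, reduced
#'   permutation counts).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 20, cohort = list(),
                            n_perm = 100, group_n_perm = 500,
                            fit_model = "bayes", ridge = 1,
                            quick = FALSE) {
  base <- cohort_config(n_subjects = n_subjects, seed = seed)
  if (quick) {
    base$dim <- c(14, 14, 10); base$roi_dim <- c(4, 4, 4)
    n_perm <- 25; group_n_perm <- 200
  }
  base <- modifyList(base, cohort)
  structure(list(seed = seed, cohort = base, n_perm = n_perm,
                 group_n_perm = group_n_perm, fit_model = fit_model,
                 ridge = ridge, quick = quick),
            class = "pipeline_config")
}

read_stage <- function(out_dir, stage) {
  f <- file.path(out_dir, stage, "artifacts.rds")
  if (!file.exists(f))
    stop(sprintf("stage '%s' artifacts not found; run the '%s' stage first",
                 stage, stage), call. = FALSE)
  readRDS(f)
}

#' Run one stage of the analysis pipeline
#'
#' Stages: `simulate` (sessions + behavior), `fit` (learner parameters),
#' `regress` (credit matrices, contrasts, precision), `neural` (synthetic
#' pattern cohort), `decode` (searchlight and information-connectivity
#' maps), `group` (TFCE-corrected group statistics), `all`. Each stage
#' writes TSV/JSON (and NIfTI for volumes) artifacts plus a manifest to
#' `out_dir/<stage>/`; downstream stages read their inputs from upstream
#' artifact directories and raise an actionable error if those are
#' missing.
#'
#' @param config A [pipeline_config()].
#' @param stage One of the stage names above.
#' @param out_dir Output directory.
#' @return Invisibly, the list of artifacts produced by the (last) stage.
#' @export
run_stage <- function(config = pipeline_config(),
                      stage = c("all", "simulate", "fit", "regress",
                                "neural", "decode", "group"),
                      out_dir = "creditlearn_out") {
  stage <- match.arg(stage)
  if (stage == "all") {
    for (s in c("simulate", "fit", "regress", "neural", "decode", "group"))
      res <- run_stage(config, s, out_dir)
    manifest <- list(stages = c("simulate", "fit", "regress", "neural",
                                "decode", "group"),
                     seed = config$seed, completed = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  dir <- file.path(out_dir, stage)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- config$cohort
  t0 <- Sys.time()
  art <- switch(stage,
    simulate = {
      subj <- list()
      for (s in seq_len(cc$n_subjects)) {
        ss <- child_seed(cc$seed, sprintf("subj%d", s))
        sess <- build_session(cc$session, seed = ss)
        sim <- simulate_agent(sess, model = cc$model,
                              params = cc$agent_params, policy = "sample",
                              grid_spec = cc$session$grid_spec,
                              seed = child_seed(ss, "agent"))
        write_tsv_events(sim$trials,
                         file.path(dir, sprintf("sub-%02d_trials.tsv", s)))
        write_tsv_events(sim$trace,
                         file.path(dir, sprintf("sub-%02d_trace.tsv", s)))
        subj[[s]] <- list(session = sess, sim = sim)
      }
      list(subjects = subj)
    },
    fit = {
      up <- read_stage(out_dir, "simulate")
      fits <- lapply(seq_along(up$subjects), function(s) {
        fit_learner(up$subjects[[s]]$sim$trials, model = config$fit_model,
                    seed = child_seed(config$seed, sprintf("fit%d", s)),
                    grid_spec = cc$session$grid_spec)
      })
      tab <- data.frame(subject = seq_along(fits),
                        t(vapply(fits, coef, coef(fits[[1]]))),
                        nll = vapply(fits, function(f) f$nll, numeric(1)))
      write_tsv_events(tab, file.path(dir, "learner_fits.tsv"))
      list(fits = fits, table = tab)
    },
    regress = {
      up <- read_stage(out_dir, "simulate")
      dmat <- lapply(up$subjects, function(s)
        participant_credit_matrix(s$sim$trials, "direct", config$ridge))
      imat <- lapply(up$subjects, function(s)
        participant_credit_matrix(s$sim$trials, "indirect", config$ridge))
      prec <- mapply(overall_credit_precision, dmat, imat)
      res <- list(direct = credit_contrasts(dmat, "direct"),
                  indirect = credit_contrasts(imat, "indirect"),
                  comparison = condition_comparison(dmat, imat))
      jsonlite::write_json(
        list(direct_t = res$direct$t, direct_p = res$direct$p,
             indirect_t = res$indirect$t, indirect_p = res$indirect$p,
             comparison_t = res$comparison$t,
             precision = prec),
        file.path(dir, "credit_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      list(direct_matrices = dmat, indirect_matrices = imat,
           precision = prec, contrasts = res)
    },
    neural = {
      up <- read_stage(out_dir, "simulate")
      geometry <- make_geometry(cc$dim, cc$roi_dim,
                                seed = child_seed(cc$seed, "geom"))
      psets <- lapply(seq_along(up$subjects), function(s) {
        ss <- child_seed(cc$seed, sprintf("subj%d", s))
        generate_subject(up$subjects[[s]]$sim$trials,
                         up$subjects[[s]]$session$layout, geometry, cc,
                         seed = child_seed(ss, "patterns"))
      })
      for (roi in names(geometry$rois))
        write_stat_volume(geometry$rois[[roi]] + 0,
                          file.path(dir, paste0("mask_", roi, ".nii.gz")))
      list(geometry = geometry, psets = psets)
    },
    decode = {
      up <- read_stage(out_dir, "neural")
      g <- up$geometry
      roi_all <- g$rois$lOFC | g$rois$HC | g$rois$lFPC
      sl <- searchlight_centroids(g$brain_mask, candidates = roi_all)
      maps <- lapply(seq_along(up$psets), function(s) {
        dm <- decode_searchlight(up$psets[[s]], "feedback", "direct",
                                 sl = sl, n_perm = config$n_perm,
                                 seed = child_seed(config$seed,
                                                   sprintf("dec%d", s)))
        ic <- information_connectivity(up$psets[[s]], g$rois$lFPC, sl = sl)
        list(decode = dm, ic = ic)
      })
      for (s in seq_along(maps))
        write_stat_volume(map_volume(maps[[s]]$decode),
                          file.path(dir, sprintf("sub-%02d_decode.nii.gz", s)))
      list(maps = maps, sl = sl)
    },
    group = {
      up <- read_stage(out_dir, "decode")
      upn <- read_stage(out_dir, "neural")
      g <- upn$geometry
      vols <- lapply(up$maps, function(m) {
        v <- map_volume(m$decode); v[is.na(v)] <- 0; v
      })
      roi <- g$rois$lOFC | g$rois$HC
      gs <- tfce_permutation_pvalues(vols, roi,
                                     n_perm = max(100, config$group_n_perm),
                                     seed = child_seed(config$seed, "group"))
      write_stat_volume(gs$t, file.path(dir, "group_t.nii.gz"))
      write_stat_volume(gs$p_tfce, file.path(dir, "group_pTFCE.nii.gz"))
      peak <- which.max(ifelse(is.na(gs$t), -Inf, gs$t))
      summary <- data.frame(peak_voxel = peak,
                            peak_t = max(gs$t, na.rm = TRUE),
                            p_tfce_at_peak = gs$p_tfce[peak],
                            n_sig = sum(gs$p_tfce < 0.05, na.rm = TRUE))
      write_tsv_events(summary, file.path(dir, "group_summary.tsv"))
      list(group = gs, summary = summary)
    })
  saveRDS(art, file.path(dir, "artifacts.rds"))
  manifest <- list(stage = stage, seed = config$seed,
                   quick = config$quick,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   outputs = list.files(dir),
                   package_version = as.character(
                     utils::packageVersion("creditlearn")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(art)
}
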