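#' Synthetic voxel geometry with three disjoint ROIs
#'
#' Builds a 3-D volume with a brain mask and three disjoint cuboid ROIs
#' standing in for lateral orbitofrontal cortex ("lOFC"), hippocampus
#' ("HC") and lateral frontopolar cortex ("lFPC"). Placement is
#' deterministic given the seed: candidate corners are shuffled and the
#' first non-overlapping, in-mask triple is taken.
#'
#' @param dim Volume dimensions, default `c(24, 24, 16)`.
#' @param roi_dim ROI cuboid dimensions, default `c(6, 6, 6)`.
#' @param seed Integer seed for placement.
#' @return Object of class `voxel_geometry`: list with `dim`, logical
#'   arrays `brain_mask` and `rois$lOFC` / `rois$HC` / `rois$lFPC`.
#' @export
make_geometry <- function(dim = c(24, 24, 16), roi_dim = c(6, 6, 6),
                          seed = 1L) {
  if (any(roi_dim > dim))
    stop_arg("ROI dimensions exceed the volume")
  brain <- array(TRUE, dim)
  corners <- with_seed(seed, {
    # lattice of candidate corners with one-voxel spacing of ROI size
    cand <- expand.grid(
      x = seq(1, dim[1] - roi_dim[1] + 1, by = roi_dim[1] + 1),
      y = seq(1, dim[2] - roi_dim[2] + 1, by = roi_dim[2] + 1),
      z = seq(1, dim[3] - roi_dim[3] + 1, by = roi_dim[3] + 1))
    if (nrow(cand) < 3) stop_arg("ROIs do not fit the volume")
    cand[sample(nrow(cand), 3), ]
  })
  roi_names <- c("lOFC", "HC", "lFPC")
  rois <- list()
  for (k in 1:3) {
    m <- array(FALSE, dim)
    cx <- corners$x[k]; cy <- corners$y[k]; cz <- corners$z[k]
    m[cx:(cx + roi_dim[1] - 1), cy:(cy + roi_dim[2] - 1),
      cz:(cz + roi_dim[3] - 1)] <- TRUE
    rois[[roi_names[k]]] <- m
  }
  if (sum(rois$lOFC & rois$HC) + sum(rois$lOFC & rois$lFPC) +
      sum(rois$HC & rois$lFPC) > 0)
    stop_arg("ROI placement overlap")  # cannot happen on the lattice
  out <- list(dim = dim, brain_mask = brain, rois = rois)
  class(out) <- "voxel_geometry"
  out
}

#' Cohort configuration for the synthetic neural data generator
#'
#' @param n_subjects Number of simulated participants. Default 20.
#' @param amplitude Signal amplitude A of the class prototypes.
#' @param noise_sd Additive i.i.d. Gaussian noise sd per voxel.
#' @param rho Fidelity coupling in \[-1, 1\] between the pending-choice
#'   latent f and the subsequent credit-assignment latent g.
#' @param share Template-to-feedback identity-code sharing in "HC"
#'   (1 = identical prototypes, 0 = independent).
#' @param smooth_fwhm Optional Gaussian spatial smoothing of the generated
#'   patterns, FWHM in voxels (0 = none).
#' @param dim,roi_dim Geometry dimensions (see [make_geometry()]).
#' @param agent_params,model Behavioral generator (see [simulate_agent()]).
#' @param session Session configuration (see [session_config()]).
#' @param seed Master seed.
#' @return Named list.
#' @export
cohort_config <- function(n_subjects = 20, amplitude = 3, noise_sd = 1,
                          rho = 0.6, share = 1, smooth_fwhm = 0,
                          dim = c(24, 24, 16), roi_dim = c(6, 6, 6),
                          agent_params = list(alpha = 1, b = 0.3),
                          model = "bayes",
                          session = session_config(), seed = 1L) {
  if (noise_sd <= 0) stop_arg("noise_sd must be positive")
  if (abs(rho) > 1) stop_arg("|rho| must be <= 1")
  list(n_subjects = n_subjects, amplitude = amplitude, noise_sd = noise_sd,
       rho = rho, share = share, smooth_fwhm = smooth_fwhm, dim = dim,
       roi_dim = roi_dim, agent_params = agent_params, model = model,
       session = session, seed = seed)
}

# Coupled latent fidelity pair: f ~ N(0,1), g = rho*f + sqrt(1-rho^2)*eps.
latent_pair <- function(n, rho) {
  f <- rnorm(n)
  g <- rho * f + sqrt(1 - rho^2) * rnorm(n)
  cbind(f = f, g = g)
}

unit_vec <- function(n) { v <- rnorm(n); v / sqrt(sum(v^2)) }

#' Generate one subject's trial-by-voxel pattern set
#'
#' Patterns are generated directly at the trial-beta level. Class
#' prototypes are unit-norm Gaussian vectors per (ROI, label, phase
#' family). Embedded structure:
#' \itemize{
#' \item direct-block feedback patterns carry the causal-choice prototype
#'   in "lOFC" and "HC" at amplitude A;
#' \item indirect-block interim-feedback patterns carry the pending-choice
#'   prototype in "lFPC" at amplitude `A * (1 + 0.5 * tanh(f_t))` with
#'   `f_t ~ N(0, 1)`;
#' \item the next feedback's causal-choice prototype in "lOFC"/"HC" has
#'   amplitude `A * (1 + 0.5 * tanh(g_t))`, `g_t = rho * f_t +
#'   sqrt(1 - rho^2) * eps_t`, so `rho` directly parameterizes the
#'   information-connectivity effect;
#' \item template patterns carry stimulus-identity prototypes; in "HC" the
#'   feedback-phase identity prototype is shared with the template
#'   prototype (degree set by `share`), enabling cross-decoding;
#' \item i.i.d. Gaussian noise everywhere, optional spatial smoothing.
#' }
#'
#' @param behavior Completed trial table (with choices and linkage).
#' @param layout Template-block layout table (see [build_session()]).
#' @param geometry A `voxel_geometry`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject.
#' @return Object of class `pattern_set`: list with `patterns` (trials x
#'   voxels matrix over in-mask voxels), `info` (per-pattern phase, run,
#'   label, trial, latent `f`/`g`), `geometry`.
#' @export
generate_subject <- function(behavior, layout, geometry, config, seed = 1L) {
  if (!all(c("choice", "causal_choice_trial") %in% names(behavior)) ||
      all(is.na(behavior$choice)))
    stop_arg("behavior must be a completed trial table with causal linkage")
  vox_idx <- which(geometry$brain_mask)
  nv <- length(vox_idx)
  roi_cols <- lapply(geometry$rois, function(m) match(which(m), vox_idx))
  A <- config$amplitude

  with_seed(seed, {
    protos <- list()
    for (roi in names(roi_cols)) {
      nroi <- length(roi_cols[[roi]])
      for (lab in c("S1", "S2")) {
        protos[[paste(roi, lab, "template", sep = ".")]] <- unit_vec(nroi)
        protos[[paste(roi, lab, "feedback", sep = ".")]] <- unit_vec(nroi)
      }
    }
    # identity-code sharing in HC: feedback prototype is a unit-norm blend
    # of the template prototype (weight `share`) and an independent vector
    s <- config$share
    for (lab in c("S1", "S2")) {
      tpl <- protos[[paste("HC", lab, "template", sep = ".")]]
      ind <- protos[[paste("HC", lab, "feedback", sep = ".")]]
      blend <- s * tpl + sqrt(max(0, 1 - s^2)) * ind
      protos[[paste("HC", lab, "feedback", sep = ".")]] <-
        blend / sqrt(sum(blend^2))
    }

    info <- list(); rows <- list()
    add_row <- function(phase, run, label, trial, amp_rois, amp, f = NA,
                        g = NA, family = "feedback",
                        condition = NA_character_) {
      x <- rnorm(nv, 0, config$noise_sd)
      if (!is.na(label) && amp != 0) {
        for (roi in amp_rois) {
          pr <- protos[[paste(roi, label, family, sep = ".")]]
          x[roi_cols[[roi]]] <- x[roi_cols[[roi]]] + amp * pr
        }
      }
      rows[[length(rows) + 1]] <<- x
      info[[length(info) + 1]] <<- data.frame(
        phase = phase, condition = condition, run = run, label = label,
        trial = trial, f = f, g = g, stringsAsFactors = FALSE)
    }

    # template phases (shape presentations only)
    tpl <- layout[layout$stimulus %in% c("S1", "S2"), , drop = FALSE]
    for (i in seq_len(nrow(tpl)))
      add_row("template", tpl$run[i], tpl$stimulus[i], NA_integer_,
              c("lOFC", "HC", "lFPC"), A, family = "template")

    # learning phases
    n <- nrow(behavior)
    ind_idx <- which(behavior$condition == "indirect")
    lat <- latent_pair(n, config$rho)  # indexed by pending-choice trial
    for (t in seq_len(n)) {
      if (behavior$condition[t] == "direct") {
        add_row("feedback", behavior$run[t], behavior$choice[t], t,
                c("lOFC", "HC"), A, condition = "direct")
      } else {
        # interim feedback: pending choice made on this trial
        add_row("interim_feedback", behavior$run[t], behavior$choice[t], t,
                "lFPC", A * (1 + 0.5 * tanh(lat[t, "f"])), f = lat[t, "f"],
                condition = "indirect")
        # feedback for the causal choice of the previous trial
        ct <- behavior$causal_choice_trial[t]
        if (!is.na(ct)) {
          add_row("feedback", behavior$run[t], behavior$choice[ct], ct,
                  c("lOFC", "HC"), A * (1 + 0.5 * tanh(lat[ct, "g"])),
                  g = lat[ct, "g"], condition = "indirect")
        }
      }
    }
    patterns <- do.call(rbind, rows)
    info <- do.call(rbind, info)
    if (config$smooth_fwhm > 0) {
      for (i in seq_len(nrow(patterns))) {
        vol <- array(0, geometry$dim)
        vol[vox_idx] <- patterns[i, ]
        sm <- smooth_volume(vol, config$smooth_fwhm,
                            mask = geometry$brain_mask)
        patterns[i, ] <- sm[vox_idx]
      }
    }
    out <- list(patterns = patterns, info = info, geometry = geometry)
    class(out) <- "pattern_set"
    out
  })
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: %d patterns x %d voxels (%s)\n",
              nrow(x$patterns), ncol(x$patterns),
              paste(names(table(x$info$phase)),
                    table(x$info$phase), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic cohort of behavior and neural patterns
#'
#' Builds one session and one simulated agent per subject (independent
#' seeds derived from the master seed), then generates each subject's
#' pattern set with subject-specific prototypes.
#'
#' @param config A [cohort_config()].
#' @param geometry Optional shared `voxel_geometry`; built from the config
#'   if missing.
#' @return Object of class `credit_cohort`: list of subjects (each with
#'   `behavior`, `patterns`), plus `geometry` and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), geometry = NULL) {
  if (is.null(geometry))
    geometry <- make_geometry(config$dim, config$roi_dim,
                              seed = child_seed(config$seed, "geom"))
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ss <- child_seed(config$seed, sprintf("subj%d", s))
    sess <- build_session(config$session, seed = ss)
    sim <- simulate_agent(sess, model = config$model,
                          params = config$agent_params,
                          policy = "sample",
                          grid_spec = config$session$grid_spec,
                          seed = child_seed(ss, "agent"))
    pat <- generate_subject(sim$trials, sess$layout, geometry, config,
                            seed = child_seed(ss, "patterns"))
    subjects[[s]] <- list(behavior = sim$trials, trace = sim$trace,
                          patterns = pat, session = sess)
  }
  out <- list(subjects = subjects, geometry = geometry, config = config)
  class(out) <- "credit_cohort"
  out
}

#' @export
print.credit_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, volume %s, A = %g, sd = %g, rho = %g\n",
              length(x$subjects), paste(x$geometry$dim, collapse = "x"),
              x$config$amplitude, x$config$noise_sd, x$config$rho))
  invisible(x)
}

#' Export a pattern set as 4-D NIfTI plus a TSV label table
#'
#' @param pattern_set A `pattern_set`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_pattern_set <- function(pattern_set, dir, prefix = "patterns") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- pattern_set$geometry
  vox_idx <- which(g$brain_mask)
  n <- nrow(pattern_set$patterns)
  arr <- array(0, c(g$dim, n))
  for (i in seq_len(n)) {
    vol <- array(0, g$dim)
    vol[vox_idx] <- pattern_set$patterns[i, ]
    arr[, , , i] <- vol
  }
  RNifti::writeNifti(RNifti::asNifti(arr),
                     file.path(dir, paste0(prefix, ".nii.gz")))
  write_tsv_events(pattern_set$info,
                   file.path(dir, paste0(prefix, "_labels.tsv")))
  for (roi in names(g$rois))
    RNifti::writeNifti(RNifti::asNifti(g$rois[[roi]] + 0),
                       file.path(dir, paste0("mask_", roi, ".nii.gz")))
  invisible(dir)
}
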