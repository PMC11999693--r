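#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single master
#' seed through this deterministic map, so that stages are independently
#' reproducible and never share an RNG stream.
#'
#' @param seed Master integer seed.
#' @param key Character tag naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a data frame as a tab-separated event file
#'
#' Event tables (trial tables, learner traces, credit matrices) are serialized
#' as plain TSV with a header row, alongside an optional JSON sidecar of
#' generator parameters.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param sidecar Optional named list written to `<path stem>.json`.
#' @return `path`, invisibly.
#' @export
write_tsv_events <- function(x, path, sidecar = NULL) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar)) {
    jpath <- sub("\\.tsv$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(sidecar, jpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a tab-separated trial table
#'
#' Entry point for externally supplied behavior: a TSV with the columns
#' produced by [build_session()] (condition, run, magnitudes, choice, observed
#' outcome, causal linkage).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_trial_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a statistic volume as NIfTI
#'
#' @param vol 3-D numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stat_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Read per-trial pattern volumes from a 4-D NIfTI file
#'
#' Entry point for externally supplied trial-wise activity estimates: a 4-D
#' NIfTI (one volume per trial) plus a TSV label table with one row per trial.
#'
#' @param nifti_path 4-D NIfTI path.
#' @param labels_path TSV with per-trial `phase`, `run`, `label` columns.
#' @return A list with `patterns` (trials x voxels matrix), `info` (label
#'   table) and `dim` (volume dimensions).
#' @export
read_pattern_set <- function(nifti_path, labels_path) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  mat <- t(matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4]))
  info <- read.delim(labels_path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(nrow(info) == d[4])
  list(patterns = mat, info = info, dim = d[1:3])
}
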