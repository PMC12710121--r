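#' Construct a feature matrix
#'
#' Recordings-by-features numeric matrix with per-recording metadata, a
#' validity mask, a removal log and (after normalisation) the per-feature
#' min/max bounds.
#'
#' @param values Numeric matrix, one row per recording; rownames are
#'   recording keys; colnames are feature names.
#' @param meta Data frame with one row per recording (at least `key`,
#'   `patient_id`, `diagnosis`, `condition`).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, meta) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(meta))
    stop("values and meta row counts differ", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- meta$key
  if (is.null(colnames(values)))
    stop("feature columns must be named", call. = FALSE)
  structure(list(
    values = values, meta = meta, normalization = NULL,
    removed = data.frame(feature = character(0), reason = character(0))
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d recordings x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$normalization)) "raw scale" else "[0,1] normalized"))
  if (nrow(x$removed))
    cat("  removed:", paste(x$removed$feature, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Remove invalid feature columns
#'
#' Drops every feature column containing non-finite values (NaN/Inf/NA) or
#' with zero variance; the removal reason is logged on the returned object.
#'
#' @param fm A [feature_matrix()].
#' @return The filtered `feature_matrix`; surviving columns are all finite
#'   with positive variance.
#' @export
filter_invalid_features <- function(fm) {
  v <- fm$values
  reasons <- character(0); bad <- character(0)
  for (cn in colnames(v)) {
    col <- v[, cn]
    if (any(is.nan(col))) { bad <- c(bad, cn); reasons <- c(reasons, "NaN") }
    else if (any(is.infinite(col))) { bad <- c(bad, cn); reasons <- c(reasons, "Inf") }
    else if (anyNA(col)) { bad <- c(bad, cn); reasons <- c(reasons, "NA") }
    else if (var(col) == 0) { bad <- c(bad, cn); reasons <- c(reasons, "zero variance") }
  }
  if (length(bad)) {
    fm$values <- v[, setdiff(colnames(v), bad), drop = FALSE]
    fm$removed <- rbind(fm$removed,
                        data.frame(feature = bad, reason = reasons))
  }
  fm
}

#' Min-max normalise features to [0, 1]
#'
#' Each feature column is mapped through `(v - min) / (max - min)`. When
#' `bounds` is supplied (e.g. bounds learned on training folds), those are
#' reused, so held-out values can fall outside `[0, 1]`; they are retained
#' unclipped and flagged via the `out_of_bounds` attribute. Normalising an
#' already-normalised matrix with its own bounds is a no-op.
#'
#' @param fm A filtered [feature_matrix()].
#' @param bounds Optional list with numeric vectors `min` and `max` (named
#'   by feature) from a training fit.
#' @return The normalised `feature_matrix` with `normalization` recording
#'   the bounds used.
#' @export
minmax_normalize_features <- function(fm, bounds = NULL) {
  v <- fm$values
  if (is.null(bounds)) {
    bounds <- list(min = apply(v, 2, min), max = apply(v, 2, max))
    if (any(bounds$max == bounds$min))
      stop("constant feature column; run filter_invalid_features() first",
           call. = FALSE)
  }
  oob <- rep(FALSE, ncol(v)); names(oob) <- colnames(v)
  for (cn in colnames(v)) {
    lo <- bounds$min[[cn]]; hi <- bounds$max[[cn]]
    if (is.null(lo) || is.null(hi))
      stop("no normalization bounds for feature ", cn, call. = FALSE)
    v[, cn] <- (v[, cn] - lo) / (hi - lo)
    oob[cn] <- any(v[, cn] < 0 | v[, cn] > 1)
  }
  fm$values <- v
  fm$normalization <- bounds
  attr(fm, "out_of_bounds") <- oob
  fm
}

#' Merge an external feature table
#'
#' Attaches arbitrary externally computed features (e.g. a large
#' comparative time-series feature table) to a feature matrix by recording
#' key. Name collisions are rejected; unmatched keys are reported.
#'
#' @param fm A [feature_matrix()].
#' @param table Data frame or CSV path; first column must be the recording
#'   key, remaining columns named features.
#' @return The merged `feature_matrix`.
#' @export
attach_external_features <- function(fm, table) {
  if (is.character(table))
    table <- data.table::fread(table, data.table = FALSE)
  if (ncol(table) < 1) stop("empty external table", call. = FALSE)
  if (ncol(table) == 1) return(fm)
  keys <- as.character(table[[1]])
  feats <- as.matrix(table[, -1, drop = FALSE])
  clash <- intersect(colnames(feats), colnames(fm$values))
  if (length(clash))
    stop("duplicate feature name(s): ", paste(clash, collapse = ", "),
         call. = FALSE)
  idx <- match(rownames(fm$values), keys)
  if (anyNA(idx))
    stop("external table missing keys: ",
         paste(rownames(fm$values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  fm$values <- cbind(fm$values, feats[idx, , drop = FALSE])
  fm
}

#' Compute the pipeline's model-based features for a cohort
#'
#' For each recording: the GARCH-residual KS feature
#' ([garch_ks_feature()], computed on the z-normalised series; it is
#' amplitude-invariant anyway) and the multi-state HMM train
#' log-likelihood feature ([hmm_compare_nstates_feature()]). The HMM
#' feature is computed on the series variant selected by `hmm_on`:
#' `"nonnormalized"` (default) retains physical amplitude, making the
#' feature amplitude-dependent as in the pipeline's headline classifier;
#' `"normalized"` yields the amplitude-independent variant.
#'
#' @param manifest A [cohort_manifest()] (or a list of `raw_recording`s).
#' @param duration,band Preprocessing parameters (defaults 15 s, 2-30 Hz).
#' @param hmm_on `"nonnormalized"` or `"normalized"`.
#' @param seed Base seed for HMM restarts.
#' @param features Which features to compute (default both).
#' @param allow_short Accept short recordings (length-ablation mode).
#' @return A raw-scale [feature_matrix()] (run [filter_invalid_features()]
#'   and [minmax_normalize_features()] downstream).
#' @export
compute_feature_matrix <- function(manifest, duration = 15, band = c(2, 30),
                                   hmm_on = c("nonnormalized", "normalized"),
                                   seed = 0,
                                   features = c("garch_ks", "hmm_maxll"),
                                   allow_short = FALSE) {
  hmm_on <- match.arg(hmm_on)
  recs <- if (inherits(manifest, "cohort_manifest")) manifest$recordings
          else manifest
  meta <- manifest_meta(if (inherits(manifest, "cohort_manifest")) manifest
                        else cohort_manifest(recs))
  vals <- matrix(NA_real_, nrow = length(recs), ncol = length(features),
                 dimnames = list(meta$key, features))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    norm <- tryCatch(
      preprocess_recording(rec, duration = duration, band = band,
                           normalize = TRUE, allow_short = allow_short),
      error = function(e) NULL)
    if ("garch_ks" %in% features && !is.null(norm))
      vals[i, "garch_ks"] <- tryCatch(
        as.numeric(garch_ks_feature(norm)), error = function(e) NA_real_)
    if ("hmm_maxll" %in% features) {
      series <- if (hmm_on == "normalized") norm else tryCatch(
        preprocess_recording(rec, duration = duration, band = band,
                             normalize = FALSE, allow_short = allow_short),
        error = function(e) NULL)
      if (!is.null(series))
        vals[i, "hmm_maxll"] <- tryCatch(
          as.numeric(hmm_compare_nstates_feature(
            series, seed = derive_seed(seed, i))),
          error = function(e) NA_real_)
    }
  }
  feature_matrix(vals, meta)
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' The CSV holds one row per recording (first column the recording key);
#' the sidecar JSON records normalisation bounds and the removal log.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV output path; the sidecar is written next to it with
#'   suffix `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(key = rownames(fm$values), fm$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, showProgress = FALSE)
  side <- list(normalization = fm$normalization,
               removed = fm$removed)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
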