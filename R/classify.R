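#' Patient-grouped k-fold assignment
#'
#' Assigns recordings to cross-validation folds such that all recordings
#' of one patient share a fold (no identity leakage), folds are balanced
#' within one patient, and — when labels are supplied — folds are
#' stratified by diagnosis. Deterministic given the seed.
#'
#' @param patient_ids Character vector, one entry per recording.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param labels Optional per-recording labels for stratification.
#' @return Integer vector of fold indices (1..k), one per recording.
#' @export
grouped_kfold <- function(patient_ids, k = 10, seed = 0, labels = NULL) {
  patients <- unique(patient_ids)
  if (length(patients) < k)
    stop(sprintf("fewer patients (%d) than folds (%d)",
                 length(patients), k), call. = FALSE)
  strata <- if (is.null(labels)) rep("all", length(patients)) else {
    vapply(patients, function(p) {
      tab <- table(labels[patient_ids == p])
      names(tab)[which.max(tab)]
    }, character(1))
  }
  fold_of <- setNames(integer(length(patients)), patients)
  counter <- 0L
  for (s in sort(unique(strata))) {
    ps <- patients[strata == s]
    ps <- with_seed(derive_seed(seed, match(s, sort(unique(strata)))),
                    sample(ps))
    for (p in ps) {
      fold_of[p] <- (counter %% k) + 1L
      counter <- counter + 1L
    }
  }
  unname(fold_of[patient_ids])
}

#' Classification metrics from confusion counts
#'
#' Plain accuracy (`100 * correct / total`), balanced accuracy (mean of
#' per-class recalls), sensitivity, specificity, PPV and NPV, all in
#' percent, from positive/negative confusion counts.
#'
#' @param tp,fn,tn,fp Confusion counts (positive class: true positives,
#'   false negatives, true negatives, false positives).
#' @return Named numeric vector (percent).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table", call. = FALSE)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  c(accuracy = 100 * (tp + tn) / total,
    balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
    sensitivity = sens,
    specificity = spec,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
}

fit_model <- function(x, y, model, seed = 0) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    svm = e1071::svm(x = as.matrix(df), y = y, kernel = "linear", cost = 1,
                     scale = FALSE),
    logistic = {
      d <- cbind(df, .y = y)
      suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
    },
    rf = with_seed(seed,
      randomForest::randomForest(x = df, y = y, ntree = 300)),
    stop("unknown model: ", model, call. = FALSE))
}

predict_model <- function(fit, x, model, levels_y) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    svm = predict(fit, as.matrix(df)),
    logistic = {
      p <- predict(fit, newdata = df, type = "response")
      factor(levels_y[1 + (p > 0.5)], levels = levels_y)
    },
    rf = predict(fit, df))
}

#' Cross-validated classifier evaluation
#'
#' Patient-grouped k-fold cross-validation of a classifier on a feature
#' matrix. Inside every fold the min-max normalisation bounds are fitted on
#' the training folds only and applied to the held-out fold (leakage-free);
#' the model is fitted and evaluated per fold, and confusion counts are
#' pooled. `PD` is the positive class for sensitivity/PPV by default.
#'
#' @param fm A raw-scale (filtered, un-normalised) [feature_matrix()].
#' @param labels Factor (or character) of class labels per recording.
#' @param features Feature columns to use (default: all).
#' @param model `"svm"` (linear, C = 1), `"logistic"` or `"rf"`.
#' @param k Folds (default 10).
#' @param seed Seed for fold assignment and any model randomness.
#' @param positive Positive class label (default `"PD"`, falling back to
#'   the last factor level when absent).
#' @param folds Optional precomputed fold vector (overrides `k`/`seed`).
#' @return A `classifier_report`: pooled and per-fold metrics, confusion
#'   counts, model, features, seed.
#' @export
evaluate_classifier <- function(fm, labels, features = colnames(fm$values),
                                model = c("svm", "logistic", "rf"),
                                k = 10, seed = 0, positive = "PD",
                                folds = NULL) {
  model <- match.arg(model)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("need exactly 2 classes, got ", nlevels(labels), call. = FALSE)
  if (!positive %in% levels(labels)) positive <- levels(labels)[nlevels(labels)]
  negative <- setdiff(levels(labels), positive)
  v <- fm$values[, features, drop = FALSE]
  if (anyNA(v)) stop("feature matrix contains invalid values; filter first",
                     call. = FALSE)
  pid <- fm$meta$patient_id
  if (is.null(folds)) folds <- grouped_kfold(pid, k, seed, labels)
  per_fold <- list()
  conf <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  pred_all <- factor(rep(NA, length(labels)), levels = levels(labels))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    if (nlevels(droplevels(labels[tr])) < 2) {
      warning(sprintf("fold %d: single-class training data; fold skipped", f),
              call. = FALSE)
      next
    }
    bounds <- list(min = apply(v[tr, , drop = FALSE], 2, min),
                   max = apply(v[tr, , drop = FALSE], 2, max))
    if (any(bounds$max == bounds$min)) {
      warning(sprintf("fold %d: constant feature in training folds; fold skipped", f),
              call. = FALSE)
      next
    }
    scale01 <- function(m) sweep(sweep(m, 2, bounds$min), 2,
                                 bounds$max - bounds$min, "/")
    fit <- fit_model(scale01(v[tr, , drop = FALSE]), labels[tr], model,
                     seed = derive_seed(seed, f))
    pr <- predict_model(fit, scale01(v[te, , drop = FALSE]), model,
                        levels(labels))
    pred_all[te] <- pr
    tp <- sum(pr == positive & labels[te] == positive)
    fn <- sum(pr == negative & labels[te] == positive)
    tn <- sum(pr == negative & labels[te] == negative)
    fp <- sum(pr == positive & labels[te] == negative)
    conf <- conf + c(tp = tp, fn = fn, tn = tn, fp = fp)
    per_fold[[length(per_fold) + 1L]] <-
      c(fold = f, confusion_metrics(tp, fn, tn, fp))
  }
  pooled <- confusion_metrics(conf[["tp"]], conf[["fn"]], conf[["tn"]],
                              conf[["fp"]])
  structure(list(
    model = model, features = features, positive = positive,
    pooled = pooled, per_fold = do.call(rbind, per_fold),
    confusion = conf, n = length(labels), folds = folds,
    predictions = pred_all, seed = seed
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s on [%s], %d recordings, positive=%s\n",
              x$model, paste(x$features, collapse = ", "), x$n, x$positive))
  m <- x$pooled
  cat(sprintf("  accuracy %.1f%% | balanced %.1f%% | sens %.1f%% | spec %.1f%% | PPV %.1f%% | NPV %.1f%%\n",
              m["accuracy"], m["balanced_accuracy"], m["sensitivity"],
              m["specificity"], m["ppv"], m["npv"]))
  invisible(x)
}

#' Markdown rendering of one or more classifier reports
#'
#' One column per report, rows in the conventional order Accuracy,
#' Sensitivity, Specificity, PPV, NPV.
#'
#' @param reports Named list of `classifier_report` objects.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(reports) {
  if (inherits(reports, "classifier_report")) reports <- list(model = reports)
  rows <- c(accuracy = "Accuracy", sensitivity = "Sensitivity",
            specificity = "Specificity", ppv = "PPV", npv = "NPV")
  hdr <- paste0("| Parameter | ", paste(names(reports), collapse = " % | "), " % |")
  sep <- paste0("|", paste(rep("---|", length(reports) + 1), collapse = ""))
  body <- vapply(names(rows), function(r) {
    vals <- vapply(reports, function(rep) sprintf("%.1f", rep$pooled[[r]]),
                   character(1))
    paste0("| ", rows[[r]], " | ", paste(vals, collapse = " | "), " |")
  }, character(1))
  c(hdr, sep, unname(body))
}

#' Univariate cross-validated feature accuracy
#'
#' Plain CV accuracy (percent) of the chosen model on one feature alone.
#'
#' @inheritParams evaluate_classifier
#' @param feature Single feature column name.
#' @return Accuracy in percent.
#' @export
univariate_feature_accuracy <- function(fm, labels, feature,
                                        model = "svm", k = 10, seed = 0,
                                        folds = NULL) {
  rep <- evaluate_classifier(fm, labels, features = feature, model = model,
                             k = k, seed = seed, folds = folds)
  unname(rep$pooled["accuracy"])
}

#' Univariate screening of features
#'
#' Returns the features whose univariate CV accuracy strictly exceeds the
#' threshold (default 75%).
#'
#' @inheritParams evaluate_classifier
#' @param threshold Screening threshold in percent (strict `>`).
#' @return Data frame `feature`, `accuracy`, `selected`, ordered by
#'   decreasing accuracy.
#' @export
screen_features <- function(fm, labels, model = "svm", k = 10, seed = 0,
                            threshold = 75, folds = NULL) {
  if (is.null(folds)) folds <- grouped_kfold(fm$meta$patient_id, k, seed,
                                             labels)
  acc <- vapply(colnames(fm$values), function(cn)
    univariate_feature_accuracy(fm, labels, cn, model, k, seed, folds),
    numeric(1))
  out <- data.frame(feature = names(acc), accuracy = unname(acc),
                    selected = unname(acc) > threshold)
  out[order(-out$accuracy), , drop = FALSE]
}

#' Exhaustive feature-combination search
#'
#' Evaluates every combination of the screened features of the requested
#' sizes (default 2, 3 and 4) by cross-validated accuracy and ranks the
#' results in ascending order (worst to best). The result is invariant to
#' the enumeration order of the input features.
#'
#' @inheritParams evaluate_classifier
#' @param features Screened feature names to combine.
#' @param sizes Combination sizes (default `2:4`).
#' @return Data frame `combo` (feature names joined by `+`), `size`,
#'   `accuracy`, `balanced_accuracy`, `rank` (1 = worst), sorted ascending
#'   by accuracy with deterministic tie-breaks.
#' @export
combination_search <- function(fm, labels, features, sizes = 2:4,
                               model = "svm", k = 10, seed = 0,
                               folds = NULL) {
  if (!length(features)) stop("empty screened feature set", call. = FALSE)
  if (is.null(folds)) folds <- grouped_kfold(fm$meta$patient_id, k, seed,
                                             labels)
  features <- sort(features)
  combos <- list()
  for (s in sizes[sizes <= length(features)]) {
    cm <- combn(features, s, simplify = FALSE)
    combos <- c(combos, cm)
  }
  res <- lapply(combos, function(cc) {
    rep <- evaluate_classifier(fm, labels, features = cc, model = model,
                               k = k, seed = seed, folds = folds)
    data.frame(combo = paste(cc, collapse = "+"), size = length(cc),
               accuracy = unname(rep$pooled["accuracy"]),
               balanced_accuracy = unname(rep$pooled["balanced_accuracy"]))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$accuracy, out$size, out$combo), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Accuracy as a function of the number of stacked features
#'
#' Ranks features by univariate CV accuracy and evaluates the top-1,
#' top-2, ... top-`max_n` stacks.
#'
#' @inheritParams evaluate_classifier
#' @param max_n Largest stack size (default 10; truncated to the number of
#'   available features).
#' @return Data frame `n_features`, `features`, `accuracy`,
#'   `balanced_accuracy` with `n_features` strictly increasing.
#' @export
incremental_feature_curve <- function(fm, labels, model = "svm", k = 10,
                                      seed = 0, max_n = 10, folds = NULL) {
  if (is.null(folds)) folds <- grouped_kfold(fm$meta$patient_id, k, seed,
                                             labels)
  sc <- screen_features(fm, labels, model, k, seed, threshold = -Inf,
                        folds = folds)
  ranked <- sc$feature
  max_n <- min(max_n, length(ranked))
  res <- lapply(seq_len(max_n), function(n) {
    rep <- evaluate_classifier(fm, labels, features = ranked[seq_len(n)],
                               model = model, k = k, seed = seed,
                               folds = folds)
    data.frame(n_features = n,
               features = paste(ranked[seq_len(n)], collapse = "+"),
               accuracy = unname(rep$pooled["accuracy"]),
               balanced_accuracy = unname(rep$pooled["balanced_accuracy"]))
  })
  do.call(rbind, res)
}

#' Segment-length ablation of the full pipeline
#'
#' Re-runs preprocessing, feature extraction and cross-validated
#' classification on truncated segments of the same recordings, one run per
#' requested segment length. Lengths too short for the model-based features
#' yield an invalid cell rather than an error.
#'
#' @param manifest A [cohort_manifest()] of the recordings to ablate.
#' @param labels Per-recording class labels (aligned with the manifest).
#' @param lengths Segment lengths in seconds (e.g. `c(3, 5, 8, 10, 12, 15)`).
#' @param model,k,seed Classifier settings as in [evaluate_classifier()].
#' @param hmm_on Series variant for the HMM feature
#'   (see [compute_feature_matrix()]).
#' @return Data frame `length_s`, `accuracy`, `balanced_accuracy`,
#'   `valid`.
#' @export
length_ablation <- function(manifest, labels, lengths, model = "svm",
                            k = 10, seed = 0,
                            hmm_on = "nonnormalized") {
  res <- lapply(lengths, function(L) {
    row <- data.frame(length_s = L, accuracy = NA_real_,
                      balanced_accuracy = NA_real_, valid = FALSE)
    fmres <- tryCatch({
      fm <- compute_feature_matrix(manifest, duration = L, hmm_on = hmm_on,
                                   seed = seed, allow_short = TRUE)
      fm <- filter_invalid_features(fm)
      if (!ncol(fm$values)) stop("no valid features at this length")
      rep <- evaluate_classifier(fm, labels, model = model, k = k,
                                 seed = seed)
      rep$pooled
    }, error = function(e) NULL)
    if (!is.null(fmres)) {
      row$accuracy <- unname(fmres["accuracy"])
      row$balanced_accuracy <- unname(fmres["balanced_accuracy"])
      row$valid <- TRUE
    }
    row
  })
  do.call(rbind, res)
}

#' External validation of a trained classifier
#'
#' Fits normalisation bounds and the model on the full training cohort,
#' then evaluates once on a held-out cohort without any refitting.
#'
#' @param train_fm,train_labels Training feature matrix (raw scale,
#'   filtered) and labels.
#' @param valid_fm,valid_labels Held-out feature matrix and labels.
#' @param features,model,seed,positive As in [evaluate_classifier()].
#' @return A `classifier_report` for the held-out cohort.
#' @export
validate_external <- function(train_fm, train_labels, valid_fm, valid_labels,
                              features = colnames(train_fm$values),
                              model = "svm", seed = 0, positive = "PD") {
  if (!nrow(valid_fm$values)) stop("empty validation set", call. = FALSE)
  missing <- setdiff(features, colnames(valid_fm$values))
  if (length(missing))
    stop("validation set lacks feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  train_labels <- factor(train_labels)
  valid_labels <- factor(valid_labels, levels = levels(train_labels))
  if (!positive %in% levels(train_labels))
    positive <- levels(train_labels)[nlevels(train_labels)]
  negative <- setdiff(levels(train_labels), positive)
  vt <- train_fm$values[, features, drop = FALSE]
  vv <- valid_fm$values[, features, drop = FALSE]
  if (anyNA(vt) || anyNA(vv))
    stop("invalid feature values; filter first", call. = FALSE)
  bounds <- list(min = apply(vt, 2, min), max = apply(vt, 2, max))
  scale01 <- function(m) sweep(sweep(m, 2, bounds$min), 2,
                               bounds$max - bounds$min, "/")
  fit <- fit_model(scale01(vt), train_labels, model, seed = seed)
  pr <- predict_model(fit, scale01(vv), model, levels(train_labels))
  tp <- sum(pr == positive & valid_labels == positive)
  fn <- sum(pr == negative & valid_labels == positive)
  tn <- sum(pr == negative & valid_labels == negative)
  fp <- sum(pr == positive & valid_labels == negative)
  structure(list(
    model = model, features = features, positive = positive,
    pooled = confusion_metrics(tp, fn, tn, fp), per_fold = NULL,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    n = length(valid_labels), folds = NULL,
    predictions = pr, seed = seed
  ), class = "classifier_report")
}
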