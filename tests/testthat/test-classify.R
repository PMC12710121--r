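test_that("grouped folds are patient-atomic, balanced and deterministic", {
  pid <- rep(sprintf("p%02d", 1:20), each = 2)
  f <- grouped_kfold(pid, k = 10, seed = 1)
  expect_equal(length(unique(f)), 10)
  for (p in unique(pid)) expect_equal(length(unique(f[pid == p])), 1)
  expect_true(all(table(f[!duplicated(pid)]) == 2))
  expect_identical(f, grouped_kfold(pid, k = 10, seed = 1))
  expect_false(identical(f, grouped_kfold(pid, k = 10, seed = 2)))
  expect_error(grouped_kfold(sprintf("p%d", 1:5), k = 10), "fewer patients")
  # stratified: each fold receives patients from both classes when possible
  labels <- rep(rep(c("ET", "PD"), each = 10), each = 2)
  fs <- grouped_kfold(pid, k = 5, seed = 3, labels = labels)
  per_fold <- table(fs[!duplicated(pid)], labels[!duplicated(pid)])
  expect_true(all(per_fold == 2))
})

test_that("confusion metrics match hand-computed arithmetic", {
  m <- confusion_metrics(tp = 8, fn = 2, tn = 0, fp = 0)
  expect_equal(unname(m["accuracy"]), 80)
  # majority-class degenerate classifier on a 70/30 split
  m2 <- confusion_metrics(tp = 70, fn = 0, tn = 0, fp = 30)
  expect_equal(unname(m2["accuracy"]), 70)
  expect_equal(unname(m2["balanced_accuracy"]), 50)
  # spec'd confusion counts: TP=19 FN=3 TN=18 FP=5
  m3 <- confusion_metrics(19, 3, 18, 5)
  expect_equal(unname(m3["sensitivity"]), 100 * 19 / 22)
  expect_equal(round(unname(m3["sensitivity"]), 1), 86.4)
  expect_equal(round(unname(m3["specificity"]), 1), 78.3)
  expect_equal(unname(m3["ppv"]), 100 * 19 / 24)
  expect_equal(unname(m3["npv"]), 100 * 18 / 21)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("report metrics are consistent with stored confusion counts", {
  toy <- toy_feature_matrix(n_per_class = 15, n_noise = 1, sep = 1.2)
  rep <- evaluate_classifier(toy$fm, toy$labels, k = 5, seed = 2)
  cc <- rep$confusion
  expect_equal(sum(cc), rep$n)
  recomputed <- confusion_metrics(cc[["tp"]], cc[["fn"]], cc[["tn"]],
                                  cc[["fp"]])
  expect_equal(rep$pooled, recomputed)
  expect_equal(unname(rep$pooled["sensitivity"]),
               100 * cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]))
})

test_that("a separable feature classifies perfectly; shuffled labels do not", {
  toy <- toy_feature_matrix(n_per_class = 20, sep = 8)
  rep <- evaluate_classifier(toy$fm, toy$labels, k = 10, seed = 1)
  expect_equal(unname(rep$pooled["accuracy"]), 100)
  accs <- vapply(1:15, function(s) {
    shuffled <- with_seed_local(s, sample(as.character(toy$labels)))
    r <- evaluate_classifier(toy$fm, shuffled, k = 10, seed = s)
    unname(r$pooled["balanced_accuracy"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("univariate screening applies a strict 75% threshold", {
  toy <- toy_feature_matrix(n_per_class = 20, n_noise = 3, sep = 8)
  folds <- grouped_kfold(toy$fm$meta$patient_id, 10, 1, toy$labels)
  sc <- screen_features(toy$fm, toy$labels, folds = folds)
  expect_true(sc$selected[sc$feature == "signal"])
  expect_false(any(sc$selected[grepl("noise", sc$feature)]))
  # identical-for-both-classes feature carries no signal
  flat_acc <- univariate_feature_accuracy(toy$fm, toy$labels, "noise1",
                                          folds = folds)
  expect_lt(flat_acc, 70)
  # boundary: exactly 75.0 is excluded by the strict rule
  sc75 <- data.frame(feature = "f", accuracy = 75)
  expect_false(sc75$accuracy > 75)
})

test_that("combination search is exhaustive, ranked and order-invariant", {
  toy <- toy_feature_matrix(n_per_class = 12, n_noise = 2, sep = 6)
  folds <- grouped_kfold(toy$fm$meta$patient_id, 6, 1, toy$labels)
  feats <- colnames(toy$fm$values)  # 3 features
  res <- combination_search(toy$fm, toy$labels, feats, sizes = 2:4,
                            folds = folds)
  expect_equal(nrow(res), choose(3, 2) + choose(3, 3))  # 3 pairs + 1 triple
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(res$accuracy))
  res2 <- combination_search(toy$fm, toy$labels, rev(feats), sizes = 2:4,
                             folds = folds)
  expect_equal(res, res2)
})

test_that("a planted informative pair wins the combination search", {
  with_seed_local(42, {
    n <- 60
    labels <- rep(c("ET", "PD"), each = n / 2)
    half <- ifelse(labels == "PD", 1.1, 0)
    # additive two-feature signal: each half alone is weak, the sum separates
    f1 <- rnorm(n, half, 0.9); f2 <- rnorm(n, half, 0.9)
    vals <- cbind(f1 = f1, f2 = f2,
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    meta <- data.frame(key = sprintf("p%02d/rest/right", 1:n),
                       patient_id = sprintf("p%02d", 1:n),
                       diagnosis = labels, condition = "rest", hand = "right")
    fm <- feature_matrix(vals, meta)
    folds <- grouped_kfold(meta$patient_id, 10, 7, labels)
    res <- combination_search(fm, labels, colnames(vals), sizes = 2:3,
                              folds = folds)
    best <- res$combo[which.max(res$accuracy)]
    expect_equal(best, "f1+f2")
    # adding a noise feature to the winning pair does not improve accuracy
    best_pair <- res$accuracy[res$combo == "f1+f2"]
    triples <- res[res$size == 3 & grepl("f1", res$combo) &
                     grepl("f2", res$combo), ]
    expect_true(all(triples$accuracy <= best_pair + 2))
  })
})

test_that("incremental feature curve plateaus after the informative features", {
  toy <- toy_feature_matrix(n_per_class = 20, n_noise = 8, sep = 6)
  folds <- grouped_kfold(toy$fm$meta$patient_id, 10, 1, toy$labels)
  curve <- incremental_feature_curve(toy$fm, toy$labels, folds = folds,
                                     max_n = 9)
  expect_equal(curve$n_features, 1:9)
  expect_gte(curve$accuracy[1], 90)           # signal feature ranked first
  expect_gte(min(curve$accuracy[1:3]), 85)    # noise does not destroy it
  # all-noise features stay near chance
  noise_only <- toy_feature_matrix(n_per_class = 20, n_noise = 5, sep = 0)
  curve0 <- incremental_feature_curve(noise_only$fm, noise_only$labels,
                                      folds = folds, max_n = 5)
  expect_lt(max(curve0$balanced_accuracy), 80)
})

test_that("normalization bounds come from training folds only", {
  toy <- toy_feature_matrix(n_per_class = 10, sep = 2)
  v <- toy$fm$values
  folds <- grouped_kfold(toy$fm$meta$patient_id, 5, 1, toy$labels)
  # train-only bounds differ from global bounds whenever the test fold
  # holds the extreme value; verify the classifier never sees global info
  for (f in unique(folds)) {
    tr <- folds != f
    b <- list(min = apply(v[tr, , drop = FALSE], 2, min),
              max = apply(v[tr, , drop = FALSE], 2, max))
    if (min(v[, 1]) < b$min[1] || max(v[, 1]) > b$max[1]) {
      held <- minmax_normalize_features(
        feature_matrix(v[!tr, , drop = FALSE], toy$fm$meta[!tr, ]), b)
      expect_true(any(held$values < 0 | held$values > 1))
    }
  }
})

test_that("external validation uses frozen bounds and models", {
  toy_tr <- toy_feature_matrix(n_per_class = 20, sep = 4, seed = 1)
  toy_va <- toy_feature_matrix(n_per_class = 10, sep = 4, seed = 2)
  rep <- validate_external(toy_tr$fm, toy_tr$labels,
                           toy_va$fm, toy_va$labels)
  expect_gte(unname(rep$pooled["accuracy"]), 90)
  # CV and external accuracy agree within 10 points for matched generators
  cv <- evaluate_classifier(toy_tr$fm, toy_tr$labels, k = 5, seed = 1)
  expect_lt(abs(unname(rep$pooled["accuracy"]) -
                unname(cv$pooled["accuracy"])), 10)
  # shifted validation cohort degrades but does not crash
  toy_far <- toy_feature_matrix(n_per_class = 10, sep = -1, seed = 3)
  rep2 <- validate_external(toy_tr$fm, toy_tr$labels,
                            toy_far$fm, toy_far$labels)
  expect_true(is.finite(rep2$pooled[["accuracy"]]))
  empty <- toy_va$fm; empty$values <- empty$values[0, , drop = FALSE]
  expect_error(validate_external(toy_tr$fm, toy_tr$labels, empty,
                                 factor(character())), "empty")
})

test_that("logistic and random-forest backends run on the same interface", {
  toy <- toy_feature_matrix(n_per_class = 15, sep = 6)
  for (mdl in c("logistic", "rf")) {
    rep <- evaluate_classifier(toy$fm, toy$labels, model = mdl, k = 5,
                               seed = 4)
    expect_gte(unname(rep$pooled["accuracy"]), 90)
  }
})
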