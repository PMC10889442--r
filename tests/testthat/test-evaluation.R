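test_that("confusion matrices cross-tabulate exactly", {
  cm <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(cm$table["A", "A"], 1L)  # class-A TP
  expect_equal(cm$table["A", "B"], 1L)  # class-A FN
  expect_equal(cm$table["B", "B"], 2L)  # class-B TP
  expect_equal(sum(cm$table[, "B"]) - cm$table["B", "B"], 1L)  # class-B FP

  perfect <- confusion(c("x", "y", "z"), c("x", "y", "z"))
  expect_true(all(perfect$table[upper.tri(perfect$table)] == 0))
  expect_true(all(perfect$table[lower.tri(perfect$table)] == 0))

  expect_error(confusion(c("A", "B"), c("A")), "differ in length")

  # brute-force pair counting on a random 3-class vector
  tr <- withr::with_seed(70, sample(c("a", "b", "c"), 60, replace = TRUE))
  pr <- withr::with_seed(71, sample(c("a", "b", "c"), 60, replace = TRUE))
  cm3 <- confusion(tr, pr)
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    expect_equal(cm3$table[i, j], sum(tr == i & pr == j))
  }
})

test_that("metrics reproduce the hand-worked binary contingency", {
  # TP=5, FP=1, FN=1, TN=3 for the positive class
  true <- rep(c("P", "N"), c(6, 4))
  pred <- c(rep("P", 5), "N", "P", rep("N", 3))
  rep <- compute_metrics(confusion(true, pred))
  p_row <- rep$per_class[rep$per_class$class == "P", ]
  expect_equal(p_row$precision, 5 / 6 * 100, tolerance = 1e-12)
  expect_equal(p_row$recall, 5 / 6 * 100, tolerance = 1e-12)
  expect_equal(p_row$f1, 5 / 6 * 100, tolerance = 1e-12)
  expect_equal(round(p_row$precision, 2), 83.33)
  expect_equal(rep$accuracy, 80)

  perfect <- compute_metrics(confusion(true, true))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class$f1 == 100))
  expect_equal(perfect$weighted$precision, 100)
})

test_that("a class never predicted gets zero precision with a warning", {
  warns <- testthat::capture_warnings(
    rep <- compute_metrics(confusion(c("A", "A", "B"), c("A", "A", "A"))))
  expect_true(any(grepl("zero denominator", warns)))
  expect_equal(rep$per_class$precision[rep$per_class$class == "B"], 0)
})

test_that("weighted recall equals accuracy on arbitrary multiclass reports", {
  for (s in 1:10) {
    k <- 2 + s %% 4
    tr <- withr::with_seed(80 + s,
                           sample(letters[1:k], 50, replace = TRUE,
                                  prob = seq_len(k)))
    pr <- withr::with_seed(90 + s, sample(letters[1:k], 50, replace = TRUE))
    rep <- suppressWarnings(compute_metrics(confusion(tr, pr)))
    expect_equal(rep$weighted$recall, rep$accuracy, tolerance = 1e-12)
  }
})

test_that("holdout evaluation keeps every fitted statistic on the training side", {
  fx <- make_reference_fixtures(n_genes = 80, seed = 21)
  sp <- fixed_holdout_split(fx$allaml$data, fx$allaml$train_idx)
  cfg <- pipeline_config(oversampler = list(method = "smote"),
                         selector = list(method = "chisig", n = 15),
                         seed = 3)
  rep <- evaluate_holdout(cfg, sp$train, sp$test)
  # normalization ranges are the training split's, not the full data's
  expect_equal(unname(rep$normalizer$min),
               unname(apply(sp$train$matrix, 2, min)))
  full_min <- apply(fx$allaml$data$matrix, 2, min)
  expect_false(isTRUE(all.equal(unname(rep$normalizer$min), unname(full_min))))
  # provenance references training samples only
  expect_true(all(rep$provenance$seed_id %in% sp$train$sample_ids))
  expect_length(intersect(rep$provenance$seed_id, sp$test$sample_ids), 0)
  # the recorded gene set is what the pipeline actually used
  expect_true(length(rep$selected_genes) >= 1)
  expect_true(all(rep$selected_genes %in% fx$allaml$data$gene_ids))

  expect_error(evaluate_holdout(cfg, sp$train, sp$train), "overlap")
})

test_that("a pipeline with no oversampler and no selector is the bare backend", {
  d <- random_dataset(n = 40, p = 10, classes = c(A = 25, B = 15), seed = 23)
  sp <- fixed_holdout_split(d, 1:28)
  cfg <- pipeline_config(normalize_scope = "none", seed = 9)
  rep <- suppressWarnings(evaluate_holdout(cfg, sp$train, sp$test))
  model <- fit_backend(classifier_config("knn_vote"), sp$train)
  direct <- suppressWarnings(predict_backend(model, sp$test$matrix))
  expect_equal(rep$predictions$predicted, as.character(direct))
})

test_that("stratified CV assigns every class across folds deterministically", {
  d <- random_dataset(n = 4, p = 4, classes = c(A = 2, B = 2), seed = 24)
  cfg <- pipeline_config(normalize_scope = "none", seed = 1)
  # tiny folds clamp the ensemble's k values, which warns by design
  rep <- suppressWarnings(cross_validate(cfg, d, folds = 2, seed = 5))
  # 2 folds on a 4-sample balanced set: one sample per class per fold
  for (f in 1:2) {
    expect_equal(sort(as.character(d$labels[rep$fold_assignment == f])),
                 c("A", "B"))
  }

  d2 <- random_dataset(n = 36, p = 8, classes = c(A = 20, B = 16), seed = 25)
  cfg2 <- pipeline_config(oversampler = list(method = "smote"), seed = 2)
  r1 <- cross_validate(cfg2, d2, folds = 4, seed = 7)
  r2 <- cross_validate(cfg2, d2, folds = 4, seed = 7)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion$table, r2$confusion$table)

  warns <- testthat::capture_warnings(cross_validate(cfg, d, folds = 10,
                                                     seed = 1))
  expect_true(any(grepl("reducing folds", warns)))
})

test_that("pooled CV accuracy equals total correct over total samples", {
  d <- random_dataset(n = 40, p = 8, classes = c(A = 22, B = 18), seed = 26)
  cfg <- pipeline_config(seed = 4)
  rep <- cross_validate(cfg, d, folds = 5, seed = 4)
  correct <- sum(vapply(rep$folds, function(f) sum(diag(f$confusion$table)),
                        numeric(1)))
  total <- sum(vapply(rep$folds, function(f) sum(f$confusion$table), numeric(1)))
  expect_equal(rep$accuracy, correct / total * 100)
  expect_equal(total, 40)
})

test_that("baseline comparison labels effects by the epsilon threshold", {
  mk <- function(acc) {
    true <- rep(c("A", "B"), c(60, 40))
    pred <- true
    flip <- seq_len(round((100 - acc)))
    pred[flip] <- ifelse(pred[flip] == "A", "B", "A")
    compute_metrics(confusion(true, pred))
  }
  reports <- list(baseline = mk(80), better = mk(85), same = mk(80),
                  worse = mk(70))
  eff <- compare_to_baseline(reports)
  expect_equal(eff$effect_accuracy[eff$method == "better"], "positive")
  expect_equal(eff$effect_accuracy[eff$method == "same"], "negligible")
  expect_equal(eff$effect_accuracy[eff$method == "worse"], "negative")
  expect_equal(eff$delta_accuracy[eff$method == "better"], 5)
  # ordering by delta is invariant to the common baseline shift
  expect_equal(order(eff$delta_accuracy), order(eff$accuracy))
  expect_error(compare_to_baseline(reports[-1]), "baseline")
})

test_that("PCA reduction is fitted on the training split only", {
  fx <- make_reference_fixtures(n_genes = 120, seed = 27)
  sp <- fixed_holdout_split(fx$cumida$data, fx$cumida$train_idx)
  red <- pca_reduce(sp$train, sp$test, n_components = 20)
  expect_equal(dim(red$train$matrix), c(51L, 20L))
  expect_equal(dim(red$test$matrix), c(13L, 20L))
  expect_identical(red$test$labels, sp$test$labels)

  # projections of the test set under a whole-data fit must differ
  whole <- pca_reduce(fx$cumida$data, NULL, n_components = 20)
  expect_false(isTRUE(all.equal(abs(red$test$matrix),
                                abs(whole$train$matrix[sp$test$sample_ids, ]))))
  expect_error(pca_reduce(sp$train, sp$test, n_components = 60),
               "exceeds")

  # full-rank projection reconstructs distances (no information lost)
  tiny <- random_dataset(n = 12, p = 5, seed = 28)
  full <- pca_reduce(tiny, NULL, n_components = 5)
  expect_equal(as.matrix(dist(full$train$matrix)), as.matrix(dist(tiny$matrix)),
               tolerance = 1e-8, ignore_attr = TRUE)
})
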