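#' Confusion matrix from true and predicted labels
#'
#' Exact cross-tabulation (rows = true class, columns = predicted class) over
#' the union of observed classes, sorted by name.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return a `ConfusionMatrix` with fields `classes` and `table`.
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors differ in length (", length(labels_true), " vs ",
         length(labels_pred), ")")
  }
  lv <- sort(union(unique(as.character(labels_true)),
                   unique(as.character(labels_pred))))
  tab <- table(true = factor(as.character(labels_true), levels = lv),
               predicted = factor(as.character(labels_pred), levels = lv))
  structure(list(classes = lv, table = unclass(tab)), class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  print(x$table)
  invisible(x)
}

.safe_div <- function(num, den, what) {
  bad <- den == 0
  if (any(bad)) {
    warning("zero denominator for ", what, " of class(es) ",
            paste(names(num)[bad] %||% which(bad), collapse = ", "),
            "; metric set to 0")
  }
  out <- ifelse(bad, 0, num / ifelse(bad, 1, den))
  out
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' Per class (one-vs-rest): precision = TP/(TP+FP) x 100,
#' recall = TP/(TP+FN) x 100, F1 = 2PR/(P+R); overall accuracy is the
#' diagonal fraction x 100. Averages are weighted by class support, which
#' makes the weighted recall algebraically equal to the accuracy. Zero
#' denominators (e.g. a class never predicted) yield 0 with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @return an `EvaluationReport` fragment: `per_class` data frame, `weighted`
#'   precision/recall/F1 (percent), `accuracy` (percent) and `n`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "ConfusionMatrix"))
  M <- cm$table
  N <- sum(M)
  if (N == 0L) stop("empty confusion matrix")
  tp <- diag(M)
  fp <- colSums(M) - tp
  fn <- rowSums(M) - tp
  support <- rowSums(M)
  precision <- .safe_div(tp, tp + fp, "precision") * 100
  recall <- .safe_div(tp, tp + fn, "recall") * 100
  f1 <- .safe_div(2 * precision * recall, precision + recall, "F1")
  w <- support / N
  structure(
    list(per_class = data.frame(class = cm$classes, support = as.integer(support),
                                precision = unname(precision),
                                recall = unname(recall), f1 = unname(f1),
                                stringsAsFactors = FALSE),
         weighted = list(precision = sum(w * precision),
                         recall = sum(w * recall),
                         f1 = sum(w * f1)),
         accuracy = sum(tp) / N * 100,
         n = as.integer(N),
         confusion = cm),
    class = "EvaluationReport"
  )
}

#' @export
print.EvaluationReport <- function(x, ...) {
  # two-decimal half-up display, matching common benchmark-table style
  fmt <- function(v) formatC(floor(v * 100 + 0.5) / 100, format = "f", digits = 2)
  cat("EvaluationReport (n = ", x$n, ")\n", sep = "")
  cat("  accuracy: ", fmt(x$accuracy),
      "   weighted P/R/F1: ", fmt(x$weighted$precision), "/",
      fmt(x$weighted$recall), "/", fmt(x$weighted$f1), "\n", sep = "")
  if (!is.null(x$folds)) cat("  folds: ", length(x$folds), "\n", sep = "")
  invisible(x)
}

#' Evaluate a pipeline on a fixed train/test split
#'
#' Runs the full, leakage-safe pipeline: the normalizer, the oversampler and
#' the gene selector are all fitted on the training split only (unless
#' `normalize_scope = "full"` is explicitly requested to mirror a
#' whole-dataset normalization), the test split is projected onto the
#' selected genes, and the configured backend is fitted and evaluated.
#'
#' @param config a [pipeline_config()].
#' @param train,test disjoint `ExpressionDataset`s with identical gene ids.
#' @return an `EvaluationReport` extended with the selected genes, the
#'   oversampling provenance, the fitted normalization statistics, the raw
#'   predictions and the config fingerprint.
#' @export
evaluate_holdout <- function(config, train, test) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!identical(train$gene_ids, test$gene_ids)) {
    stop("train and test gene ids differ")
  }
  if (length(intersect(train$sample_ids, test$sample_ids)) > 0L) {
    stop("train and test sets overlap")
  }
  seed <- config$seed
  norm <- NULL
  if (config$normalize_scope != "none") {
    fit_on <- if (config$normalize_scope == "full") {
      expression_dataset(rbind(train$matrix, test$matrix),
                         c(as.character(train$labels), as.character(test$labels)),
                         gene_ids = train$gene_ids,
                         sample_ids = c(train$sample_ids, test$sample_ids))
    } else {
      train
    }
    norm <- fit_normalizer(fit_on, fitted_on = config$normalize_scope)
    train <- apply_normalizer(norm, train)
    test <- apply_normalizer(norm, test)
  }
  provenance <- NULL
  train_work <- train
  selected <- NULL

  do_select <- function(ds) {
    sel <- select_genes(ds, method = config$selector$method,
                        n = config$selector$n,
                        disc_method = config$selector$disc %||% "mdl",
                        max_bins = config$selector$max_bins %||% 10L)
    if (length(sel$genes) == 0L) {
      stop("gene selection (", config$selector$method,
           ") produced an empty gene set")
    }
    sel
  }
  do_oversample <- function(ds) {
    os_args <- config$oversampler
    res <- do.call(oversample, c(list(train = ds, method = os_args$method,
                                      seed = stage_seed(seed, "oversample")),
                                 os_args[setdiff(names(os_args), "method")]))
    res
  }

  if (!is.null(config$selector) && config$select_before_oversample) {
    selected <- do_select(train_work)
    train_work <- subset_dataset(train_work, genes = selected$genes)
    test <- subset_dataset(test, genes = selected$genes)
  }
  if (!is.null(config$oversampler)) {
    os <- do_oversample(train_work)
    provenance <- os$provenance
    train_work <- os$data
  }
  if (!is.null(config$selector) && !config$select_before_oversample) {
    selected <- do_select(train_work)
    train_work <- subset_dataset(train_work, genes = selected$genes)
    test <- subset_dataset(test, genes = selected$genes)
  }
  if (!is.null(config$pca)) {
    red <- pca_reduce(train_work, test, n_components = config$pca)
    train_work <- red$train
    test <- red$test
  }
  model <- fit_backend(config$backend, train_work,
                       seed = stage_seed(seed, "fit"))
  pred <- predict_backend(model, test)
  rep <- compute_metrics(confusion(test$labels, pred))
  rep$selected_genes <- selected$genes
  rep$provenance <- provenance
  rep$normalizer <- if (is.null(norm)) NULL else
    list(min = norm$min, max = norm$max, fitted_on = norm$fitted_on)
  rep$predictions <- data.frame(sample_id = test$sample_ids,
                                true = as.character(test$labels),
                                predicted = as.character(pred),
                                stringsAsFactors = FALSE)
  rep$fingerprint <- config_fingerprint(config)
  rep
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' Assigns stratified folds (class proportions preserved; assignment drawn
#' from the fold RNG stream of `seed`), then refits the entire pipeline -
#' normalization, oversampling, gene selection, backend - on each training
#' split only. Synthetic samples are generated inside the training folds, so
#' no test sample can leak into any oversampling provenance record. The
#' headline numbers come from the pooled (micro) confusion matrix across
#' folds; per-fold reports are attached.
#'
#' @param config a [pipeline_config()].
#' @param data a labeled `ExpressionDataset`.
#' @param folds requested fold count (default 10); reduced with a warning
#'   when the smallest class has fewer samples.
#' @param seed integer seed controlling fold assignment and per-fold stages.
#' @return an `EvaluationReport` with `folds` (per-fold reports),
#'   `fold_assignment` and pooled metrics.
#' @export
cross_validate <- function(config, data, folds = 10, seed = 1L) {
  stopifnot(inherits(config, "PipelineConfig"))
  dist <- class_distribution(data)
  if (length(dist$counts) < 2L) stop("cross-validation needs >= 2 classes")
  min_count <- min(dist$counts)
  if (min_count < folds) {
    folds <- max(2L, min_count)
    warning("smallest class has ", min_count,
            " samples; reducing folds to ", folds)
  }
  n <- n_samples(data)
  assign <- integer(n)
  withr::with_seed(stage_seed(seed, "folds"), {
    for (cls in names(dist$counts)) {
      idx <- which(as.character(data$labels) == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_reports <- vector("list", folds)
  pooled <- NULL
  for (f in seq_len(folds)) {
    cfg <- config
    cfg$seed <- stage_seed(seed, paste0("fold", f))
    split <- list(train = subset_dataset(data, samples = which(assign != f)),
                  test = subset_dataset(data, samples = which(assign == f)))
    fold_reports[[f]] <- evaluate_holdout(cfg, split$train, split$test)
    tab <- fold_reports[[f]]$confusion$table
    pooled <- if (is.null(pooled)) tab else pooled + tab
  }
  cm <- structure(list(classes = rownames(pooled), table = pooled),
                  class = "ConfusionMatrix")
  rep <- compute_metrics(cm)
  rep$folds <- fold_reports
  rep$fold_assignment <- assign
  rep$fold_accuracy <- vapply(fold_reports, function(r) r$accuracy, numeric(1))
  rep$fingerprint <- config_fingerprint(config)
  rep
}

#' Compare evaluation reports against a baseline
#'
#' Computes per-method deltas of accuracy and weighted precision/recall/F1
#' relative to the `baseline` report and labels each method's effect as
#' `positive` (delta > epsilon), `negative` (delta < -epsilon) or
#' `negligible`, per metric.
#'
#' @param reports named list of `EvaluationReport`s including one called
#'   `"baseline"`.
#' @param epsilon effect threshold in percentage points (default 0.5).
#' @return a data frame with one row per non-baseline method.
#' @export
compare_to_baseline <- function(reports, epsilon = 0.5) {
  if (!"baseline" %in% names(reports)) stop("no 'baseline' report supplied")
  base <- reports[["baseline"]]
  metrics_of <- function(r) {
    c(precision = r$weighted$precision, recall = r$weighted$recall,
      f1 = r$weighted$f1, accuracy = r$accuracy)
  }
  b <- metrics_of(base)
  methods <- setdiff(names(reports), "baseline")
  rows <- lapply(methods, function(m) {
    v <- metrics_of(reports[[m]])
    d <- v - b
    eff <- ifelse(d > epsilon, "positive",
                  ifelse(d < -epsilon, "negative", "negligible"))
    data.frame(method = m, t(v), t(stats::setNames(d, paste0("delta_", names(d)))),
               t(stats::setNames(eff, paste0("effect_", names(d)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA front end fitted on the training split
#'
#' Projects train and test onto the leading principal components of the
#' training data (centering with training means only, no scaling), the usual
#' dimensionality condenser in front of ensemble learners.
#'
#' @param train,test `ExpressionDataset`s with identical gene ids (`test`
#'   may be `NULL`).
#' @param n_components number of components (default 50); must not exceed
#'   `min(n_train - 1, n_genes)`.
#' @return list with reduced `train` and `test` datasets (features `PC1..`).
#' @export
pca_reduce <- function(train, test = NULL, n_components = 50) {
  limit <- min(n_samples(train) - 1L, n_genes(train))
  if (n_components > limit) {
    stop("n_components (", n_components, ") exceeds min(samples-1, genes) = ",
         limit)
  }
  pc <- stats::prcomp(train$matrix, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  ids <- paste0("PC", seq_len(n_components))
  tr <- expression_dataset(pc$x[, seq_len(n_components), drop = FALSE],
                           train$labels, gene_ids = ids,
                           sample_ids = train$sample_ids)
  te <- NULL
  if (!is.null(test)) {
    proj <- stats::predict(pc, test$matrix)[, seq_len(n_components), drop = FALSE]
    te <- expression_dataset(proj, test$labels, gene_ids = ids,
                             sample_ids = test$sample_ids)
  }
  list(train = tr, test = te)
}
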