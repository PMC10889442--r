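#' Declarative pipeline configuration
#'
#' Captures every tunable of the end-to-end pipeline in one validated,
#' serializable object: normalization scope, oversampler, gene selector,
#' stage order, optional PCA front end, classification backend and the root
#' seed from which every stage derives its own RNG stream. Unknown fields
#' are rejected.
#'
#' @param normalize_scope `"train"` (default, leakage-safe), `"full"` or
#'   `"none"`.
#' @param oversampler `NULL` (baseline) or a list with `method` in
#'   `smote|b1|b2|svm|kmeans` plus optional variant arguments (`k`, `m`,
#'   `n_clusters`, ...).
#' @param selector `NULL` or a list with `method` in `chis|ig|chisig`, the
#'   top-N size `n`, and optional `disc` (`"mdl"`/`"equal_width"`) and
#'   `max_bins`.
#' @param select_before_oversample stage order flag; default `FALSE`
#'   (oversample first, then select on the augmented training data).
#' @param pca `NULL` or the number of principal components to keep.
#' @param backend a [classifier_config()] (default the k-NN voting ensemble).
#' @param seed root integer seed.
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(normalize_scope = c("train", "full", "none"),
                            oversampler = NULL, selector = NULL,
                            select_before_oversample = FALSE, pca = NULL,
                            backend = classifier_config("knn_vote"),
                            seed = 1L) {
  normalize_scope <- match.arg(normalize_scope)
  if (!is.null(oversampler)) {
    if (!is.list(oversampler) || is.null(oversampler$method)) {
      stop("oversampler must be a list with a 'method' field")
    }
    oversampler$method <- match.arg(oversampler$method,
                                    c("smote", "b1", "b2", "svm", "kmeans"))
    known <- c("method", "k", "m", "n_clusters", "minority_threshold",
               "density_exponent", "svm_regularization", "kernel",
               "allow_duplication")
    bad <- setdiff(names(oversampler), known)
    if (length(bad)) stop("unknown oversampler field(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(selector)) {
    if (!is.list(selector) || is.null(selector$method) || is.null(selector$n)) {
      stop("selector must be a list with 'method' and 'n' fields")
    }
    selector$method <- match.arg(selector$method, c("chis", "ig", "chisig"))
    bad <- setdiff(names(selector), c("method", "n", "disc", "max_bins"))
    if (length(bad)) stop("unknown selector field(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!inherits(backend, "ClassifierConfig")) {
    stop("backend must be a classifier_config()")
  }
  structure(
    list(normalize_scope = normalize_scope, oversampler = oversampler,
         selector = selector,
         select_before_oversample = isTRUE(select_before_oversample),
         pca = pca, backend = backend, seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

#' Fingerprint of a pipeline configuration
#'
#' Serializes the configuration to canonical JSON and returns it together
#' with a short content hash, so every report and artifact can be traced to
#' the exact configuration that produced it.
#'
#' @param config a `PipelineConfig`.
#' @return list with `json` and `hash`.
#' @export
config_fingerprint <- function(config) {
  x <- unclass(config)
  x$backend <- list(backend = config$backend$backend,
                    params = config$backend$params)
  json <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                        null = "null"))
  ch <- utf8ToInt(json)
  hash <- sprintf("%08x", sum(ch * (seq_along(ch) %% 97 + 1)) %% 4294967291)
  list(json = json, hash = hash)
}

#' Run the full pipeline on one dataset
#'
#' Executes the configured stages (normalize, oversample, select, classify,
#' evaluate) under either a fixed holdout split or stratified
#' cross-validation, and optionally writes the report (JSON), the selected
#' gene set (one id per line), the oversampling provenance (TSV) and a
#' per-stage log to `out_dir`. Every output embeds the configuration
#' fingerprint.
#'
#' @param config a [pipeline_config()].
#' @param data a labeled `ExpressionDataset`.
#' @param train_idx fixed holdout training indices (mutually exclusive with
#'   `folds`).
#' @param folds cross-validation fold count (default 10 when `train_idx` is
#'   missing).
#' @param out_dir optional output directory for artifacts.
#' @return the `EvaluationReport`, with `$artifacts` naming any files
#'   written.
#' @export
run_pipeline <- function(config, data, train_idx = NULL, folds = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(train_idx) && !is.null(folds)) {
    stop("give either train_idx (holdout) or folds (CV), not both")
  }
  t0 <- Sys.time()
  log <- character(0)
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                           stage, msg))
  }
  note("setup", sprintf("%d samples x %d genes, seed %d, config %s",
                        n_samples(data), n_genes(data), config$seed,
                        config_fingerprint(config)$hash))
  report <- tryCatch({
    if (!is.null(train_idx)) {
      split <- fixed_holdout_split(data, train_idx)
      note("evaluate", sprintf("holdout %d/%d", n_samples(split$train),
                               n_samples(split$test)))
      evaluate_holdout(config, split$train, split$test)
    } else {
      folds <- folds %||% 10
      note("evaluate", sprintf("%d-fold stratified CV", folds))
      cross_validate(config, data, folds = folds, seed = config$seed)
    }
  }, error = function(e) {
    stop("pipeline failed in stage [evaluate]: ", conditionMessage(e),
         call. = FALSE)
  })
  note("done", sprintf("accuracy %.2f%% (%.1fs)", report$accuracy,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- report$fingerprint %||% config_fingerprint(config)
    paths <- list(report = file.path(out_dir, "report.json"),
                  genes = file.path(out_dir, "genes.txt"),
                  provenance = file.path(out_dir, "provenance.tsv"),
                  log = file.path(out_dir, "pipeline.log"))
    jsonlite::write_json(
      list(fingerprint = fp,
           accuracy = report$accuracy, weighted = report$weighted,
           per_class = report$per_class,
           fold_accuracy = report$fold_accuracy,
           confusion = as.data.frame(report$confusion$table)),
      paths$report, auto_unbox = TRUE, digits = NA, null = "null")
    sel <- report$selected_genes %||%
      unique(unlist(lapply(report$folds, function(f) f$selected_genes)))
    writeLines(c(paste0("# fingerprint ", fp$hash), sel %||% character(0)),
               paths$genes)
    prov <- report$provenance %||%
      do.call(rbind, lapply(report$folds, function(f) f$provenance))
    if (is.null(prov)) {
      prov <- data.frame(synthetic_id = character(0))
    }
    utils::write.table(prov, paths$provenance, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    writeLines(c(paste0("# fingerprint ", fp$hash), log), paths$log)
    report$artifacts <- paths
  }
  report$log <- log
  report
}

#' Oversampler x backend benchmark grid
#'
#' Runs every combination of the requested oversamplers (plus the
#' no-oversampling baseline) and backends on one dataset, reusing the
#' baseline report of each backend for the effect comparison. This mirrors
#' the usual empirical layout for assessing how much each resampler helps
#' each ensemble learner.
#'
#' @param data a labeled `ExpressionDataset`.
#' @param backends character vector of backend tags (see
#'   [classifier_config()]).
#' @param oversamplers character vector of oversampler names; `"baseline"`
#'   rows are added automatically.
#' @param base_config a [pipeline_config()] supplying the shared stages
#'   (normalization, selector, PCA, seed); its oversampler/backend fields
#'   are overridden cell by cell.
#' @param folds CV folds per cell (default 10).
#' @param epsilon effect threshold passed to [compare_to_baseline()].
#' @return list with `reports` (backend -> oversampler -> report) and
#'   `effects` (backend -> effect data frame).
#' @export
run_benchmark_grid <- function(data,
                               backends = c("knn_vote", "random_forests"),
                               oversamplers = c("smote", "b1", "b2", "svm",
                                                "kmeans"),
                               base_config = pipeline_config(pca = NULL),
                               folds = 10, epsilon = 0.5) {
  oversamplers <- setdiff(oversamplers, "baseline")
  reports <- list()
  effects <- list()
  for (bk in backends) {
    reports[[bk]] <- list()
    for (os in c("baseline", oversamplers)) {
      cfg <- base_config
      cfg$backend <- classifier_config(bk)
      cfg$oversampler <- if (os == "baseline") NULL else list(method = os)
      reports[[bk]][[os]] <- cross_validate(cfg, data, folds = folds,
                                            seed = base_config$seed)
    }
    effects[[bk]] <- compare_to_baseline(reports[[bk]], epsilon = epsilon)
  }
  list(reports = reports, effects = effects)
}
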