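#' Single k-nearest-neighbour prediction
#'
#' Predicts the plurality class among the k nearest training samples under
#' the Euclidean metric. Distance ties break by training index order; vote
#' ties break in favour of the class of the nearest neighbour among the tied
#' classes, so every prediction is deterministic.
#'
#' @param train a labeled `ExpressionDataset`.
#' @param query numeric matrix of query rows (or a single vector), aligned to
#'   the training genes.
#' @param k neighbourhood size (default 1); must not exceed the training size.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @return factor of predicted labels (levels of the training labels).
#' @export
knn_predict <- function(train, query, k = 1, metric = "euclidean") {
  match.arg(metric, "euclidean")
  if (n_samples(train) == 0L) stop("empty training set")
  if (k > n_samples(train)) stop("k (", k, ") exceeds training size")
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  d <- cross_dist(query, train$matrix)
  y <- train$labels
  preds <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(d[i, ], seq_len(ncol(d)))
    preds[i] <- .plurality(as.character(y)[ord[seq_len(k)]])
  }
  factor(preds, levels = levels(y))
}

# Plurality over an ordered vote vector; ties go to the first vote (in the
# given order) whose class is among the tied leaders.
.plurality <- function(votes) {
  tab <- table(votes)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) == 1L) return(cand)
  votes[votes %in% cand][1]
}

#' Majority vote over ordered predictions
#'
#' Returns the most frequent label; ties break in favour of the earliest
#' prediction in the vector (by convention the smallest-k, most local model).
#'
#' @param predictions ordered vector of class labels (>= 1).
#' @return the winning label (character scalar).
#' @export
vote <- function(predictions) {
  predictions <- as.character(predictions)
  if (length(predictions) == 0L) stop("no predictions to vote over")
  .plurality(predictions)
}

#' Homogeneous 1/3/5-NN majority-voting ensemble
#'
#' Fits nearest-neighbour models for each requested k (default 1, 3, 5) on a
#' shared training set and metric; predictions are combined per query by
#' majority vote, with ties resolved by the smallest-k model. Infeasible k
#' values (larger than the training size) are dropped with a warning.
#'
#' @param train a labeled `ExpressionDataset`.
#' @param k_values odd, distinct, ascending neighbourhood sizes.
#' @param metric distance metric tag (`"euclidean"`).
#' @return a `KnnVoteEnsemble`.
#' @export
knn_vote_ensemble <- function(train, k_values = c(1, 3, 5),
                              metric = "euclidean") {
  k_values <- as.integer(k_values)
  if (any(k_values %% 2L == 0L)) stop("k values must be odd")
  if (anyDuplicated(k_values) || is.unsorted(k_values, strictly = TRUE)) {
    stop("k values must be distinct and ascending")
  }
  n <- n_samples(train)
  if (n == 0L) stop("empty training set")
  feasible <- k_values[k_values <= n]
  if (length(feasible) < length(k_values)) {
    warning("dropping k value(s) ",
            paste(setdiff(k_values, feasible), collapse = ", "),
            " (training size ", n, ")")
    k_values <- feasible
  }
  structure(list(train = train, k_values = k_values, metric = metric),
            class = "KnnVoteEnsemble")
}

#' Predict with the k-NN voting ensemble
#'
#' Identical to voting over the individual [knn_predict()] outputs: for each
#' query, every base model votes and the plurality wins (ties to the
#' smallest k).
#'
#' @param model a [knn_vote_ensemble()].
#' @param queries numeric matrix of query rows (or `ExpressionDataset`).
#' @return factor of predicted labels.
#' @export
knn_ensemble_predict <- function(model, queries) {
  stopifnot(inherits(model, "KnnVoteEnsemble"))
  if (inherits(queries, "ExpressionDataset")) queries <- queries$matrix
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  base <- vapply(model$k_values, function(k) {
    as.character(knn_predict(model$train, queries, k = k, metric = model$metric))
  }, character(nrow(queries)))
  if (!is.matrix(base)) base <- matrix(base, nrow = nrow(queries))
  preds <- apply(base, 1, vote)
  factor(preds, levels = levels(model$train$labels))
}

#' @export
predict.KnnVoteEnsemble <- function(object, newdata, ...) {
  knn_ensemble_predict(object, newdata)
}

#' Hidden-layer size for the single-hidden-layer MLP
#'
#' The sizing rule sets the number of hidden neurons to the rounded
#' (half-up) average of the input and output dimensions:
#' `round((n_features + n_classes) / 2)`. For 300 input genes and 7 classes
#' this gives 154 neurons.
#'
#' @param n_features number of input attributes (>= 1).
#' @param n_classes number of output classes (>= 1).
#' @return integer neuron count.
#' @examples
#' mlp_hidden_units(300, 7)  # 154
#' @export
mlp_hidden_units <- function(n_features, n_classes) {
  if (n_features < 1 || n_classes < 1) stop("both dimensions must be >= 1")
  as.integer(floor((n_features + n_classes) / 2 + 0.5))
}

# Shipped hyperparameter presets (ensemble settings follow the common
# scikit-learn/WEKA defaults used in comparable benchmark studies).
.backend_presets <- list(
  knn_vote = list(k_values = c(1, 3, 5), metric = "euclidean"),
  random_forests = list(n_estimators = 100, criterion = "gini",
                        min_samples_split = 2, bootstrap = TRUE),
  mlp = list(hidden_units = NULL, learning_rate = 0.3, momentum = 0.2,
             maxit = 200),
  smo_svm = list(kernel = "poly", C = 1, degree = 3),
  bagging = list(n_estimators = 10, max_samples = 1.0),
  stacking = list(svm_C = 1, svm_gamma = NULL),
  voting_hard = list(svm_C = 1, svm_gamma = NULL),
  voting_soft = list(svm_C = 1, svm_gamma = NULL),
  gradient_boosting = list(n_estimators = 100, learning_rate = 0.3,
                           max_depth = 6)
)

#' Classifier configuration with validated hyperparameters
#'
#' Backends: the package's own `knn_vote` ensemble plus configured learners
#' from established libraries (`random_forests`, `mlp`, `smo_svm`, `bagging`,
#' `stacking`, `voting_hard`, `voting_soft`, `gradient_boosting`).
#' Hyperparameter names are validated against the backend's preset schema;
#' unknown names are rejected. The `smo_svm` kernel `"puk_approx"` maps to a
#' radial-basis kernel (the Pearson-universal kernel of WEKA has no
#' counterpart in common libraries). The `mlp` preset applies the
#' [mlp_hidden_units()] sizing rule when `hidden_units` is `NULL`; its
#' `learning_rate`/`momentum` fields document the reference backprop
#' configuration but are not consumed by the quasi-Newton optimizer used
#' here.
#'
#' @param backend backend tag.
#' @param params named list of hyperparameter overrides.
#' @return a `ClassifierConfig`.
#' @export
classifier_config <- function(backend = names(.backend_presets),
                              params = list()) {
  backend <- match.arg(backend)
  preset <- .backend_presets[[backend]]
  bad <- setdiff(names(params), names(preset))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for backend '", backend, "': ",
         paste(bad, collapse = ", "))
  }
  preset[names(params)] <- params
  # numeric hyperparameters are stored as doubles so that a config
  # round-trips through JSON to an identical object
  for (nm in names(preset)) {
    if (is.numeric(preset[[nm]])) preset[[nm]] <- as.numeric(preset[[nm]])
  }
  structure(list(backend = backend, params = preset),
            class = "ClassifierConfig")
}

#' Serialize / restore a classifier configuration
#'
#' @param config a `ClassifierConfig`.
#' @return `config_to_json`: a JSON string; `config_from_json`: the restored
#'   `ClassifierConfig` (hyperparameters identical to the original).
#' @export
config_to_json <- function(config) {
  jsonlite::toJSON(list(backend = config$backend, params = config$params),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname config_to_json
#' @param json a JSON string from [config_to_json()].
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  classifier_config(x$backend, as.list(x$params))
}

# rpart/nnet need syntactic feature names; map gene ids to f1..fp.
.feature_frame <- function(mat) {
  df <- as.data.frame(mat)
  names(df) <- paste0("f", seq_len(ncol(mat)))
  df
}

#' Fit a configured classification backend
#'
#' Routes `knn_vote` to the package's own ensemble and every other tag to an
#' established learner library with the configured hyperparameters:
#' random forests ([randomForest::randomForest()], 100 gini trees by
#' default), a single-hidden-layer MLP ([nnet::nnet()], softmax output,
#' hidden size from the sizing rule), a C = 1 SVM with polynomial or RBF
#' kernel and one-vs-one multiclass ([e1071::svm()]), bootstrap-aggregated
#' decision trees ([rpart::rpart()]), stacking and hard/soft voting over an
#' SVM + decision tree + multinomial-logistic base trio, and gradient
#' boosted trees ([xgboost::xgboost()]).
#'
#' @param config a [classifier_config()].
#' @param train a labeled `ExpressionDataset`.
#' @param seed integer seed for stochastic backends.
#' @return a fitted `geneximb_model`.
#' @export
fit_backend <- function(config, train, seed = 1L) {
  stopifnot(inherits(config, "ClassifierConfig"))
  p <- config$params
  X <- train$matrix
  y <- droplevels(train$labels)
  K <- nlevels(y)
  fit <- withr::with_seed(stage_seed(seed, paste0("backend_", config$backend)), {
    switch(config$backend,
      knn_vote = knn_vote_ensemble(train, k_values = p$k_values,
                                   metric = p$metric),
      random_forests = randomForest::randomForest(
        x = X, y = y, ntree = p$n_estimators),
      mlp = {
        size <- p$hidden_units %||% mlp_hidden_units(ncol(X), K)
        nnet::nnet(X, nnet::class.ind(y), size = size, softmax = TRUE,
                   maxit = p$maxit, MaxNWts = 1e7, trace = FALSE)
      },
      smo_svm = {
        kern <- switch(p$kernel, poly = "polynomial", puk_approx = "radial",
                       p$kernel)
        e1071::svm(X, y, kernel = kern, cost = p$C,
                   degree = p$degree %||% 3, scale = FALSE)
      },
      bagging = {
        df <- .feature_frame(X)
        df$.y <- y
        n <- nrow(df)
        lapply(seq_len(p$n_estimators), function(b) {
          idx <- sample.int(n, size = max(1L, round(p$max_samples * n)),
                            replace = TRUE)
          rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class")
        })
      },
      stacking = ,
      voting_hard = ,
      voting_soft = {
        df <- .feature_frame(X)
        soft <- config$backend == "voting_soft"
        bases <- list(
          svm = e1071::svm(X, y, kernel = "radial", cost = p$svm_C,
                           gamma = p$svm_gamma %||% (1 / ncol(X)),
                           scale = FALSE, probability = soft),
          tree = rpart::rpart(y ~ ., data = cbind(df, y = y),
                              method = "class"),
          logit = nnet::multinom(y ~ ., data = cbind(df, y = y),
                                 maxit = 200, MaxNWts = 1e7, trace = FALSE))
        meta <- NULL
        if (config$backend == "stacking") {
          mf <- data.frame(
            b_svm = factor(as.character(stats::predict(bases$svm, X)),
                           levels = levels(y)),
            b_tree = factor(as.character(
              stats::predict(bases$tree, df, type = "class")),
              levels = levels(y)),
            b_logit = factor(as.character(stats::predict(bases$logit, df)),
                             levels = levels(y)),
            y = y)
          meta <- nnet::multinom(y ~ ., data = mf, maxit = 200,
                                 MaxNWts = 1e7, trace = FALSE)
        }
        list(bases = bases, meta = meta)
      },
      gradient_boosting = xgboost::xgboost(
        X, y, nrounds = p$n_estimators, learning_rate = p$learning_rate,
        max_depth = p$max_depth, nthreads = 1, verbosity = 0),
      stop("unknown backend tag '", config$backend, "'"))
  })
  structure(list(backend = config$backend, fit = fit, config = config,
                 classes = levels(y), n_features = ncol(X)),
            class = "geneximb_model")
}

#' Predict with a fitted backend
#'
#' @param model a `geneximb_model` from [fit_backend()].
#' @param queries numeric matrix (or `ExpressionDataset`) aligned to the
#'   training genes.
#' @return factor of predicted labels.
#' @export
predict_backend <- function(model, queries) {
  stopifnot(inherits(model, "geneximb_model"))
  if (inherits(queries, "ExpressionDataset")) queries <- queries$matrix
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  queries <- as.matrix(queries)
  lv <- model$classes
  out <- switch(model$backend,
    knn_vote = as.character(knn_ensemble_predict(model$fit, queries)),
    random_forests = as.character(stats::predict(model$fit, queries)),
    mlp = {
      pr <- stats::predict(model$fit, queries)
      colnames(pr)[max.col(pr, ties.method = "first")]
    },
    smo_svm = as.character(stats::predict(model$fit, queries)),
    bagging = {
      df <- .feature_frame(queries)
      votes <- vapply(model$fit, function(t) {
        as.character(stats::predict(t, df, type = "class"))
      }, character(nrow(queries)))
      if (!is.matrix(votes)) votes <- matrix(votes, nrow = nrow(queries))
      apply(votes, 1, vote)
    },
    stacking = {
      df <- .feature_frame(queries)
      mf <- data.frame(
        b_svm = factor(as.character(stats::predict(model$fit$bases$svm, queries)),
                       levels = lv),
        b_tree = factor(as.character(
          stats::predict(model$fit$bases$tree, df, type = "class")),
          levels = lv),
        b_logit = factor(as.character(stats::predict(model$fit$bases$logit, df)),
                         levels = lv))
      as.character(stats::predict(model$fit$meta, mf))
    },
    voting_hard = {
      df <- .feature_frame(queries)
      votes <- cbind(
        as.character(stats::predict(model$fit$bases$svm, queries)),
        as.character(stats::predict(model$fit$bases$tree, df, type = "class")),
        as.character(stats::predict(model$fit$bases$logit, df)))
      apply(votes, 1, vote)
    },
    voting_soft = {
      df <- .feature_frame(queries)
      pr_svm <- attr(stats::predict(model$fit$bases$svm, queries,
                                    probability = TRUE), "probabilities")
      pr_svm <- pr_svm[, lv, drop = FALSE]
      pr_tree <- stats::predict(model$fit$bases$tree, df, type = "prob")
      pr_tree <- pr_tree[, lv, drop = FALSE]
      pr_log <- stats::predict(model$fit$bases$logit, df, type = "probs")
      if (is.null(dim(pr_log))) {
        pr_log <- if (length(lv) == 2L) cbind(1 - pr_log, pr_log)
          else matrix(pr_log, nrow = nrow(queries), byrow = FALSE)
        colnames(pr_log) <- lv
      }
      pr <- (pr_svm + pr_tree + pr_log[, lv, drop = FALSE]) / 3
      lv[max.col(pr, ties.method = "first")]
    },
    gradient_boosting = as.character(stats::predict(model$fit, queries,
                                                    type = "class")))
  factor(out, levels = lv)
}
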