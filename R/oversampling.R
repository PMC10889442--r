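#' Balance-to-majority resampling plan
#'
#' Raises every class's target training count to the majority class's count,
#' so that after oversampling all classes are represented equally at the
#' original majority level. The number of synthetic samples needed per class
#' is `target - original count`.
#'
#' @param dist a `ClassDistribution` (or an `ExpressionDataset`, whose
#'   distribution is computed first).
#' @return a `ResamplingPlan` with `target_counts` and `original_counts`.
#' @examples
#' d <- class_distribution(factor(c(rep("ALL", 27), rep("AML", 11))))
#' plan_balance_to_majority(d)  # targets ALL:27, AML:27
#' @export
plan_balance_to_majority <- function(dist) {
  if (inherits(dist, "ExpressionDataset")) dist <- class_distribution(dist)
  stopifnot(inherits(dist, "ClassDistribution"))
  counts <- dist$counts
  if (length(counts) < 2L) {
    stop("balance-to-majority needs at least two classes")
  }
  structure(
    list(target_counts = stats::setNames(rep.int(max(counts), length(counts)),
                                         names(counts)),
         original_counts = counts),
    class = "ResamplingPlan"
  )
}

#' @export
print.ResamplingPlan <- function(x, ...) {
  cat("ResamplingPlan (synthetic samples needed):\n")
  print(x$target_counts - x$original_counts)
  invisible(x)
}

# Per-class synthetic-sample needs from a plan, validated against the data.
.plan_needs <- function(train, plan) {
  stopifnot(inherits(plan, "ResamplingPlan"))
  dist <- class_distribution(train)
  classes <- names(dist$counts)
  if (!all(classes %in% names(plan$target_counts))) {
    stop("plan is missing target counts for class(es): ",
         paste(setdiff(classes, names(plan$target_counts)), collapse = ", "))
  }
  targets <- plan$target_counts[classes]
  if (any(targets < dist$counts)) {
    stop("plan target below original count for class(es): ",
         paste(classes[targets < dist$counts], collapse = ", "))
  }
  stats::setNames(as.integer(targets - dist$counts), classes)
}

# Generation context shared by every variant.
.os_context <- function(train) {
  list(X = train$matrix,
       lab = as.character(train$labels),
       n = n_samples(train),
       dmat = as.matrix(stats::dist(train$matrix)))
}

# Plain SMOTE generation for one class: cycle through the seed rows in index
# order, draw one of the k nearest same-pool neighbours and a gap, one record
# per needed sample. `gap_max` < 1 is used for majority-directed Borderline-B2
# draws; `sign` -1 flags extrapolation (SVM-SMOTE), stored as a negative gap.
.gen_interpolations <- function(ctx, seed_rows, neighbor_pool, need, k,
                                gap_max = 1, sign = rep(1, need),
                                cluster = NA_integer_) {
  recs <- vector("list", need)
  ns <- length(seed_rows)
  for (i in seq_len(need)) {
    s <- seed_rows[((i - 1L) %% ns) + 1L]
    nn <- nn_in_pool(ctx$dmat, s, neighbor_pool, k)
    if (length(nn) == 0L) stop("no neighbours available for seed sample ", s)
    nb <- nn[sample.int(length(nn), 1L)]
    gap <- stats::runif(1, 0, gap_max) * sign[i]
    recs[[i]] <- list(seed = s, neighbor = nb, gap = gap, cluster = cluster)
  }
  recs
}

# Validate minority size / clamp k, shared by all variants.
.check_minority <- function(min_rows, k, class, allow_duplication) {
  nmin <- length(min_rows)
  if (nmin < 2L) {
    if (allow_duplication) return(0L)  # caller duplicates instead
    stop("class '", class, "' has a single sample; SMOTE needs at least 2 ",
         "(set allow_duplication = TRUE to fall back to plain duplication)")
  }
  k_eff <- min(k, nmin - 1L)
  if (k_eff < k) {
    warning("k = ", k, " clamped to ", k_eff, " for class '", class,
            "' (only ", nmin, " samples)")
  }
  k_eff
}

# Duplication records for a 1-sample class (allow_duplication fallback):
# seed == neighbour, gap 0, so the replay identity still holds.
.gen_duplicates <- function(row, need) {
  lapply(seq_len(need), function(i) {
    list(seed = row, neighbor = row, gap = 0, cluster = NA_integer_)
  })
}

# Assemble the augmented dataset + provenance from per-class record lists.
# Original samples are kept first and bitwise untouched.
.assemble_oversample <- function(train, recs_by_class, method) {
  classes <- names(recs_by_class)
  rows <- list(); prov <- list()
  for (cls in classes) {
    recs <- recs_by_class[[cls]]
    if (length(recs) == 0L) next
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      v <- train$matrix[r$seed, ] +
        r$gap * (train$matrix[r$neighbor, ] - train$matrix[r$seed, ])
      id <- sprintf("syn_%s_%03d", cls, i)
      rows[[id]] <- v
      prov[[id]] <- data.frame(
        synthetic_id = id, class = cls,
        seed_index = r$seed, neighbor_index = r$neighbor, gap = r$gap,
        seed_id = train$sample_ids[r$seed],
        neighbor_id = train$sample_ids[r$neighbor],
        neighbor_class = as.character(train$labels)[r$neighbor],
        cluster = r$cluster, method = method,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    syn <- do.call(rbind, rows)
    aug <- expression_dataset(
      rbind(train$matrix, syn),
      c(as.character(train$labels),
        unlist(lapply(classes, function(cl) rep(cl, length(recs_by_class[[cl]]))))),
      gene_ids = train$gene_ids,
      sample_ids = c(train$sample_ids, names(rows)))
    provenance <- do.call(rbind, prov)
    rownames(provenance) <- NULL
  } else {
    aug <- train
    provenance <- data.frame(synthetic_id = character(0), class = character(0),
                             seed_index = integer(0), neighbor_index = integer(0),
                             gap = numeric(0), seed_id = character(0),
                             neighbor_id = character(0),
                             neighbor_class = character(0),
                             cluster = integer(0), method = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(data = aug, provenance = provenance, method = method),
            class = "OversampleResult")
}

#' @export
print.OversampleResult <- function(x, ...) {
  cat("OversampleResult (", x$method, "): ", nrow(x$provenance),
      " synthetic samples\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Replay synthetic samples from their provenance records
#'
#' Recomputes every synthetic sample as
#' `seed + gap * (neighbor - seed)` from the stored seed index, neighbour
#' index and gap. A negative stored gap encodes SVM-SMOTE extrapolation away
#' from the neighbour; the same formula still reproduces the sample exactly.
#'
#' @param train the original (pre-oversampling) `ExpressionDataset`.
#' @param provenance the provenance data frame of an `OversampleResult`.
#' @return matrix of replayed synthetic rows (one per provenance record).
#' @export
replay_synthetic <- function(train, provenance) {
  out <- matrix(NA_real_, nrow(provenance), n_genes(train),
                dimnames = list(provenance$synthetic_id, train$gene_ids))
  for (i in seq_len(nrow(provenance))) {
    s <- train$matrix[provenance$seed_index[i], ]
    nb <- train$matrix[provenance$neighbor_index[i], ]
    out[i, ] <- s + provenance$gap[i] * (nb - s)
  }
  out
}

#' Synthetic minority oversampling (SMOTE)
#'
#' For every class whose plan target exceeds its count, new samples are
#' created by linear interpolation between a class member (seeds cycle
#' through the class in index order) and one of its k nearest same-class
#' neighbours under the Euclidean metric, with interpolation gap drawn from
#' U(0, 1). Originals are untouched and come first in the augmented dataset;
#' each synthetic sample carries an exact provenance record.
#'
#' In multiclass data every non-majority class is oversampled one-vs-rest:
#' neighbours are searched within the class itself, all other classes pooled
#' as "majority" where a variant needs them.
#'
#' @param train training `ExpressionDataset` (oversample training data only).
#' @param plan a [plan_balance_to_majority()] plan; defaults to
#'   balance-to-majority on `train`.
#' @param k number of nearest neighbours (default 5); clamped with a warning
#'   when a class has fewer than `k + 1` samples.
#' @param seed integer seed for the dedicated gap/neighbour RNG stream.
#' @param allow_duplication fall back to plain duplication for classes with a
#'   single sample instead of erroring (default `FALSE`).
#' @return an `OversampleResult`: `data` (augmented dataset) and `provenance`
#'   (one row per synthetic sample: seed, neighbour, gap).
#' @export
smote <- function(train, plan = plan_balance_to_majority(train), k = 5,
                  seed = 1L, allow_duplication = FALSE) {
  needs <- .plan_needs(train, plan)
  ctx <- .os_context(train)
  recs <- withr::with_seed(stage_seed(seed, "smote"), {
    out <- list()
    for (cls in names(needs)) {
      need <- needs[[cls]]
      if (need == 0L) { out[[cls]] <- list(); next }
      min_rows <- which(ctx$lab == cls)
      k_eff <- .check_minority(min_rows, k, cls, allow_duplication)
      out[[cls]] <- if (k_eff == 0L) {
        .gen_duplicates(min_rows[1], need)
      } else {
        .gen_interpolations(ctx, min_rows, min_rows, need, k_eff)
      }
    }
    out
  })
  .assemble_oversample(train, recs, "smote")
}

#' Categorize minority samples as safe, danger or noise
#'
#' For each sample of the minority class, counts how many of its m nearest
#' neighbours over the whole training set (self excluded, all other classes
#' pooled as majority) belong to the majority: with m' majority neighbours,
#' the sample is `noise` if m' == m, `danger` (borderline) if m/2 <= m' < m,
#' and `safe` if m' < m/2. The danger set seeds Borderline-SMOTE.
#'
#' @param train training `ExpressionDataset`.
#' @param minority_class class whose samples are categorized.
#' @param m neighbourhood size (default 10); clamped to `n - 1`.
#' @return factor (`safe`/`danger`/`noise`) named by sample id, with the
#'   majority-neighbour counts in attribute `m_majority`.
#' @export
classify_neighborhoods <- function(train, minority_class, m = 10) {
  if (m < 1) stop("m must be >= 1")
  ctx <- .os_context(train)
  min_rows <- which(ctx$lab == minority_class)
  if (length(min_rows) == 0L) stop("no samples of class '", minority_class, "'")
  m_eff <- min(m, ctx$n - 1L)
  cat_of <- character(length(min_rows))
  mprime <- integer(length(min_rows))
  for (j in seq_along(min_rows)) {
    i <- min_rows[j]
    nn <- nn_in_pool(ctx$dmat, i, seq_len(ctx$n), m_eff)
    mp <- sum(ctx$lab[nn] != minority_class)
    mprime[j] <- mp
    cat_of[j] <- if (mp == m_eff) "noise"
      else if (mp >= m_eff / 2) "danger"
      else "safe"
  }
  out <- factor(cat_of, levels = c("safe", "danger", "noise"))
  names(out) <- train$sample_ids[min_rows]
  attr(out, "m_majority") <- stats::setNames(mprime, names(out))
  attr(out, "rows") <- min_rows
  out
}

#' Borderline-SMOTE (variants B1 and B2)
#'
#' Like [smote()], but interpolation seeds are drawn only from the danger
#' (borderline) samples identified by [classify_neighborhoods()]. Variant B1
#' interpolates toward the k nearest minority neighbours with gap U(0, 1).
#' Variant B2 additionally directs every second synthetic sample toward one
#' of the seed's nearest majority neighbours with gap U(0, 0.5), keeping it
#' on the minority side of the segment. Classes with an empty danger set fall
#' back to plain SMOTE with a warning.
#'
#' @inheritParams smote
#' @param m neighbourhood size for danger detection (default 10).
#' @param variant `"B1"` or `"B2"`.
#' @return an `OversampleResult`.
#' @export
borderline_smote <- function(train, plan = plan_balance_to_majority(train),
                             k = 5, m = 10, variant = c("B1", "B2"),
                             seed = 1L, allow_duplication = FALSE) {
  variant <- match.arg(variant)
  needs <- .plan_needs(train, plan)
  ctx <- .os_context(train)
  recs <- withr::with_seed(stage_seed(seed, paste0("borderline", variant)), {
    out <- list()
    for (cls in names(needs)) {
      need <- needs[[cls]]
      if (need == 0L) { out[[cls]] <- list(); next }
      min_rows <- which(ctx$lab == cls)
      k_eff <- .check_minority(min_rows, k, cls, allow_duplication)
      if (k_eff == 0L) { out[[cls]] <- .gen_duplicates(min_rows[1], need); next }
      cats <- classify_neighborhoods(train, cls, m)
      danger <- attr(cats, "rows")[cats == "danger"]
      if (length(danger) == 0L) {
        warning("no danger samples for class '", cls,
                "'; falling back to plain SMOTE")
        out[[cls]] <- .gen_interpolations(ctx, min_rows, min_rows, need, k_eff)
        next
      }
      maj_rows <- which(ctx$lab != cls)
      cls_recs <- vector("list", need)
      nd <- length(danger)
      for (i in seq_len(need)) {
        s <- danger[((i - 1L) %% nd) + 1L]
        if (variant == "B2" && i %% 2L == 0L && length(maj_rows) > 0L) {
          nn <- nn_in_pool(ctx$dmat, s, maj_rows, k_eff)
          gap_max <- 0.5
        } else {
          nn <- nn_in_pool(ctx$dmat, s, min_rows, k_eff)
          gap_max <- 1
        }
        nb <- nn[sample.int(length(nn), 1L)]
        cls_recs[[i]] <- list(seed = s, neighbor = nb,
                              gap = stats::runif(1, 0, gap_max),
                              cluster = NA_integer_)
      }
      out[[cls]] <- cls_recs
    }
    out
  })
  .assemble_oversample(train, recs, paste0("borderline_", tolower(variant)))
}

#' SVM-guided SMOTE
#'
#' Fits a soft-margin SVM separating the target class from the rest and uses
#' the target class's support vectors as interpolation seeds. For each seed,
#' if the majority of its m nearest whole-set neighbours belong to other
#' classes the new sample is interpolated toward one of the seed's k nearest
#' same-class neighbours (gap U(0, 1)); otherwise it is extrapolated away
#' from the neighbour, `new = seed + gap * (seed - neighbor)`, expanding the
#' class region. Extrapolations are stored with a negative provenance gap so
#' the single replay formula remains exact. Classes without support vectors
#' fall back to plain SMOTE with a warning.
#'
#' @inheritParams borderline_smote
#' @param svm_regularization soft-margin cost C of the guiding SVM (default 1).
#' @param kernel kernel of the guiding SVM (default `"linear"`).
#' @return an `OversampleResult`.
#' @export
svm_smote <- function(train, plan = plan_balance_to_majority(train), k = 5,
                      m = 10, seed = 1L, svm_regularization = 1,
                      kernel = "linear", allow_duplication = FALSE) {
  needs <- .plan_needs(train, plan)
  ctx <- .os_context(train)
  recs <- withr::with_seed(stage_seed(seed, "svmsmote"), {
    out <- list()
    for (cls in names(needs)) {
      need <- needs[[cls]]
      if (need == 0L) { out[[cls]] <- list(); next }
      min_rows <- which(ctx$lab == cls)
      k_eff <- .check_minority(min_rows, k, cls, allow_duplication)
      if (k_eff == 0L) { out[[cls]] <- .gen_duplicates(min_rows[1], need); next }
      y <- factor(ifelse(ctx$lab == cls, "target", "rest"))
      fit <- e1071::svm(ctx$X, y, kernel = kernel, cost = svm_regularization,
                        scale = FALSE)
      sv_rows <- fit$index[ctx$lab[fit$index] == cls]
      if (length(sv_rows) == 0L) {
        warning("no support vectors in class '", cls,
                "'; falling back to plain SMOTE")
        out[[cls]] <- .gen_interpolations(ctx, min_rows, min_rows, need, k_eff)
        next
      }
      m_eff <- min(m, ctx$n - 1L)
      cls_recs <- vector("list", need)
      nsv <- length(sv_rows)
      for (i in seq_len(need)) {
        s <- sv_rows[((i - 1L) %% nsv) + 1L]
        whole_nn <- nn_in_pool(ctx$dmat, s, seq_len(ctx$n), m_eff)
        crowded <- sum(ctx$lab[whole_nn] != cls) > m_eff / 2
        nn <- nn_in_pool(ctx$dmat, s, min_rows, k_eff)
        nb <- nn[sample.int(length(nn), 1L)]
        g <- stats::runif(1)
        cls_recs[[i]] <- list(seed = s, neighbor = nb,
                              gap = if (crowded) g else -g,
                              cluster = NA_integer_)
      }
      out[[cls]] <- cls_recs
    }
    out
  })
  .assemble_oversample(train, recs, "svm_smote")
}

#' K-means cluster-based SMOTE
#'
#' Clusters the training set with k-means, keeps the clusters dominated by
#' the target class (minority fraction >= `minority_threshold`, with at
#' least two class members), apportions the class's synthetic-sample budget
#' across those clusters proportionally to a sparsity weight (mean pairwise
#' within-cluster distance of class members raised to `density_exponent`,
#' normalized; largest-remainder rounding keeps totals exact), and runs
#' plain SMOTE within each cluster. Sparser clusters thus receive more
#' synthetic samples, filling out thin regions of the class. Classes without
#' an eligible cluster fall back to plain SMOTE with a warning.
#'
#' @inheritParams smote
#' @param n_clusters number of k-means clusters; default
#'   `max(2, min(8, n/2))`.
#' @param minority_threshold minimum within-cluster fraction of the target
#'   class for eligibility (default 0.5).
#' @param density_exponent exponent of the sparsity weight; default
#'   `min(sqrt(n_genes), 2)`.
#' @return an `OversampleResult`; the provenance `cluster` column records the
#'   shared cluster of every seed/neighbour pair.
#' @export
kmeans_smote <- function(train, plan = plan_balance_to_majority(train), k = 5,
                         n_clusters = NULL, minority_threshold = 0.5,
                         density_exponent = NULL, seed = 1L,
                         allow_duplication = FALSE) {
  needs <- .plan_needs(train, plan)
  ctx <- .os_context(train)
  if (is.null(n_clusters)) n_clusters <- max(2L, min(8L, floor(ctx$n / 2)))
  if (is.null(density_exponent)) density_exponent <- min(sqrt(ncol(ctx$X)), 2)
  km <- withr::with_seed(stage_seed(seed, "kmeans"),
                         stats::kmeans(ctx$X, centers = n_clusters,
                                       nstart = 10, iter.max = 100))
  assign <- km$cluster
  recs <- withr::with_seed(stage_seed(seed, "kmeanssmote"), {
    out <- list()
    for (cls in names(needs)) {
      need <- needs[[cls]]
      if (need == 0L) { out[[cls]] <- list(); next }
      min_rows <- which(ctx$lab == cls)
      k_eff <- .check_minority(min_rows, k, cls, allow_duplication)
      if (k_eff == 0L) { out[[cls]] <- .gen_duplicates(min_rows[1], need); next }
      eligible <- integer(0)
      sparsity <- numeric(0)
      for (cl in sort(unique(assign))) {
        members <- which(assign == cl)
        cls_members <- intersect(members, min_rows)
        if (length(cls_members) >= 2L &&
            length(cls_members) / length(members) >= minority_threshold) {
          eligible <- c(eligible, cl)
          d <- ctx$dmat[cls_members, cls_members]
          sparsity <- c(sparsity,
                        mean(d[upper.tri(d)])^density_exponent)
        }
      }
      if (length(eligible) == 0L) {
        warning("no eligible cluster for class '", cls,
                "'; falling back to plain SMOTE")
        out[[cls]] <- .gen_interpolations(ctx, min_rows, min_rows, need, k_eff)
        next
      }
      alloc <- largest_remainder(sparsity, need)
      cls_recs <- list()
      for (j in seq_along(eligible)) {
        if (alloc[j] == 0L) next
        rows_j <- intersect(which(assign == eligible[j]), min_rows)
        kj <- min(k_eff, length(rows_j) - 1L)
        cls_recs <- c(cls_recs,
                      .gen_interpolations(ctx, rows_j, rows_j, alloc[j], kj,
                                          cluster = eligible[j]))
      }
      out[[cls]] <- cls_recs
    }
    out
  })
  res <- .assemble_oversample(train, recs, "kmeans_smote")
  attr(res$provenance, "cluster_assignment") <- assign
  res
}

#' Run a SMOTE-family oversampler by name
#'
#' Dispatcher used by the pipeline: `"smote"`, `"b1"`, `"b2"`, `"svm"` or
#' `"kmeans"`.
#'
#' @inheritParams smote
#' @param method oversampler name.
#' @param ... passed to the chosen variant.
#' @return an `OversampleResult`.
#' @export
oversample <- function(train, method = c("smote", "b1", "b2", "svm", "kmeans"),
                       plan = plan_balance_to_majority(train), k = 5,
                       seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
    smote = smote(train, plan, k = k, seed = seed, ...),
    b1 = borderline_smote(train, plan, k = k, variant = "B1", seed = seed, ...),
    b2 = borderline_smote(train, plan, k = k, variant = "B2", seed = seed, ...),
    svm = svm_smote(train, plan, k = k, seed = seed, ...),
    kmeans = kmeans_smote(train, plan, k = k, seed = seed, ...))
}
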