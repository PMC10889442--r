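#' Construct a labeled expression dataset
#'
#' The basic container used throughout the package: a samples x genes matrix
#' of real-valued microarray intensities together with gene identifiers,
#' sample identifiers and one categorical class label per sample.
#'
#' Validation enforces matching dimensions, unique gene and sample
#' identifiers, and the absence of missing values. Labels are stored as a
#' factor whose levels are sorted by name, which makes every downstream
#' tie-break ("first in class-name order") deterministic.
#'
#' @param matrix numeric matrix, samples as rows and genes as columns.
#' @param labels vector of per-sample class labels (length `nrow(matrix)`).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the matrix column names (or `g0001`-style ids when absent).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix row names (or `s0001`-style ids when absent).
#' @return An object of class `ExpressionDataset` with fields `matrix`,
#'   `gene_ids`, `sample_ids` and `labels`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' ds <- expression_dataset(m, c("A", "A", "B", "B"))
#' class_distribution(ds)
#' @export
expression_dataset <- function(matrix, labels,
                               gene_ids = colnames(matrix),
                               sample_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  p <- ncol(matrix)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%0*d", max(4L, nchar(p)), seq_len(p))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%0*d", max(4L, nchar(n)), seq_len(n))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p) {
    stop("gene_ids length (", length(gene_ids), ") != number of genes (", p, ")")
  }
  if (length(sample_ids) != n) {
    stop("sample_ids length (", length(sample_ids), ") != number of samples (", n, ")")
  }
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of samples (", n, ")")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(matrix)) {
    bad <- which(is.na(matrix), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", sample_ids[bad[1]], "', gene '",
         gene_ids[bad[2]], "' (no imputation requested)")
  }
  if (anyNA(labels)) stop("missing class label(s)")
  dimnames(matrix) <- list(sample_ids, gene_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = factor(as.character(labels))),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset: ", length(x$sample_ids), " samples x ",
      length(x$gene_ids), " genes, ", nlevels(x$labels), " classes\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Number of samples / genes in a dataset
#' @param data an `ExpressionDataset`.
#' @return integer count.
#' @export
n_samples <- function(data) length(data$sample_ids)

#' @rdname n_samples
#' @export
n_genes <- function(data) length(data$gene_ids)

#' Subset a dataset by samples and/or genes
#'
#' @param data an `ExpressionDataset`.
#' @param samples integer indices or sample ids (optional).
#' @param genes integer indices or gene ids (optional).
#' @return the subsetted `ExpressionDataset`; order follows the index vectors.
#' @export
subset_dataset <- function(data, samples = NULL, genes = NULL) {
  si <- if (is.null(samples)) seq_along(data$sample_ids) else samples
  gi <- if (is.null(genes)) seq_along(data$gene_ids) else genes
  if (is.character(si)) si <- match(si, data$sample_ids)
  if (is.character(gi)) gi <- match(gi, data$gene_ids)
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(gi)) stop("unknown gene id(s)")
  expression_dataset(data$matrix[si, gi, drop = FALSE],
                     data$labels[si],
                     gene_ids = data$gene_ids[gi],
                     sample_ids = data$sample_ids[si])
}

#' Load a labeled expression matrix from CSV, TSV or ARFF
#'
#' Delimited files carry one header row of gene identifiers plus one label
#' column; samples are rows. An optional `sample_id` column supplies sample
#' identifiers. ARFF files (WEKA dialect) are read via [foreign::read.arff()];
#' gene attributes must be numeric and the class attribute nominal.
#'
#' Files that store genes as rows can be read with `transpose = TRUE`, in
#' which case the first column holds gene ids, the remaining columns are
#' samples, and the row named by `label_column` holds the class labels.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"arff"`; default guessed from the
#'   file extension.
#' @param label_column name of the class-label column (default `"class"`).
#' @param sample_id_column optional name of a sample-identifier column;
#'   a column literally named `sample_id` is always used when present.
#' @param transpose logical; set `TRUE` for genes-as-rows delimited files.
#' @param impute `"none"` (default: any missing value is an error) or
#'   `"mean"` for per-gene mean imputation.
#' @return an `ExpressionDataset`.
#' @export
load_dataset <- function(path, format = c("auto", "csv", "tsv", "arff"),
                         label_column = "class", sample_id_column = NULL,
                         transpose = FALSE, impute = c("none", "mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", arff = "arff",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "arff") {
    df <- foreign::read.arff(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    if (transpose) {
      raw <- utils::read.table(path, sep = sep, header = TRUE,
                               check.names = FALSE, row.names = 1,
                               stringsAsFactors = FALSE)
      if (!label_column %in% rownames(raw)) {
        stop("label row '", label_column, "' not found in transposed file")
      }
      labels <- unlist(raw[label_column, ], use.names = FALSE)
      raw <- raw[setdiff(rownames(raw), label_column), , drop = FALSE]
      df <- as.data.frame(lapply(as.data.frame(t(raw),
                                               stringsAsFactors = FALSE),
                                 identity),
                          check.names = FALSE)
      df[[label_column]] <- labels
      rownames(df) <- colnames(raw)
      df <- cbind(sample_id = colnames(raw), df)
    } else {
      df <- utils::read.table(path, sep = sep, header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  cn <- names(df)
  dup <- unique(cn[duplicated(cn)])
  dup <- setdiff(dup, label_column)
  if (length(dup)) stop("duplicated gene id(s) in header: ",
                        paste(dup, collapse = ", "))
  if (!label_column %in% cn) {
    stop("label column '", label_column, "' not found (columns: ",
         paste(utils::head(cn, 5), collapse = ", "), ", ...)")
  }
  labels <- as.character(df[[label_column]])
  id_col <- sample_id_column %||% intersect("sample_id", cn)[1]
  sample_ids <- NULL
  if (length(id_col) == 1L && !is.na(id_col) && id_col %in% cn) {
    sample_ids <- as.character(df[[id_col]])
    dup <- unique(sample_ids[duplicated(sample_ids)])
    if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  } else {
    id_col <- NA_character_
  }
  gene_cols <- setdiff(cn, c(label_column, id_col))
  mat <- matrix(NA_real_, nrow(df), length(gene_cols),
                dimnames = list(NULL, gene_cols))
  for (g in gene_cols) {
    v <- df[[g]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1]], "' in gene column '", g,
             "', row ", bad[1])
      }
      v <- vn
    }
    mat[, g] <- v
  }
  if (anyNA(mat)) {
    if (impute == "mean") {
      for (j in which(colSums(is.na(mat)) > 0)) {
        mat[is.na(mat[, j]), j] <- mean(mat[, j], na.rm = TRUE)
      }
    } else {
      bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop("missing value in gene column '", gene_cols[bad[2]], "', row ",
           bad[1], " (use impute = \"mean\" to impute)")
    }
  }
  expression_dataset(mat, labels, gene_ids = gene_cols, sample_ids = sample_ids)
}

#' Write an expression dataset to CSV, TSV or ARFF
#'
#' The written file round-trips through [load_dataset()]: matrix values, gene
#' ids, sample ids and labels are reproduced exactly (a `sample_id` column /
#' attribute is always included).
#'
#' @param data an `ExpressionDataset`.
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"arff"`.
#' @param label_column name to use for the label column (default `"class"`).
#' @return the path, invisibly.
#' @export
write_dataset <- function(data, path, format = c("csv", "tsv", "arff"),
                          label_column = "class") {
  format <- match.arg(format)
  df <- data.frame(sample_id = data$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(data$matrix, check.names = FALSE))
  df[[label_column]] <- data$labels
  if (format == "arff") {
    df$sample_id <- factor(df$sample_id)
    foreign::write.arff(df, path, relation = "expression")
  } else {
    # full double precision so the file round-trips bit-exactly
    for (g in data$gene_ids) df[[g]] <- sprintf("%.17g", df[[g]])
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Fit a per-gene min-max normalization model
#'
#' Records each gene's minimum and maximum on the supplied (training) data so
#' that expression can be rescaled to the unit interval,
#' x' = (x - min) / (max - min). Fitting on training data only avoids test-set
#' leakage; pass the full dataset to mirror a whole-dataset normalization.
#'
#' @param train an `ExpressionDataset`.
#' @param fitted_on marker recorded in the model: `"train"` or `"full"`.
#' @return a `NormalizationModel` with per-gene `min` and `max`.
#' @export
fit_normalizer <- function(train, fitted_on = c("train", "full")) {
  fitted_on <- match.arg(fitted_on)
  if (n_samples(train) == 0L) stop("cannot fit a normalizer on an empty dataset")
  structure(
    list(gene_ids = train$gene_ids,
         min = apply(train$matrix, 2, min),
         max = apply(train$matrix, 2, max),
         fitted_on = fitted_on),
    class = "NormalizationModel"
  )
}

#' Apply a min-max normalization model
#'
#' Maps every value to (x - min) / (max - min) with the model's per-gene
#' statistics. Values from the fitting set land in `[0, 1]`; out-of-range test
#' values are deliberately not clipped and may fall outside that interval.
#' Constant genes (max == min) map to 0, keeping them inert.
#'
#' @param model a `NormalizationModel` from [fit_normalizer()].
#' @param data an `ExpressionDataset` with the same gene ids.
#' @return the normalized `ExpressionDataset`.
#' @export
apply_normalizer <- function(model, data) {
  if (!identical(model$gene_ids, data$gene_ids)) {
    stop("gene ids of the data do not match the normalizer's fitting set")
  }
  rng <- model$max - model$min
  scaled <- sweep(data$matrix, 2, model$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  if (any(rng == 0)) scaled[, rng == 0] <- 0
  expression_dataset(scaled, data$labels, gene_ids = data$gene_ids,
                     sample_ids = data$sample_ids)
}

#' Per-class sample counts with majority and minority classes
#'
#' @param data an `ExpressionDataset` (or a factor of labels).
#' @return a `ClassDistribution`: integer `counts` (named by class, sorted by
#'   class name), `majority_class` and `minority_class`. Ties break by
#'   class-name order.
#' @export
class_distribution <- function(data) {
  labels <- if (inherits(data, "ExpressionDataset")) data$labels else factor(data)
  if (length(labels) == 0L) stop("no labels")
  counts <- table(labels)
  counts <- counts[order(names(counts))]
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts,
         majority_class = names(counts)[counts == max(counts)][1],
         minority_class = names(counts)[counts == min(counts)][1]),
    class = "ClassDistribution"
  )
}

#' @export
print.ClassDistribution <- function(x, ...) {
  cat("ClassDistribution (majority:", x$majority_class,
      "| minority:", x$minority_class, ")\n")
  print(x$counts)
  invisible(x)
}

#' Split a dataset into fixed train and test partitions
#'
#' Mirrors published fixed train/test splits: the given indices form the
#' training set and the remaining samples the test set. The partition is
#' exact and disjoint and label alignment is preserved.
#'
#' @param data an `ExpressionDataset`.
#' @param train_index_set integer sample indices (or sample ids) to train on.
#' @return list with `train` and `test` `ExpressionDataset`s.
#' @export
fixed_holdout_split <- function(data, train_index_set) {
  idx <- train_index_set
  if (is.character(idx)) idx <- match(idx, data$sample_ids)
  idx <- as.integer(idx)
  n <- n_samples(data)
  if (length(idx) == 0L) stop("empty train index set")
  if (anyNA(idx) || any(idx < 1L) || any(idx > n)) {
    stop("train index out of range 1..", n)
  }
  if (anyDuplicated(idx)) stop("duplicated train indices")
  list(train = subset_dataset(data, samples = idx),
       test = subset_dataset(data, samples = setdiff(seq_len(n), idx)))
}
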