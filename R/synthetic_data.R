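#' Specification for a synthetic microarray-like dataset
#'
#' Describes an imbalanced, high-dimensional expression dataset with a known
#' subset of class-informative genes. Informative gene g in class c is drawn
#' from Normal(base_intensity + c * effect_size * noise_sd, noise_sd), where c
#' is the 0-based class index; non-informative genes share the single
#' class-independent distribution Normal(base_intensity, noise_sd). All
#' intensities are clamped at zero so they stay nonnegative like microarray
#' signal. `effect_size` is therefore the between-adjacent-class mean shift in
#' units of the noise standard deviation.
#'
#' @param samples_per_class named integer vector, class name -> sample count
#'   (every count >= 1).
#' @param n_genes total number of genes.
#' @param n_informative number of class-informative genes (<= `n_genes`).
#' @param effect_size mean shift between adjacent classes in noise-sd units
#'   (default 3).
#' @param noise_sd positive noise standard deviation (default 1).
#' @param base_intensity positive baseline intensity (default 10).
#' @param distribution `"normal"` (default) or `"lognormal"` for skewed
#'   intensities (the normal model is exponentiated after scaling by
#'   `log1p(noise_sd) / noise_sd`).
#' @param seed integer seed; identical spec + seed give a bit-identical
#'   dataset.
#' @return a `SyntheticSpec`.
#' @export
synthetic_spec <- function(samples_per_class, n_genes, n_informative,
                           effect_size = 3, noise_sd = 1, base_intensity = 10,
                           distribution = c("normal", "lognormal"), seed = 1L) {
  distribution <- match.arg(distribution)
  if (is.null(names(samples_per_class)) || any(names(samples_per_class) == "")) {
    stop("samples_per_class must be a named vector (class -> count)")
  }
  samples_per_class <- stats::setNames(as.integer(samples_per_class),
                                       names(samples_per_class))
  if (any(samples_per_class < 1L)) stop("every class needs at least 1 sample")
  if (n_informative > n_genes) stop("n_informative (", n_informative,
                                    ") > n_genes (", n_genes, ")")
  if (n_informative < 0L || n_genes < 1L) stop("invalid gene counts")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (base_intensity <= 0) stop("base_intensity must be positive")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  structure(
    list(n_classes = length(samples_per_class),
         samples_per_class = samples_per_class,
         n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         base_intensity = base_intensity, distribution = distribution,
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

#' Generate a synthetic expression dataset with known informative genes
#'
#' Samples are laid out grouped by class in the order the classes appear in
#' the spec. The identities of the informative genes (drawn uniformly over
#' the gene set) are returned as ground truth for selection benchmarks.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (an `ExpressionDataset`) and `truth` (ordered ids
#'   of the informative genes, length `n_informative`).
#' @examples
#' sp <- synthetic_spec(c(maj = 52, min = 9), n_genes = 100, n_informative = 5)
#' gen <- generate_dataset(sp)
#' class_distribution(gen$data)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  p <- spec$n_genes
  counts <- spec$samples_per_class
  n <- sum(counts)
  gene_ids <- sprintf("g%0*d", max(4L, nchar(p)), seq_len(p))
  labels <- rep(names(counts), counts)
  shifts <- rep(seq_along(counts) - 1L, counts) * spec$effect_size * spec$noise_sd
  withr::with_seed(spec$seed, {
    informative <- if (spec$n_informative > 0L) {
      sort(sample.int(p, spec$n_informative))
    } else {
      integer(0)
    }
    mat <- matrix(stats::rnorm(n * p, mean = spec$base_intensity,
                               sd = spec$noise_sd), n, p)
  })
  if (length(informative)) {
    mat[, informative] <- mat[, informative] + shifts
  }
  if (spec$distribution == "lognormal") {
    mat <- exp((mat - spec$base_intensity) * log1p(spec$noise_sd) / spec$noise_sd +
                 log(spec$base_intensity))
  }
  mat <- pmax(mat, 0)
  list(data = expression_dataset(mat, labels, gene_ids = gene_ids),
       truth = gene_ids[informative])
}

#' Synthetic fixtures shaped like four published benchmark datasets
#'
#' Builds four synthetic datasets whose class counts and fixed train/test
#' splits mirror well-known leukemia and colon microarray benchmarks:
#' the 5-class curated leukemia microarray collection (CuMiDa, 64 samples),
#' the 7-class acute lymphoblastic leukemia subtype dataset (327 samples),
#' the binary ALL/AML leukemia dataset (72 samples) and the binary colon
#' tumor dataset (62 samples). Gene counts are reduced (default 500) so the
#' fixtures stay fast; full-scale shapes can be produced directly with
#' [synthetic_spec()].
#'
#' @param n_genes genes per fixture (default 500).
#' @param n_informative informative genes per fixture (default 20).
#' @param effect_size between-class shift in noise-sd units (default 3).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed integer seed.
#' @return named list (`cumida`, `subtype`, `allaml`, `colon`); each element
#'   has `data`, `truth` and `train_idx` (the fixed holdout training indices).
#' @export
make_reference_fixtures <- function(n_genes = 500, n_informative = 20,
                                    effect_size = 3, noise_sd = 1, seed = 1L) {
  shapes <- list(
    cumida = list(
      total = c(AML = 26, Bone_Marrow = 10, Bone_Marrow_CD34 = 8,
                PB = 10, PBSC_CD34 = 10),
      train = c(21, 8, 6, 8, 8)),
    subtype = list(
      total = c(BCR_ABL = 15, E2A_PBX1 = 27, Hyperdiploid = 64, MLL = 20,
                T_ALL = 43, TEL_AML1 = 79, Others = 79),
      train = c(9, 18, 42, 14, 28, 52, 52)),
    allaml = list(total = c(ALL = 47, AML = 25), train = c(27, 11)),
    colon = list(total = c(Tumor = 40, Normal = 22), train = c(28, 15))
  )
  out <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    spec <- synthetic_spec(sh$total, n_genes = n_genes,
                           n_informative = n_informative,
                           effect_size = effect_size, noise_sd = noise_sd,
                           seed = stage_seed(seed, nm))
    gen <- generate_dataset(spec)
    offsets <- c(0L, cumsum(sh$total))
    train_idx <- unlist(lapply(seq_along(sh$total), function(i) {
      offsets[i] + seq_len(sh$train[i])
    }), use.names = FALSE)
    out[[nm]] <- list(data = gen$data, truth = gen$truth,
                      train_idx = as.integer(train_idx))
  }
  out
}
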