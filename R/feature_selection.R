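#' Supervised discretization of expression values
#'
#' Chi-square and information-gain scoring operate on binned expression, so a
#' per-gene discretization model is fitted first. The default is recursive
#' entropy-based binary partitioning with the minimum-description-length
#' (MDL) stopping rule (Fayyad-Irani style): a candidate cut is accepted only
#' when its information gain exceeds `(log2(N-1) + delta) / N` with
#' `delta = log2(3^c - 2) - (c*H(S) - c1*H(S1) - c2*H(S2))`, where c, c1, c2
#' count the classes present in the node and its two halves. Genes for which
#' no cut passes the test collapse to a single bin (score 0 downstream) — on
#' pure-noise genes this is the common outcome, which is exactly the
#' behaviour a zero-threshold filter relies on. The `equal_width` fallback
#' splits each gene's observed range into `max_bins` equal intervals.
#'
#' @param train a labeled `ExpressionDataset`.
#' @param method `"mdl"` (default) or `"equal_width"`.
#' @param max_bins bins for the equal-width method (default 10).
#' @return a `DiscretizationModel`: per-gene strictly increasing cut points
#'   (possibly empty) plus the method tag.
#' @export
discretize <- function(train, method = c("mdl", "equal_width"), max_bins = 10L) {
  method <- match.arg(method)
  y <- as.integer(train$labels)
  K <- nlevels(train$labels)
  cuts <- lapply(seq_along(train$gene_ids), function(j) {
    x <- train$matrix[, j]
    if (method == "mdl") .mdl_cuts(x, y, K) else .ew_cuts(x, max_bins)
  })
  structure(list(cuts = stats::setNames(cuts, train$gene_ids),
                 method = method, gene_ids = train$gene_ids),
            class = "DiscretizationModel")
}

.ew_cuts <- function(x, max_bins) {
  r <- range(x)
  if (r[1] == r[2]) return(numeric(0))
  cuts <- seq(r[1], r[2], length.out = max_bins + 1)[-c(1, max_bins + 1)]
  unique(cuts)
}

# Fayyad-Irani recursive entropy partitioning with MDL stopping.
.mdl_cuts <- function(x, y, K) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(numeric(0))
    xx <- xs[lo:hi]
    yy <- ys[lo:hi]
    # cumulative class counts; candidate boundaries where the value changes
    cmat <- vapply(seq_len(K), function(k) cumsum(yy == k), numeric(n))
    if (!is.matrix(cmat)) cmat <- matrix(cmat, nrow = n)
    cand <- which(xx[-n] < xx[-1])
    if (length(cand) == 0L) return(numeric(0))
    total <- cmat[n, ]
    entS <- entropy_bits(total)
    left <- cmat[cand, , drop = FALSE]
    right <- matrix(total, length(cand), K, byrow = TRUE) - left
    nl <- cand
    nr <- n - cand
    wE <- (nl * row_entropy_bits(left) + nr * row_entropy_bits(right)) / n
    b <- which.min(wE)  # ties: smallest boundary index
    gain <- entS - wE[b]
    c0 <- sum(total > 0)
    c1 <- sum(left[b, ] > 0)
    c2 <- sum(right[b, ] > 0)
    delta <- log2(3^c0 - 2) -
      (c0 * entS - c1 * entropy_bits(left[b, ]) - c2 * entropy_bits(right[b, ]))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    i <- cand[b]
    cut <- (xx[i] + xx[i + 1]) / 2
    c(rec(lo, lo + i - 1L), cut, rec(lo + i, hi))
  }
  rec(1L, length(xs))
}

# Bin index per value given ordered cut points (1-based; no cuts -> all 1).
.bin_values <- function(x, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}

# Shared scorer: per-gene bin x class contingency, then `statistic(O)`.
.score_genes <- function(train, disc, statistic) {
  stopifnot(inherits(disc, "DiscretizationModel"))
  if (!all(train$gene_ids %in% disc$gene_ids)) {
    stop("discretization model does not cover all genes")
  }
  y <- train$labels
  vapply(train$gene_ids, function(g) {
    b <- .bin_values(train$matrix[, g], disc$cuts[[g]])
    if (length(unique(b)) < 2L) return(0)
    O <- table(b, y)
    statistic(unclass(O))
  }, numeric(1))
}

.rank_scores <- function(scores, method, disc_method) {
  ord <- order(-scores, names(scores))
  structure(data.frame(gene_id = names(scores)[ord],
                       score = unname(scores)[ord],
                       rank = seq_along(scores),
                       stringsAsFactors = FALSE),
            class = c("GeneRanking", "data.frame"),
            method = method, discretization = disc_method)
}

#' Rank genes by the chi-square statistic
#'
#' For each gene, builds the bin x class contingency table of the training
#' samples (bins from the supplied discretization) and computes
#' `sum((O - E)^2 / E)` over all cells with positive expected count, where
#' E is the usual independence expectation. Genes collapsing to a single bin
#' score 0. Scores are sorted non-increasing with ties broken by gene id,
#' so the ranking is deterministic.
#'
#' @param train a labeled `ExpressionDataset`.
#' @param disc a [discretize()] model covering all genes of `train`.
#' @return a `GeneRanking` data frame (`gene_id`, `score`, `rank`) with
#'   attribute `method = "chis"`.
#' @export
chi_square_scores <- function(train, disc) {
  scores <- .score_genes(train, disc, function(O) {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O[E > 0] - E[E > 0])^2 / E[E > 0])
  })
  .rank_scores(scores, "chis", disc$method)
}

#' Rank genes by information gain
#'
#' For each gene, `IG = H(class) - H(class | bin)` in bits, with bins from
#' the supplied discretization. Single-bin genes score 0; IG never exceeds
#' the class entropy. Ordering and tie-breaks as in [chi_square_scores()].
#'
#' @inheritParams chi_square_scores
#' @return a `GeneRanking` with attribute `method = "ig"`.
#' @export
info_gain_scores <- function(train, disc) {
  Hy <- entropy_bits(table(train$labels))
  scores <- .score_genes(train, disc, function(O) {
    n <- sum(O)
    nb <- rowSums(O)
    Hy - sum(nb / n * row_entropy_bits(O))
  })
  scores <- pmax(scores, 0)  # guard tiny negative rounding
  .rank_scores(scores, "ig", disc$method)
}

.gene_set <- function(genes, name) {
  structure(list(name = name, genes = as.character(genes)), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Keep genes with strictly positive scores
#'
#' The zero-threshold filter: genes whose ranking score is exactly 0 (single
#' bin, or no association with the class) are excluded; survivors keep the
#' ranking order. Chi-square and information gain are nonnegative, so this
#' is the operative form of a "drop non-positive ranks" rule.
#'
#' @param r a `GeneRanking`.
#' @return a `GeneSet` in ranking order.
#' @export
select_positive <- function(r) {
  stopifnot(inherits(r, "GeneRanking"))
  .gene_set(r$gene_id[r$score > 0], paste0(attr(r, "method"), "_positive"))
}

#' Select the top-N positively scored genes
#'
#' First applies the strictly-positive filter, then keeps the first `n`
#' genes of the ranking. If fewer than `n` genes survive the filter, all
#' survivors are returned with a warning.
#'
#' @param r a `GeneRanking`.
#' @param n number of genes to keep (>= 1).
#' @return a `GeneSet`.
#' @export
select_top_n <- function(r, n) {
  stopifnot(inherits(r, "GeneRanking"), n >= 1)
  pos <- select_positive(r)$genes
  if (length(pos) < n) {
    warning("only ", length(pos), " genes have positive scores (requested ",
            n, "); returning all survivors")
    n <- length(pos)
  }
  .gene_set(utils::head(pos, n), attr(r, "method"))
}

#' Intersect two selected gene sets (the combined ChiSIG selector)
#'
#' Keeps the genes present in both sets, ordered by their rank in the first
#' set. The result can never be larger than the smaller input, which is what
#' makes the combined selector strictly more parsimonious than either
#' individual ranking. An empty intersection triggers a warning since
#' downstream classification needs at least one gene.
#'
#' @param a,b `GeneSet`s selected from the same dataset (conventionally the
#'   chi-square and information-gain selections).
#' @return a `GeneSet` named `"chisig"`.
#' @export
chisig_intersect <- function(a, b) {
  stopifnot(inherits(a, "GeneSet"), inherits(b, "GeneSet"))
  keep <- a$genes[a$genes %in% b$genes]
  if (length(keep) == 0L) {
    warning("empty intersection of gene sets '", a$name, "' and '", b$name, "'")
  }
  .gene_set(keep, "chisig")
}

#' One-call gene selection front end
#'
#' Fits one discretization on the training data, computes the requested
#' ranking(s) and returns the selected `GeneSet`: `"chis"` or `"ig"` select
#' their own top-N; `"chisig"` intersects the two top-N selections (ordered
#' by chi-square rank).
#'
#' @param train a labeled `ExpressionDataset` (typically the - possibly
#'   oversampled - training split).
#' @param method `"chis"`, `"ig"` or `"chisig"`.
#' @param n top-N size per individual ranking.
#' @param disc_method discretization method, see [discretize()].
#' @param max_bins equal-width bin count.
#' @return a `GeneSet` with the rankings in attribute `rankings`.
#' @export
select_genes <- function(train, method = c("chis", "ig", "chisig"), n,
                         disc_method = "mdl", max_bins = 10L) {
  method <- match.arg(method)
  disc <- discretize(train, method = disc_method, max_bins = max_bins)
  rankings <- list()
  if (method %in% c("chis", "chisig")) {
    rankings$chis <- chi_square_scores(train, disc)
  }
  if (method %in% c("ig", "chisig")) {
    rankings$ig <- info_gain_scores(train, disc)
  }
  set <- switch(method,
    chis = select_top_n(rankings$chis, n),
    ig = select_top_n(rankings$ig, n),
    chisig = chisig_intersect(select_top_n(rankings$chis, n),
                              select_top_n(rankings$ig, n)))
  attr(set, "rankings") <- rankings
  set
}
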