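# Shared fixtures and independent brute-force oracles.
# The oracles deliberately recompute everything from first principles
# (explicit contingency tables, exhaustive distance sorts) so they share no
# code with the implementation paths they check.

tiny_dataset <- function() {
  m <- matrix(c(2, 1, 0,
                4, 2, 0,
                6, 9, 1,
                8, 10, 1), nrow = 4, byrow = TRUE)
  expression_dataset(m, c("A", "A", "B", "B"),
                     gene_ids = c("g1", "g2", "g3"),
                     sample_ids = c("s1", "s2", "s3", "s4"))
}

random_dataset <- function(n = 30, p = 10, classes = c(A = 18, B = 12),
                           seed = 42) {
  gen <- generate_dataset(synthetic_spec(classes, n_genes = p,
                                         n_informative = min(3, p),
                                         effect_size = 2, seed = seed))
  gen$data
}

# chi-square statistic of a binned gene, by explicit contingency enumeration
brute_chi2 <- function(bins, labels) {
  bl <- sort(unique(bins)); cl <- sort(unique(as.character(labels)))
  if (length(bl) < 2) return(0)
  O <- matrix(0, length(bl), length(cl))
  for (i in seq_along(bins)) {
    O[match(bins[i], bl), match(as.character(labels)[i], cl)] <-
      O[match(bins[i], bl), match(as.character(labels)[i], cl)] + 1
  }
  N <- sum(O)
  stat <- 0
  for (r in seq_along(bl)) for (c in seq_along(cl)) {
    E <- sum(O[r, ]) * sum(O[, c]) / N
    if (E > 0) stat <- stat + (O[r, c] - E)^2 / E
  }
  stat
}

# information gain in bits, by explicit entropy sums
brute_ig <- function(bins, labels) {
  labels <- as.character(labels)
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + mean(sel) * H(labels[sel])
  }
  H(labels) - cond
}

# k-NN by exhaustive distance sort with the package's stated tie rules
brute_knn <- function(train_mat, train_lab, q, k) {
  d <- sqrt(colSums((t(train_mat) - q)^2))
  ord <- order(d, seq_along(d))
  votes <- as.character(train_lab)[ord[seq_len(k)]]
  tab <- table(votes)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) == 1) return(cand)
  votes[votes %in% cand][1]
}

# original rows of an augmented dataset (originals are always first)
original_block <- function(result, train) {
  result$data$matrix[seq_len(n_samples(train)), , drop = FALSE]
}

synthetic_block <- function(result, train) {
  result$data$matrix[-seq_len(n_samples(train)), , drop = FALSE]
}
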