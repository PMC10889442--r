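# Internal helpers shared across modules.

# Derive a per-stage RNG seed from one root seed so that the randomness of one
# stage (fold assignment, gap draws, backend fitting) never perturbs another.
# Kept below 2^31 - 19 so the result is always a valid R integer seed.
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((abs(root) %% 2147483629 * 7919 + h * 104729) %% 2147483629)
}

# Euclidean cross-distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Shannon entropy in bits of a vector of nonnegative counts.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# Row-wise entropy in bits of a matrix of counts (each row one distribution).
# Rows must have positive totals.
row_entropy_bits <- function(m) {
  n <- rowSums(m)
  t <- m * log2(pmax(m, 1))  # m * log2(m), with 0*log2(0) := 0
  log2(n) - rowSums(t) / n
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Indices of the k nearest neighbours of point i within `pool` (self excluded),
# given a full pairwise distance matrix. Distance ties break by index order.
nn_in_pool <- function(dmat, i, pool, k) {
  pool <- pool[pool != i]
  if (length(pool) == 0L) return(integer(0))
  d <- dmat[i, pool]
  ord <- order(d, pool)
  pool[ord][seq_len(min(k, length(pool)))]
}

# Largest-remainder apportionment of `total` integer units over weights.
# Remainder ties break by position, so allocation is deterministic.
largest_remainder <- function(weights, total) {
  if (total == 0L) return(integer(length(weights)))
  if (sum(weights) <= 0) weights <- rep(1, length(weights))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
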