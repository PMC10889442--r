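# 2-class geometric fixture: majority blob near the origin, minority points
# placed explicitly so neighbourhood structure is known by construction.
geom_dataset <- function(minority, majority) {
  m <- rbind(majority, minority)
  expression_dataset(m, rep(c("maj", "min"), c(nrow(majority), nrow(minority))),
                     gene_ids = c("gx", "gy"))
}

test_that("balance-to-majority plans raise every class to the majority count", {
  d <- class_distribution(factor(rep(c("ALL", "AML"), c(27, 11))))
  plan <- plan_balance_to_majority(d)
  expect_equal(plan$target_counts, c(ALL = 27L, AML = 27L))
  expect_equal(plan$target_counts - plan$original_counts, c(ALL = 0L, AML = 16L))

  bal <- plan_balance_to_majority(class_distribution(factor(rep(c("A", "B"), 10))))
  expect_true(all(bal$target_counts - bal$original_counts == 0))

  cum <- plan_balance_to_majority(class_distribution(
    factor(rep(c("AML", "BM", "BM34", "PB", "PBSC"), c(21, 8, 6, 8, 8)))))
  expect_true(all(cum$target_counts == 21L))

  expect_error(plan_balance_to_majority(class_distribution(factor(c("A", "A")))),
               "at least two classes")
})

test_that("SMOTE interpolates on the seed-neighbour segment with exact provenance", {
  d <- geom_dataset(minority = rbind(c(0, 0), c(1, 1)),
                    majority = rbind(c(10, 10), c(11, 10), c(10, 11)))
  res <- smote(d, k = 1, seed = 3)
  expect_equal(class_distribution(res$data)$counts, c(maj = 3L, min = 3L))
  expect_equal(nrow(res$provenance), 1L)
  pr <- res$provenance
  # only neighbour pair is (0,0)-(1,1): synthetic = gap * (1,1)
  syn <- synthetic_block(res, d)
  expect_equal(unname(syn[1, ]), c(pr$gap, pr$gap))
  expect_identical(replay_synthetic(d, pr), syn)
  expect_true(pr$gap >= 0 && pr$gap <= 1)
})

test_that("a plan needing nothing returns the input unchanged", {
  d <- random_dataset(n = 20, p = 6, classes = c(A = 10, B = 10))
  res <- smote(d, seed = 1)
  expect_identical(res$data$matrix, d$matrix)
  expect_equal(nrow(res$provenance), 0L)
})

test_that("SMOTE clamps k with a warning and errors on singleton classes", {
  d <- random_dataset(n = 13, p = 4, classes = c(A = 10, B = 3))
  expect_warning(smote(d, k = 5, seed = 1), "clamped to 2")

  d1 <- random_dataset(n = 11, p = 4, classes = c(A = 10, B = 1))
  expect_error(smote(d1, seed = 1), "single sample")
  res <- smote(d1, seed = 1, allow_duplication = TRUE)
  expect_equal(class_distribution(res$data)$counts, c(A = 10L, B = 10L))
  # duplicates replay exactly too (gap 0, neighbour == seed)
  expect_identical(replay_synthetic(d1, res$provenance),
                   synthetic_block(res, d1))
})

test_that("SMOTE output is deterministic in the seed and varies across seeds", {
  d <- random_dataset(n = 40, p = 8, classes = c(A = 30, B = 10))
  r1 <- smote(d, seed = 11)
  r2 <- smote(d, seed = 11)
  r3 <- smote(d, seed = 12)
  expect_identical(r1$data$matrix, r2$data$matrix)
  expect_identical(r1$provenance, r2$provenance)
  expect_false(identical(r1$data$matrix, r3$data$matrix))
})

test_that("neighbourhood categories follow the majority-count rule", {
  # minority point at the origin inside a tight majority blob -> noise;
  # minority cluster far away -> safe interior
  minority <- rbind(c(0, 0),
                    c(50, 50), c(50.5, 50), c(50, 50.5), c(50.5, 50.5), c(50.2, 50.2))
  majority <- withr::with_seed(8, cbind(runif(12, -1, 1), runif(12, -1, 1)))
  d <- geom_dataset(minority, majority)
  cats <- classify_neighborhoods(d, "min", m = 4)
  expect_equal(as.character(cats)[1], "noise")   # engulfed by majority
  expect_true(all(as.character(cats)[-1] == "safe"))  # deep in own cluster

  # brute-force the rule on a random mixture
  d2 <- random_dataset(n = 30, p = 5, classes = c(A = 20, B = 10), seed = 17)
  m <- 7
  cats2 <- classify_neighborhoods(d2, "B", m = m)
  rows2 <- attr(cats2, "rows")
  for (j in seq_along(rows2)) {
    i <- rows2[j]
    dd <- sqrt(colSums((t(d2$matrix) - d2$matrix[i, ])^2))
    ord <- order(dd, seq_along(dd))
    nn <- setdiff(ord, i)[seq_len(m)]
    mp <- sum(d2$labels[nn] == "A")
    want <- if (mp == m) "noise" else if (mp >= m / 2) "danger" else "safe"
    expect_equal(as.character(cats2)[j], want)
  }
})

test_that("Borderline-SMOTE seeds only danger samples; B2 majority gaps < 0.5", {
  # minority split: 3 points on the class border, 4 deep inside their cluster
  border <- rbind(c(1, 0), c(1.2, 0.2), c(0.9, -0.2))
  interior <- rbind(c(6, 0), c(6.2, 0.1), c(5.9, -0.1), c(6.1, 0.2))
  majority <- withr::with_seed(4, cbind(rnorm(14, 0, 0.4), rnorm(14, 0, 0.4)))
  d <- geom_dataset(rbind(border, interior), majority)
  cats <- classify_neighborhoods(d, "min", m = 5)
  danger <- attr(cats, "rows")[cats == "danger"]
  expect_gt(length(danger), 0)

  for (variant in c("B1", "B2")) {
    res <- borderline_smote(d, k = 3, m = 5, variant = variant, seed = 21)
    expect_equal(class_distribution(res$data)$counts, c(maj = 14L, min = 14L))
    expect_true(all(res$provenance$seed_index %in% danger), info = variant)
    expect_identical(replay_synthetic(d, res$provenance),
                     synthetic_block(res, d), info = variant)
  }

  resb2 <- borderline_smote(d, k = 3, m = 5, variant = "B2", seed = 22)
  majd <- resb2$provenance[resb2$provenance$neighbor_class == "maj", ]
  expect_gt(nrow(majd), 0)
  expect_true(all(majd$gap < 0.5))
  expect_true(all(majd$gap >= 0))
  # B1 never uses majority neighbours
  resb1 <- borderline_smote(d, k = 3, m = 5, variant = "B1", seed = 22)
  expect_true(all(resb1$provenance$neighbor_class == "min"))
})

test_that("Borderline-SMOTE falls back to plain SMOTE when every sample is safe", {
  minority <- withr::with_seed(5, cbind(rnorm(8, 30), rnorm(8, 30)))
  majority <- withr::with_seed(6, cbind(rnorm(12, 0), rnorm(12, 0)))
  d <- geom_dataset(minority, majority)
  expect_warning(res <- borderline_smote(d, k = 3, m = 5, seed = 2),
                 "no danger samples.*plain SMOTE")
  expect_equal(class_distribution(res$data)$counts, c(maj = 12L, min = 12L))
})

test_that("SVM-SMOTE seeds minority support vectors and extrapolates collinearly", {
  minority <- rbind(c(1, 0), c(3, 0), c(3, 1), c(4, 0.5))
  majority <- rbind(c(-1, 0), c(-1, 1), c(-2, 0), c(-1.5, 0.5), c(-2, 1))
  d <- geom_dataset(minority, majority)
  res <- svm_smote(d, k = 2, m = 3, seed = 13)
  expect_equal(class_distribution(res$data)$counts, c(maj = 5L, min = 5L))

  # independent SVM fit: seeds must be minority-class support vectors
  fit <- e1071::svm(d$matrix, factor(ifelse(as.character(d$labels) == "min",
                                            "target", "rest")),
                    kernel = "linear", cost = 1, scale = FALSE)
  sv_min <- fit$index[as.character(d$labels)[fit$index] == "min"]
  expect_true(all(res$provenance$seed_index %in% sv_min))
  expect_identical(replay_synthetic(d, res$provenance), synthetic_block(res, d))

  # extrapolated samples (negative stored gap) lie on the far side of the
  # seed: new - seed is antiparallel to neighbour - seed
  ext <- res$provenance[res$provenance$gap < 0, ]
  if (nrow(ext) > 0) {
    for (i in seq_len(nrow(ext))) {
      s <- d$matrix[ext$seed_index[i], ]
      nb <- d$matrix[ext$neighbor_index[i], ]
      new <- s + ext$gap[i] * (nb - s)
      expect_lt(sum((new - s) * (nb - s)), 0)
    }
  }
})

test_that("k-means SMOTE apportions symmetric clusters 50/50 and keeps pairs in-cluster", {
  # two congruent minority clusters (one a pure translation of the other)
  base <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  minority <- rbind(base + 20, base - 20)
  majority <- withr::with_seed(7, cbind(rnorm(24, 0, 0.5), rnorm(24, 0, 0.5)))
  d <- geom_dataset(minority, majority)
  res <- kmeans_smote(d, n_clusters = 3, seed = 31)
  expect_equal(class_distribution(res$data)$counts, c(maj = 24L, min = 24L))

  pr <- res$provenance
  alloc <- table(pr$cluster)
  expect_length(alloc, 2L)
  expect_lte(abs(diff(as.integer(alloc))), 1L)

  assign <- attr(pr, "cluster_assignment")
  expect_true(all(assign[pr$seed_index] == pr$cluster))
  expect_true(all(assign[pr$neighbor_index] == pr$cluster))
  expect_identical(replay_synthetic(d, pr), synthetic_block(res, d))
})

test_that("k-means SMOTE with one eligible cluster routes the full budget there", {
  minority <- withr::with_seed(9, cbind(rnorm(6, 15), rnorm(6, 15)))
  majority <- withr::with_seed(10, cbind(rnorm(18, 0), rnorm(18, 0)))
  d <- geom_dataset(minority, majority)
  res <- kmeans_smote(d, n_clusters = 2, seed = 5)
  expect_equal(nrow(res$provenance), 12L)
  expect_length(unique(res$provenance$cluster), 1L)
})

test_that("every variant preserves originals bitwise and keeps convexity", {
  d <- random_dataset(n = 45, p = 10, classes = c(A = 30, B = 15), seed = 33)
  for (m in c("smote", "b1", "b2", "svm", "kmeans")) {
    res <- suppressWarnings(oversample(d, m, seed = 19))
    expect_identical(original_block(res, d), d$matrix, info = m)
    pr <- res$provenance
    interp <- pr[pr$gap >= 0 & pr$gap <= 1, ]
    for (i in seq_len(nrow(interp))) {
      s <- d$matrix[interp$seed_index[i], ]
      nb <- d$matrix[interp$neighbor_index[i], ]
      v <- res$data$matrix[interp$synthetic_id[i], ]
      expect_true(all(v >= pmin(s, nb) - 1e-12 & v <= pmax(s, nb) + 1e-12),
                  info = m)
    }
  }
})

test_that("multiclass oversampling treats each non-majority class one-vs-rest", {
  fx <- make_reference_fixtures(n_genes = 40, seed = 12)
  tr <- subset_dataset(fx$cumida$data, fx$cumida$train_idx)
  res <- suppressWarnings(smote(tr, seed = 4))
  cd <- class_distribution(res$data)
  expect_true(all(cd$counts == 21L))
  # each synthetic sample interpolates within its own class
  pr <- res$provenance
  lab <- as.character(tr$labels)
  expect_true(all(lab[pr$seed_index] == pr$class))
  expect_true(all(lab[pr$neighbor_index] == pr$class))
})
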