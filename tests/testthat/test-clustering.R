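# helper: expression matrix of Gaussian blobs in gene space
blob_expression <- function(sizes, separation = 10, n_genes = 30, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  centers <- matrix(rnorm(length(sizes) * n_genes), length(sizes), n_genes)
  centers <- centers / sqrt(rowSums(centers^2)) * separation
  lab <- rep(seq_along(sizes), sizes)
  X <- centers[lab, ] + matrix(rnorm(n * n_genes), n, n_genes)
  expr <- t(X)
  dimnames(expr) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%04d", seq_len(n)))
  list(expr = expr, labels = lab)
}

test_that("normalization scales to the median library and log-transforms", {
  counts <- matrix(c(2, 0), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  norm <- normalize_counts(counts)
  expect_equal(as.numeric(norm[, 1]), c(log(3), 0))

  # library-depth invariance: doubling ONE cell's counts leaves that cell's
  # normalized profile unchanged (its scale factor halves; the median total
  # over the other cells is unmoved)
  set.seed(5)
  counts <- matrix(rpois(220, 2), 20, 11,
                   dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:11)))
  counts <- counts + 1L  # no zero totals, stable median
  doubled <- counts
  doubled[, 1] <- doubled[, 1] * 2L
  n1 <- normalize_counts(counts)
  n2 <- normalize_counts(doubled)
  expect_equal(as.matrix(n2)[, 1], as.matrix(n1)[, 1])

  # zero-total cell excluded with warning
  counts[, 3] <- 0
  expect_warning(n3 <- normalize_counts(counts), "zero total")
  expect_false("c3" %in% colnames(n3))
  expect_equal(attr(n3, "excluded_cells"), "c3")

  expect_error(normalize_counts(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("x", "y")))),
               "all-zero")
})

test_that("two well-separated blobs are recovered exactly", {
  world <- blob_expression(c(200, 200), separation = 10, seed = 7)
  res <- embed_and_cluster(world$expr, clustering_config(n_components = 10))
  k <- length(unique(res$assignment$labels))
  expect_equal(k, 2)
  # partition matches ground truth (up to label permutation)
  tab <- table(res$assignment$labels, world$labels)
  expect_equal(sum(apply(tab, 1, max)), 400)
})

test_that("clustering is deterministic for a fixed seed", {
  world <- blob_expression(c(150, 150), separation = 8, seed = 9)
  cfg <- clustering_config(n_components = 10, seed = 4)
  r1 <- embed_and_cluster(world$expr, cfg)
  r2 <- embed_and_cluster(world$expr, cfg)
  expect_identical(r1$assignment$labels, r2$assignment$labels)
  expect_identical(r1$embedding, r2$embedding)
})

test_that("i.i.d. noise is not split into more than 3 clusters", {
  world <- blob_expression(500, separation = 0, seed = 3)
  res <- embed_and_cluster(world$expr, clustering_config(n_components = 10))
  expect_lte(length(unique(res$assignment$labels)), 3)
})

test_that("cluster labels are a partition ordered by decreasing size", {
  world <- blob_expression(c(300, 100, 50), separation = 12, seed = 13)
  res <- embed_and_cluster(world$expr, clustering_config(n_components = 10))
  labels <- res$assignment$labels
  expect_setequal(names(labels), colnames(world$expr))
  sizes <- as.integer(table(labels)[as.character(sort(unique(labels)))])
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sort(unique(labels)), seq_along(sizes) - 1L)
})

test_that("too few cells for the kNN graph is an error", {
  world <- blob_expression(15, separation = 0, n_genes = 20, seed = 2)
  expect_error(embed_and_cluster(world$expr,
                                 clustering_config(n_components = 5,
                                                   n_neighbors = 20)),
               "n_neighbors")
})

test_that("subclustering recovers planted sub-blobs and keeps coverage", {
  # parent cluster 0 = union of 3 sub-blobs; cluster 1 = homogeneous blob.
  # The parent assignment is given, as after an annotation-driven selection.
  sub <- blob_expression(c(80, 80, 80), separation = 8, seed = 33)
  far <- blob_expression(120, separation = 0, seed = 34)
  expr <- cbind(sub$expr, far$expr)
  colnames(expr) <- sprintf("c%04d", seq_len(ncol(expr)))
  parent <- cluster_assignment(
    "global", setNames(rep(c(0L, 1L), c(240, 120)), colnames(expr)))
  res <- subcluster(expr, parent, 0L, clustering_config(n_components = 10))
  in_parent <- colnames(expr)[1:240]
  expect_setequal(names(res$assignment$labels), in_parent)
  expect_equal(length(unique(res$assignment$labels)), 3)
  tab <- table(res$assignment$labels, sub$labels)
  expect_equal(sum(apply(tab, 1, max)), 240)  # exact recovery
  expect_equal(res$assignment$level, "global.0")
  # homogeneous cluster 1: labels exist for every subset cell, none other
  res_h <- subcluster(expr, parent, 1L, clustering_config(n_components = 10))
  expect_setequal(names(res_h$assignment$labels), colnames(expr)[241:360])
  # determinism
  res2 <- subcluster(expr, parent, 0L, clustering_config(n_components = 10))
  expect_identical(res$assignment$labels, res2$assignment$labels)
  # absent target and too-small target error
  expect_error(subcluster(expr, parent, 99), "not present")
  tiny <- cluster_assignment(
    "global", setNames(rep(c(0L, 1L), c(350, 10)), colnames(expr)))
  expect_error(subcluster(expr, tiny, 1L), "fewer than")
})

test_that("find_markers applies the pct and fold-change filters", {
  w <- two_group_expression(n_in = 30, n_out = 70, n_genes = 6)
  counts <- w$counts
  counts[,] <- 0L
  in_cells <- names(w$labels)[w$labels == 1]
  out_cells <- names(w$labels)[w$labels == 0]
  # g001: expressed in 40% of in-cluster at high level -> excluded by pct
  counts["g001", in_cells[1:12]] <- 50L
  # g002: expressed in 60% of in-cluster, modest fold -> retained
  counts["g002", in_cells[1:18]] <- 8L
  counts["g002", out_cells[1:35]] <- 2L
  # g003: ubiquitous, no fold change -> excluded by log2fc
  counts["g003", ] <- 5L
  # g004: all-zero -> excluded (pct_in = 0)
  # g005/g006: background noise
  set.seed(8)
  counts["g005", ] <- rpois(100, 1)
  counts["g006", ] <- rpois(100, 1)
  expr <- normalize_counts(counts + 0)  # densities differ per cell; generic path
  assignment <- cluster_assignment("global", w$labels)
  mk <- find_markers(expr, counts, assignment, 1)
  expect_false("g001" %in% mk$gene)  # pct_in 0.4 < 0.5 despite huge fold
  expect_true("g002" %in% mk$gene)
  expect_false("g003" %in% mk$gene)
  expect_false("g004" %in% mk$gene)
  row <- mk[mk$gene == "g002", ]
  expect_equal(row$pct_in, 0.6)
  expect_true(row$log2fc > 0.25)
  expect_true(all(mk$p_adj >= mk$p_value))

  # output shrinks weakly as thresholds rise
  mk_strict1 <- find_markers(expr, counts, assignment, 1, min_pct = 0.9)
  mk_strict2 <- find_markers(expr, counts, assignment, 1, min_log2fc = 2)
  expect_true(all(mk_strict1$gene %in% mk$gene))
  expect_true(all(mk_strict2$gene %in% mk$gene))

  # degenerate cluster
  tiny_labels <- w$labels
  tiny_labels[] <- 0L
  tiny_labels[1:2] <- 1L
  expect_error(find_markers(expr, counts,
                            cluster_assignment("global", tiny_labels), 1),
               "fewer than 3")
})

test_that("BH adjustment matches a brute-force oracle", {
  set.seed(17)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and is monotone, >= p (as used in marker output)
  p <- runif(100)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("differential expression flags by inclusive thresholds", {
  set.seed(23)
  n_per <- 400
  genes <- sprintf("g%03d", 1:30)
  cells <- sprintf("c%04d", seq_len(2 * n_per))
  mu <- matrix(3, 30, 2 * n_per)
  mu[1:3, seq_len(n_per) + n_per] <- 12  # true fold 4 in group B
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), 30, 2 * n_per,
                   dimnames = list(genes, cells))
  expr <- normalize_counts(counts)
  cell_samples <- setNames(rep(c("sA1", "sA2", "sB1", "sB2"),
                               each = n_per / 2 * 2)[seq_len(2 * n_per)],
                           cells)
  cell_samples[seq_len(n_per)] <- rep(c("sA1", "sA2"), each = n_per / 2)
  cell_samples[seq_len(n_per) + n_per] <- rep(c("sB1", "sB2"),
                                              each = n_per / 2)
  de <- differential_expression(expr, counts, cell_samples,
                                c("sA1", "sA2"), c("sB1", "sB2"))
  expect_true(all(c("g001", "g002", "g003") %in% de$gene[de$significant]))
  # flag implements the inclusive >= rule on its own columns
  expect_equal(de$significant,
               de$log2fc >= 1 & de$neglog10_p >= 2)
  # sorted by log2fc descending
  expect_true(all(diff(de$log2fc) <= 0))
  # overlapping groups rejected
  expect_error(differential_expression(expr, counts, cell_samples,
                                       c("sA1"), c("sA1", "sB1")),
               "overlap")
})

test_that("identical groups produce no flagged genes", {
  set.seed(29)
  flagged <- vapply(1:3, function(i) {
    counts <- matrix(rnbinom(30 * 200, mu = 1, size = 2), 30, 200,
                     dimnames = list(sprintf("g%03d", 1:30),
                                     sprintf("c%04d", 1:200)))
    expr <- normalize_counts(counts)
    cs <- setNames(rep(c("a1", "a2", "b1", "b2"), each = 50),
                   colnames(counts))
    de <- differential_expression(expr, counts, cs, c("a1", "a2"),
                                  c("b1", "b2"))
    sum(de$significant)
  }, numeric(1))
  expect_true(mean(flagged == 0) >= 2 / 3)
})

test_that("cluster frequencies sum to 1 with explicit zero rows", {
  labels <- setNames(c(rep(0L, 30), rep(1L, 70), rep(0L, 50)),
                     sprintf("c%04d", 1:150))
  cell_samples <- setNames(c(rep("s1", 100), rep("s2", 50)), names(labels))
  fr <- cluster_frequencies(cluster_assignment("global", labels),
                            cell_samples)
  expect_equal(fr$frequency[fr$sample_id == "s1" & fr$cluster == 0], 0.3)
  expect_equal(fr$frequency[fr$sample_id == "s1" & fr$cluster == 1], 0.7)
  # cluster 1 absent from s2: explicit zero row
  expect_equal(fr$frequency[fr$sample_id == "s2" & fr$cluster == 1], 0)
  sums <- tapply(fr$frequency, fr$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("compare_frequencies detects a planted 2.6-fold shift and is antisymmetric", {
  set.seed(37)
  jitter <- function(x) x + rnorm(length(x), 0, 1e-4)
  freqs <- rbind(
    data.frame(sample_id = sprintf("a%d", 1:4), level = "global", cluster = 0,
               n_cells = 10, frequency = jitter(rep(0.10, 4))),
    data.frame(sample_id = sprintf("b%d", 1:4), level = "global", cluster = 0,
               n_cells = 26, frequency = jitter(rep(0.26, 4))))
  groups <- setNames(rep(c("skin", "PCL"), each = 4),
                     c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)))
  cmp <- compare_frequencies(freqs, groups, "skin", "PCL")
  oracle <- oracle_student_t(
    freqs$frequency[5:8], freqs$frequency[1:4])
  expect_equal(cmp$table$t_statistic, oracle$t, tolerance = 1e-9)
  expect_equal(cmp$table$fold_change, 2.6, tolerance = 1e-2)
  expect_true(0 %in% cmp$significant_up)
  # swapped groups: same p, inverted fold, no longer "up"
  rev <- compare_frequencies(freqs, groups, "PCL", "skin")
  expect_equal(rev$table$p_value, cmp$table$p_value)
  expect_equal(rev$table$fold_change, 1 / cmp$table$fold_change,
               tolerance = 1e-9)
  expect_length(rev$significant_up, 0)

  # equal means are never flagged
  freqs$frequency <- jitter(rep(0.2, 8))
  cmp2 <- compare_frequencies(freqs, groups, "skin", "PCL")
  expect_false(isTRUE(cmp2$table$p_value < 0.05))
})

test_that("program_score averages panel genes and separates planted cells", {
  set.seed(41)
  counts <- matrix(rpois(20 * 400, 1), 20, 400,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("c%04d", 1:400)))
  counts[1:3, 1:200] <- matrix(rpois(3 * 200, 4), 3, 200)  # 4x baseline
  expr <- normalize_counts(counts)
  # single-gene panel equals that row
  expect_equal(program_score(expr, "g05"), expr["g05", ])
  # duplicated gene same as unique
  expect_equal(program_score(expr, c("g01", "g02", "g01")),
               program_score(expr, c("g01", "g02")))
  # missing genes warn; all-missing errors
  expect_warning(program_score(expr, c("g01", "nope")), "nope")
  expect_error(program_score(expr, "nope"), "none of the")
  # planted cells score higher
  sc <- program_score(expr, c("g01", "g02", "g03"))
  p <- wilcox.test(sc[1:200], sc[201:400], alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
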