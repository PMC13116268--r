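# Expression workflow: median-library normalization, PCA + SNN-graph Louvain
# clustering and subclustering, marker detection with explicit
# expression-fraction / fold-change filters, condition-level differential
# expression, gene-program scoring, and cluster-frequency statistics.

#' Clustering configuration
#'
#' Defaults follow the standard in-situ workflow: 15 principal components,
#' Louvain community detection at resolution 0.8 on a k-nearest-neighbor
#' graph (k = 20, Euclidean in PC space) with shared-nearest-neighbor
#' Jaccard edge weights.
#'
#' @param n_components number of principal components (>= 1).
#' @param resolution Louvain resolution (> 0).
#' @param n_neighbors neighbors for the kNN graph.
#' @param seed integer seed controlling Louvain; identical seeds give
#'   identical labels.
#' @param algorithm only `"louvain"` is implemented.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(n_components = 15, resolution = 0.8,
                              n_neighbors = 20, seed = 0,
                              algorithm = "louvain") {
  stopifnot(n_components >= 1, resolution > 0, n_neighbors >= 1)
  algorithm <- match.arg(algorithm, "louvain")
  structure(list(n_components = as.integer(n_components),
                 resolution = resolution,
                 n_neighbors = as.integer(n_neighbors),
                 seed = as.integer(seed), algorithm = algorithm),
            class = "clustering_config")
}

#' Normalize a count matrix
#'
#' Per cell, counts are scaled to the median total count across cells and
#' log(1 + x)-transformed. Cells with zero total counts cannot be normalized
#' and are excluded with a warning (their ids are recorded in the
#' `excluded_cells` attribute).
#'
#' @param counts gene-by-cell count matrix (sparse or dense, gene rownames
#'   and cell colnames).
#' @return Sparse gene-by-cell matrix of normalized expression with
#'   attribute `excluded_cells`.
#' @export
normalize_counts <- function(counts) {
  counts <- .as_dgc(Matrix::Matrix(counts, sparse = TRUE))
  totals <- Matrix::colSums(counts)
  if (all(totals == 0)) stop("normalize_counts: all-zero count matrix")
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts excluded: ",
            paste(utils::head(colnames(counts)[zero], 5), collapse = ", "))
  }
  kept <- counts[, !zero, drop = FALSE]
  totals <- totals[!zero]
  sf <- stats::median(totals) / totals
  norm <- kept %*% Matrix::Diagonal(x = sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(kept)
  structure(norm, excluded_cells = colnames(counts)[zero])
}

# Blocked exact kNN in Euclidean space. Returns n x k index matrix
# (self excluded).
.knn_indices <- function(X, k, block = 1024L) {
  n <- nrow(X)
  if (k >= n) stop("fewer points than n_neighbors + 1")
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # within a row, ranking by ||x_i - x_j||^2 only needs sq_j - 2 x_i.x_j
    d2 <- -2 * Matrix::tcrossprod(X[idx, , drop = FALSE], X)
    d2 <- sweep(d2, 2, sq, "+")
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    for (r in seq_along(idx)) {
      row <- d2[r, ]
      thr <- sort.int(row, partial = k)[k]  # k-th smallest, O(n)
      cand <- which(row <= thr)
      out[idx[r], ] <- cand[order(row[cand])][seq_len(k)]
    }
  }
  out
}

# SNN graph: undirected, edge weight = Jaccard overlap of the two cells'
# neighbor sets (each including the cell itself). No pruning by default:
# keeping all weighted edges markedly reduces spurious fragmentation of
# homogeneous populations under Louvain.
.snn_graph <- function(knn, prune = 0) {
  n <- nrow(knn)
  k <- ncol(knn)
  nbr <- cbind(seq_len(n), knn)  # each cell neighbors itself
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                            j = as.vector(t(nbr)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  tri <- Matrix::triu(shared, k = 1)
  tw <- methods::as(tri, "TsparseMatrix")
  jac <- tw@x / (2 * (k + 1) - tw@x)
  keep <- jac >= prune
  igraph::graph_from_data_frame(
    data.frame(from = tw@i[keep] + 1L, to = tw@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

# Relabel integer memberships 0..K-1 by decreasing cluster size, ties broken
# by the lexicographically smallest member cell id.
.relabel_by_size <- function(membership, cell_ids) {
  tab <- table(membership)
  first_id <- vapply(names(tab), function(cl) {
    min(cell_ids[membership == cl])
  }, character(1))
  ord <- order(-as.integer(tab), first_id)
  new <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  unname(new[as.character(membership)])
}

#' Construct a cluster assignment
#'
#' @param level assignment level name (e.g. `"global"`, or a lineage name
#'   like `"global.2"` for a subclustering).
#' @param labels integer cluster indices (0-based, ordered by decreasing
#'   cluster size) named by cell id.
#' @param annotation optional named character vector mapping cluster index
#'   (as character) to a cell-type name.
#' @return Object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(level, labels, annotation = NULL) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  structure(list(level = level, labels = labels, annotation = annotation),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment '%s': %d cells, %d clusters>\n",
              x$level, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' PCA embedding and Louvain graph clustering
#'
#' Genes are standardized across cells (zero-variance genes dropped), cells
#' projected onto the leading principal components, connected in a
#' k-nearest-neighbor graph with shared-nearest-neighbor Jaccard weights,
#' and partitioned with Louvain at the configured resolution. Cluster
#' indices are 0..K-1 ordered by decreasing size. The 2-D embedding returned
#' for visualization is the first two components of the same PC space and
#' carries no contract beyond determinism.
#'
#' @param expr gene-by-cell normalized expression matrix (see
#'   [normalize_counts()]).
#' @param cfg a [clustering_config()].
#' @param level level name recorded on the assignment.
#' @return List with elements `assignment` ([cluster_assignment()]),
#'   `embedding` (data frame `cell_id, dim1, dim2`) and `pcs` (cell-by-PC
#'   score matrix).
#' @export
embed_and_cluster <- function(expr, cfg = clustering_config(),
                              level = "global") {
  n <- ncol(expr)
  if (n < cfg$n_neighbors + 1) {
    stop("embed_and_cluster: ", n, " cells is fewer than n_neighbors + 1 = ",
         cfg$n_neighbors + 1)
  }
  if (nrow(expr) < cfg$n_components) {
    stop("embed_and_cluster: fewer genes than n_components")
  }
  cell_ids <- colnames(expr)
  X <- t(as.matrix(expr))                       # cells x genes
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  k <- min(cfg$n_components, ncol(X), n - 1L)
  pcs <- stats::prcomp(X, center = FALSE, rank. = k)$x
  knn <- .knn_indices(pcs, cfg$n_neighbors)
  g <- .snn_graph(knn)
  set.seed(cfg$seed)
  comm <- igraph::cluster_louvain(g, resolution = cfg$resolution)
  labels <- .relabel_by_size(igraph::membership(comm), cell_ids)
  names(labels) <- cell_ids
  list(assignment = cluster_assignment(level, labels),
       embedding = data.frame(cell_id = cell_ids, dim1 = pcs[, 1],
                              dim2 = pcs[, 2], stringsAsFactors = FALSE),
       pcs = pcs)
}

#' Subcluster one cluster with the same parameters
#'
#' Re-runs [embed_and_cluster()] on the cells of a single parent cluster;
#' the resulting level name records the lineage
#' (`"<parent level>.<target>"`).
#'
#' @param expr gene-by-cell normalized expression matrix covering (at least)
#'   the parent cells.
#' @param parent a [cluster_assignment()].
#' @param target cluster index within `parent` to subcluster.
#' @param cfg a [clustering_config()].
#' @return As [embed_and_cluster()], restricted to the target's cells.
#' @export
subcluster <- function(expr, parent, target, cfg = clustering_config()) {
  in_target <- names(parent$labels)[parent$labels == target]
  if (!length(in_target)) {
    stop("subcluster: cluster '", target, "' not present at level '",
         parent$level, "'")
  }
  if (length(in_target) < cfg$n_neighbors + 1) {
    stop("subcluster: cluster '", target, "' has ", length(in_target),
         " cells, fewer than n_neighbors + 1 = ", cfg$n_neighbors + 1)
  }
  embed_and_cluster(expr[, in_target, drop = FALSE], cfg,
                    level = paste0(parent$level, ".", target))
}

# Shared marker/DE statistics for an in-group vs out-group split of cells.
# pct_* from raw counts > 0; log2fc on de-logged normalized means with
# pseudocount 1; two-sided Wilcoxon rank-sum (or Student t) on normalized
# values; BH adjustment over all tested genes.
.group_de_stats <- function(expr, counts, in_cells, out_cells,
                            test = c("wilcox", "t")) {
  test <- match.arg(test)
  counts <- counts[rownames(expr), , drop = FALSE]
  pct_in <- Matrix::rowMeans(counts[, in_cells, drop = FALSE] > 0)
  pct_out <- Matrix::rowMeans(counts[, out_cells, drop = FALSE] > 0)
  delog <- expm1(expr)
  mean_in <- Matrix::rowMeans(delog[, in_cells, drop = FALSE])
  mean_out <- Matrix::rowMeans(delog[, out_cells, drop = FALSE])
  log2fc <- log2((mean_in + 1) / (mean_out + 1))
  ein <- as.matrix(expr[, in_cells, drop = FALSE])
  eout <- as.matrix(expr[, out_cells, drop = FALSE])
  p <- vapply(seq_len(nrow(expr)), function(g) {
    x <- ein[g, ]; y <- eout[g, ]
    if (all(x == x[1]) && all(y == x[1])) return(1)
    if (test == "wilcox") {
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    } else {
      stats::t.test(x, y)$p.value
    }
  }, numeric(1))
  data.frame(gene = rownames(expr), pct_in = unname(pct_in),
             pct_out = unname(pct_out), log2fc = unname(log2fc),
             p_value = p, p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Marker genes of one cluster
#'
#' For each gene: the fraction of in-cluster and out-of-cluster cells with a
#' raw count > 0, log2 fold change `log2((mean_in + 1) / (mean_out + 1))` of
#' de-logged normalized means, and a two-sided Wilcoxon rank-sum p-value on
#' normalized values with Benjamini-Hochberg adjustment over all tested
#' genes. Genes are retained when `pct_in >= min_pct` AND
#' `log2fc > min_log2fc` (the defaults are the 50% expression-fraction and
#' 0.25 fold-change cutoffs used for cell annotation).
#'
#' @param expr gene-by-cell normalized expression matrix.
#' @param counts matching raw count matrix (used for the detection
#'   fractions).
#' @param assignment a [cluster_assignment()] covering the columns of
#'   `expr`.
#' @param cluster cluster index to profile (needs >= 3 cells in and out).
#' @param min_pct minimum in-cluster expression fraction, default 0.5.
#' @param min_log2fc strict lower bound on log2 fold change, default 0.25.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return Data frame of retained markers:
#'   `cluster, gene, log2fc, pct_in, pct_out, p_value, p_adj`, sorted by
#'   decreasing log2fc.
#' @export
find_markers <- function(expr, counts, assignment, cluster, min_pct = 0.5,
                         min_log2fc = 0.25, test = c("wilcox", "t")) {
  labels <- assignment$labels[colnames(expr)]
  in_cells <- colnames(expr)[!is.na(labels) & labels == cluster]
  out_cells <- colnames(expr)[!is.na(labels) & labels != cluster]
  if (length(in_cells) < 3) {
    stop("find_markers: cluster '", cluster,
         "' has fewer than 3 cells; rank test degenerate")
  }
  if (!length(out_cells)) stop("find_markers: complement of cluster is empty")
  st <- .group_de_stats(expr, counts, in_cells, out_cells, test = test)
  keep <- st$pct_in >= min_pct & st$log2fc > min_log2fc
  out <- st[keep, , drop = FALSE]
  out <- out[order(-out$log2fc), , drop = FALSE]
  out$cluster <- rep(cluster, nrow(out))
  rownames(out) <- NULL
  out[, c("cluster", "gene", "log2fc", "pct_in", "pct_out", "p_value",
          "p_adj")]
}

#' Differential expression between condition groups
#'
#' Same per-gene statistics as [find_markers()], computed between all cells
#' of two disjoint sample groups (B relative to A). A gene is flagged
#' significant when `log2fc >= fc_threshold` and
#' `-log10(p) >= neglog10p_threshold`; both thresholds are inclusive and,
#' matching the volcano convention, applied to the raw p-value (the BH
#' adjusted value is reported alongside).
#'
#' @param expr gene-by-cell normalized expression matrix over all cells.
#' @param counts matching raw count matrix.
#' @param cell_samples character vector (named by cell id) giving each
#'   cell's sample id.
#' @param samples_a,samples_b disjoint sample id sets; `samples_a` is the
#'   reference.
#' @param fc_threshold inclusive log2 fold-change cutoff, default 1.
#' @param neglog10p_threshold inclusive -log10 p cutoff, default 2.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return Data frame `gene, log2fc, pct_in, pct_out, p_value, p_adj,
#'   neglog10_p, significant`, sorted by decreasing log2fc.
#' @export
differential_expression <- function(expr, counts, cell_samples, samples_a,
                                    samples_b, fc_threshold = 1.0,
                                    neglog10p_threshold = 2.0,
                                    test = c("wilcox", "t")) {
  if (length(intersect(samples_a, samples_b))) {
    stop("differential_expression: sample groups overlap: ",
         paste(intersect(samples_a, samples_b), collapse = ", "))
  }
  smp <- cell_samples[colnames(expr)]
  cells_a <- colnames(expr)[smp %in% samples_a]
  cells_b <- colnames(expr)[smp %in% samples_b]
  if (!length(cells_a) || !length(cells_b)) {
    stop("differential_expression: empty group")
  }
  st <- .group_de_stats(expr, counts, cells_b, cells_a, test = test)
  st$neglog10_p <- -log10(st$p_value)
  st$significant <- st$log2fc >= fc_threshold &
    st$neglog10_p >= neglog10p_threshold
  st <- st[order(-st$log2fc), , drop = FALSE]
  rownames(st) <- NULL
  st
}

#' Per-sample cluster frequencies
#'
#' Counts and fractions of cells per cluster within each sample. A cluster
#' absent from a sample gets an explicit zero row, so every sample reports
#' the same cluster panel and frequencies sum to 1 per sample.
#'
#' @param assignment a [cluster_assignment()].
#' @param cell_samples character vector (named by cell id) giving each
#'   cell's sample id; must cover every assigned cell.
#' @return Data frame `sample_id, level, cluster, n_cells, frequency`.
#' @export
cluster_frequencies <- function(assignment, cell_samples) {
  ids <- names(assignment$labels)
  smp <- cell_samples[ids]
  if (any(is.na(smp))) {
    stop("cluster_frequencies: cells without a sample id: ",
         paste(utils::head(ids[is.na(smp)], 5), collapse = ", "))
  }
  clusters <- sort(unique(assignment$labels))
  out <- do.call(rbind, lapply(sort(unique(smp)), function(s) {
    lab <- assignment$labels[smp == s]
    n <- vapply(clusters, function(cl) sum(lab == cl), integer(1))
    data.frame(sample_id = s, level = assignment$level, cluster = clusters,
               n_cells = n, frequency = n / length(lab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare cluster frequencies between two groups of samples
#'
#' One unpaired Student's t-test per cluster on the per-sample frequencies,
#' reported with mean ± SEM and fold change (B over A), plus the subset of
#' clusters significantly more frequent in group B (`p_value < alpha` and
#' `mean_b > mean_a`) — the gate used to select subclusters for
#' colocalization analysis. BH-adjusted p-values across clusters are
#' reported alongside the raw ones.
#'
#' @param freqs output of [cluster_frequencies()].
#' @param sample_groups character vector (named by sample id) giving each
#'   sample's group label.
#' @param group_a,group_b group labels (A is the reference); >= 2 samples
#'   each.
#' @param alpha significance level for the gate, default 0.05.
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return List with `table` (one row per cluster: `cluster, mean_a, mean_b,
#'   sem_a, sem_b, fold_change, t_statistic, p_value, p_adj, n_a, n_b,
#'   significant_up`) and `significant_up` (vector of gated cluster
#'   indices).
#' @export
compare_frequencies <- function(freqs, sample_groups, group_a, group_b,
                                alpha = 0.05, var_equal = TRUE) {
  freqs$group <- sample_groups[freqs$sample_id]
  rows <- lapply(sort(unique(freqs$cluster)), function(cl) {
    fa <- freqs$frequency[freqs$cluster == cl & freqs$group == group_a]
    fb <- freqs$frequency[freqs$cluster == cl & freqs$group == group_b]
    if (length(fa) < 2 || length(fb) < 2) {
      stop("compare_frequencies needs >= 2 samples per group")
    }
    tt <- .two_sample_t(fb, fa, var_equal = var_equal)
    data.frame(cluster = cl, mean_a = mean(fa), mean_b = mean(fb),
               sem_a = stats::sd(fa) / sqrt(length(fa)),
               sem_b = stats::sd(fb) / sqrt(length(fb)),
               fold_change = if (mean(fa) > 0) mean(fb) / mean(fa) else NaN,
               t_statistic = tt$t, p_value = tt$p,
               n_a = length(fa), n_b = length(fb),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant_up <- tab$p_value < alpha & tab$mean_b > tab$mean_a
  list(table = tab, significant_up = tab$cluster[tab$significant_up])
}

#' Score cells for a gene program
#'
#' Per-cell mean normalized expression over the panel genes present in the
#' matrix; duplicated panel entries are collapsed and panel genes missing
#' from the matrix are reported in a warning.
#'
#' @param expr gene-by-cell normalized expression matrix.
#' @param gene_panel character vector of gene symbols.
#' @return Numeric vector of scores named by cell id.
#' @export
program_score <- function(expr, gene_panel) {
  panel <- unique(gene_panel)
  present <- intersect(panel, rownames(expr))
  if (!length(present)) {
    stop("program_score: none of the ", length(panel),
         " panel genes are in the matrix")
  }
  missing <- setdiff(panel, present)
  if (length(missing)) {
    warning("panel genes missing from matrix: ",
            paste(missing, collapse = ", "))
  }
  Matrix::colMeans(expr[present, , drop = FALSE])
}
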