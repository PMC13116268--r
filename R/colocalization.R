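# Radius-neighborhood colocalization: around every cell of a source
# subcluster a disc of fixed radius (default 25 µm) is drawn and cells of
# each target subcluster inside it are counted, giving a directed
# subcluster-pair interaction matrix. The disc is closed: distance == radius
# counts. Neighbor search uses a uniform grid with bin width = radius so
# results equal the O(n^2) computation exactly.

# Grid-accelerated enumeration of all unordered point pairs within `radius`
# of one another. Returns a 2-column integer matrix of indices (i < j).
.radius_pairs <- function(xy, radius) {
  n <- nrow(xy)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  bx <- floor(xy[, 1] / radius)
  by <- floor(xy[, 2] / radius)
  key <- paste(bx, by)
  bins <- split(seq_len(n), key)
  coords <- do.call(rbind, lapply(strsplit(names(bins), " ", fixed = TRUE),
                                  as.numeric))
  lookup <- stats::setNames(seq_along(bins), names(bins))
  r2 <- radius * radius
  # (0,0) handled as within-bin pairs; half the neighbor offsets to visit
  # each bin pair exactly once
  offsets <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  acc_i <- vector("list", 0)
  acc_j <- vector("list", 0)
  for (b in seq_along(bins)) {
    ii <- bins[[b]]
    if (length(ii) > 1) {
      d2 <- as.matrix(stats::dist(xy[ii, , drop = FALSE]))^2
      hit <- which(upper.tri(d2) & d2 <= r2, arr.ind = TRUE)
      if (nrow(hit)) {
        acc_i[[length(acc_i) + 1]] <- ii[hit[, 1]]
        acc_j[[length(acc_j) + 1]] <- ii[hit[, 2]]
      }
    }
    for (off in offsets) {
      nb <- lookup[paste(coords[b, 1] + off[1], coords[b, 2] + off[2])]
      if (is.na(nb)) next
      jj <- bins[[nb]]
      dx <- outer(xy[ii, 1], xy[jj, 1], "-")
      dy <- outer(xy[ii, 2], xy[jj, 2], "-")
      hit <- which(dx * dx + dy * dy <= r2, arr.ind = TRUE)
      if (nrow(hit)) {
        acc_i[[length(acc_i) + 1]] <- ii[hit[, 1]]
        acc_j[[length(acc_j) + 1]] <- jj[hit[, 2]]
      }
    }
  }
  if (!length(acc_i)) return(matrix(integer(0), ncol = 2))
  cbind(unlist(acc_i, use.names = FALSE), unlist(acc_j, use.names = FALSE))
}

#' Count target cells within a radius of each source cell
#'
#' Closed-disc counts (Euclidean distance <= radius). When the two lists
#' share cell identities, a cell is never counted as its own neighbor.
#'
#' @param source_cells,target_cells two-column matrices or data frames of
#'   (x, y) µm positions (data frames may carry a `cell_id` column used for
#'   self-exclusion).
#' @param radius disc radius in µm (> 0).
#' @param source_ids,target_ids optional cell identifiers aligned with the
#'   rows; pairs with equal ids are excluded.
#' @return List with `per_source` (integer counts per source cell) and
#'   `total` (their sum).
#' @export
neighbor_counts <- function(source_cells, target_cells, radius,
                            source_ids = NULL, target_ids = NULL) {
  if (radius <= 0) stop("neighbor_counts: radius must be > 0")
  get_xy <- function(z) {
    if (is.data.frame(z)) cbind(z$x, z$y) else as.matrix(z)[, 1:2, drop = FALSE]
  }
  get_ids <- function(z, ids) {
    if (!is.null(ids)) ids
    else if (is.data.frame(z) && "cell_id" %in% colnames(z)) z$cell_id
    else NULL
  }
  sxy <- get_xy(source_cells)
  txy <- get_xy(target_cells)
  sid <- get_ids(source_cells, source_ids)
  tid <- get_ids(target_cells, target_ids)
  ns <- nrow(sxy)
  pairs <- .radius_pairs(rbind(sxy, txy), radius)
  per_source <- integer(ns)
  if (nrow(pairs)) {
    a <- pairs[, 1]; b <- pairs[, 2]
    # source->target hits in either orientation of the unordered pair
    keep1 <- a <= ns & b > ns
    keep2 <- b <= ns & a > ns
    src <- c(a[keep1], b[keep2])
    tgt <- c(b[keep1], a[keep2]) - ns
    if (!is.null(sid) && !is.null(tid)) {
      same <- sid[src] == tid[tgt]
      src <- src[!same]
    } else if (identical(sxy, txy)) {
      # same list passed twice: a cell is never its own neighbor
      src <- src[src != tgt]
    }
    if (length(src)) {
      per_source <- tabulate(src, nbins = ns)
    }
  }
  list(per_source = per_source, total = sum(per_source))
}

#' Colocalization matrix between subclusters
#'
#' Directed neighbor-count matrix over all ordered pairs of the included
#' subclusters: entry (A, B) is the total number of B cells found within
#' `radius` of A cells, summed over all A source cells. A cell is never its
#' own neighbor, so the diagonal equals twice the number of within-cluster
#' pairs inside the radius, and off-diagonal entries are symmetric. The
#' intended gating for `included_subclusters` is the set of subclusters
#' significantly more frequent in the implanted condition (see
#' [compare_frequencies()]).
#'
#' @param cells data frame with `cell_id, x, y`.
#' @param assignment a [cluster_assignment()] covering these cells.
#' @param included_subclusters non-empty vector of subcluster labels present
#'   in the assignment.
#' @param radius disc radius in µm, default 25.
#' @return Object of class `colocalization_matrix`: list with `level`,
#'   `radius`, `subclusters`, `total_counts` (directed matrix),
#'   `mean_per_cell` (total / source-cluster size) and `n_source_cells`.
#' @export
colocalization_matrix <- function(cells, assignment, included_subclusters,
                                  radius = 25) {
  if (radius <= 0) stop("colocalization_matrix: radius must be > 0")
  if (!length(included_subclusters)) {
    stop("colocalization_matrix: included_subclusters is empty")
  }
  labels <- assignment$labels[cells$cell_id]
  unknown <- setdiff(included_subclusters, unique(assignment$labels))
  if (length(unknown)) {
    stop("colocalization_matrix: unknown subcluster label(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- !is.na(labels) & labels %in% included_subclusters
  xy <- cbind(cells$x, cells$y)[keep, , drop = FALSE]
  lab <- as.character(labels[keep])
  subs <- as.character(sort(unique(included_subclusters)))
  K <- length(subs)
  total <- matrix(0L, K, K, dimnames = list(subs, subs))
  pairs <- .radius_pairs(xy, radius)
  if (nrow(pairs)) {
    la <- lab[pairs[, 1]]
    lb <- lab[pairs[, 2]]
    # each unordered pair contributes one neighbor in each direction
    t1 <- table(factor(la, levels = subs), factor(lb, levels = subs))
    total <- total + unclass(t1) + t(unclass(t1))
  }
  n_src <- vapply(subs, function(s) sum(lab == s), integer(1))
  mean_pc <- sweep(total, 1, pmax(n_src, 1), "/")
  mean_pc[n_src == 0, ] <- NaN
  structure(list(level = assignment$level, radius = radius,
                 subclusters = subs, total_counts = total,
                 mean_per_cell = mean_pc, n_source_cells = n_src),
            class = "colocalization_matrix")
}

#' @export
print.colocalization_matrix <- function(x, ...) {
  cat(sprintf("<colocalization_matrix '%s': %d subclusters, radius %g um>\n",
              x$level, length(x$subclusters), x$radius))
  print(x$total_counts)
  invisible(x)
}

#' Export a colocalization matrix as edge list and heatmap table
#'
#' The edge list (chord-diagram input) holds the upper triangle plus
#' diagonal of the total-count matrix in long format, zero-weight edges
#' retained; the heatmap table is the full directed matrix (totals by
#' default, per-source-cell means via `values`).
#'
#' @param matrix a [colocalization_matrix()].
#' @param values `"total"` (default) or `"mean"` for the heatmap table.
#' @return List with `edges` (data frame `source, target, weight`) and
#'   `heatmap` (data frame, first column `source`).
#' @export
export_interaction <- function(matrix, values = c("total", "mean")) {
  values <- match.arg(values)
  tot <- matrix$total_counts
  subs <- matrix$subclusters
  ut <- which(upper.tri(tot, diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  edges <- data.frame(source = subs[ut[, 1]], target = subs[ut[, 2]],
                      weight = tot[ut], stringsAsFactors = FALSE)
  hm <- if (values == "total") tot else matrix$mean_per_cell
  heatmap <- data.frame(source = subs, as.data.frame(hm),
                        check.names = FALSE, stringsAsFactors = FALSE)
  rownames(heatmap) <- NULL
  list(edges = edges, heatmap = heatmap)
}

#' Rebuild a total-count matrix from an exported edge list
#'
#' Inverse of the `edges` component of [export_interaction()].
#'
#' @param edges data frame `source, target, weight`.
#' @return Symmetric matrix of total counts.
#' @export
edges_to_matrix <- function(edges) {
  subs <- sort(unique(c(edges$source, edges$target)))
  m <- matrix(0, length(subs), length(subs), dimnames = list(subs, subs))
  for (r in seq_len(nrow(edges))) {
    m[edges$source[r], edges$target[r]] <- edges$weight[r]
    m[edges$target[r], edges$source[r]] <- edges$weight[r]
  }
  m
}
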