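# Over-representation analysis of query gene lists against user-supplied
# gene sets (GMT): one-sided hypergeometric test (equivalent to one-sided
# Fisher's exact on the 2x2 overlap table) with Benjamini-Hochberg
# adjustment across sets. The default universe is the measured gene panel,
# the defensible null for small curated in-situ panels.

#' Over-representation of a gene list in gene sets
#'
#' For every set: the overlap with the query within the universe and the
#' one-sided hypergeometric probability of an overlap at least that large.
#' Query genes outside the universe are dropped with a warning; set genes
#' outside the universe do not count toward set size.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of background genes (e.g. the measured
#'   panel); defaults to the collection's universe.
#' @return Data frame sorted by p-value: `set_name, overlap, set_size,
#'   query_size, universe_size, p_value, p_adj, overlap_genes`
#'   (comma-separated).
#' @export
overrepresentation <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- collection$universe
  if (is.null(universe)) stop("overrepresentation: no universe given")
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) outside the universe dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  query <- intersect(query, universe)
  if (!length(query)) {
    stop("overrepresentation: empty query after universe intersection")
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    ov <- intersect(query, set)
    k <- length(ov)
    m <- length(set)
    # P(overlap >= k) drawing q genes from N with m marked
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = m, query_size = q,
               universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -out$overlap, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_name", "overlap", "set_size", "query_size", "universe_size",
          "p_value", "p_adj", "overlap_genes")]
}

#' Annotate clusters by their best-matching gene set
#'
#' Runs [overrepresentation()] on each cluster's marker genes and assigns
#' the smallest-p set (ties broken by larger overlap, then lexicographic
#' set name). All per-set records are retained for audit.
#'
#' @param marker_tables named list (cluster label to marker data frame with
#'   a `gene` column, or plain character vector of genes); each cluster
#'   needs at least one marker.
#' @param collection a [gene_set_collection()].
#' @param universe background genes, defaulting to the collection's.
#' @return List with `annotation` (named character vector cluster ->
#'   set name) and `records` (combined data frame with a `cluster`
#'   column).
#' @export
annotate_clusters <- function(marker_tables, collection, universe = NULL) {
  recs <- list()
  ann <- character(0)
  for (cl in names(marker_tables)) {
    mt <- marker_tables[[cl]]
    genes <- if (is.data.frame(mt)) mt$gene else mt
    res <- overrepresentation(genes, collection, universe)
    recs[[cl]] <- cbind(cluster = cl, res)
    ann[cl] <- res$set_name[1]  # table already sorted by the tie-break rule
  }
  list(annotation = ann,
       records = do.call(rbind, c(recs, list(make.row.names = FALSE))))
}
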