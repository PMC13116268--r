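# End-to-end pipeline: QC -> normalization -> global clustering -> markers
# -> condition differential expression -> cluster frequencies ->
# subclustering of the implant-responsive target -> signed-distance region
# assignment -> gated colocalization -> enrichment annotation -> embedding
# export. Every intermediate is written as CSV next to a JSON run-metadata
# record; the whole run is deterministic given the configured seed.

#' Pipeline configuration
#'
#' @param simulate when TRUE (default) the input study is generated with
#'   [simulate_study()] from `sim`; otherwise `manifest` must point at a
#'   manifest CSV (`sample_id, condition, transcripts, cells, counts, genes,
#'   cell_names[, boundary_scaffold, boundary_capsule_outer, tissue_roi]`).
#' @param sim a [simulation_config()] used when `simulate` is TRUE.
#' @param manifest manifest CSV path used when `simulate` is FALSE.
#' @param qv_threshold QC quality-value cutoff.
#' @param clustering a [clustering_config()].
#' @param region a [region_config()]; samples carrying a `capsule_outer`
#'   boundary use it regardless of mode.
#' @param radius colocalization radius, µm.
#' @param min_pct,min_log2fc marker filter cutoffs.
#' @param fc_threshold,neglog10p_threshold volcano significance cutoffs.
#' @param subcluster_target global cluster to subcluster: `"auto"` picks the
#'   significantly implant-enriched cluster with the largest frequency
#'   increase (falling back to the largest cluster).
#' @param gene_sets optional GMT path for annotation; when NULL and
#'   `simulate` is TRUE, the generator's planted marker panels are used.
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            manifest = NULL, qv_threshold = 20,
                            clustering = clustering_config(),
                            region = region_config(), radius = 25,
                            min_pct = 0.5, min_log2fc = 0.25,
                            fc_threshold = 1.0, neglog10p_threshold = 2.0,
                            subcluster_target = "auto", gene_sets = NULL,
                            out_dir = tempfile("stimplant_run_"), seed = 1) {
  structure(list(simulate = simulate, sim = sim, manifest = manifest,
                 qv_threshold = qv_threshold, clustering = clustering,
                 region = region, radius = radius, min_pct = min_pct,
                 min_log2fc = min_log2fc, fc_threshold = fc_threshold,
                 neglog10p_threshold = neglog10p_threshold,
                 subcluster_target = subcluster_target,
                 gene_sets = gene_sets, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

# fail-fast validation of a manifest before any compute
.read_manifest_samples <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  .require_columns(man, c("sample_id", "condition", "transcripts", "cells",
                          "counts", "genes", "cell_names"), "manifest")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.path(base, p) == p | file.exists(p),
                                p, file.path(base, p))
  for (r in seq_len(nrow(man))) {
    for (col in c("transcripts", "cells", "counts", "genes", "cell_names")) {
      if (!file.exists(resolve(man[[col]][r]))) {
        stop("validation error: sample '", man$sample_id[r], "': missing ",
             col, " file ", man[[col]][r])
      }
    }
    if (man$condition[r] != "skin") {
      if (!"boundary_scaffold" %in% colnames(man) ||
          !nzchar(man$boundary_scaffold[r]) ||
          !file.exists(resolve(man$boundary_scaffold[r]))) {
        stop("validation error: implanted sample '", man$sample_id[r],
             "' has no scaffold boundary file")
      }
    }
  }
  samples <- list()
  for (r in seq_len(nrow(man))) {
    paths <- list(transcripts = resolve(man$transcripts[r]),
                  cells = resolve(man$cells[r]),
                  counts = resolve(man$counts[r]),
                  genes = resolve(man$genes[r]),
                  cell_names = resolve(man$cell_names[r]))
    bnd <- character(0)
    if ("boundary_scaffold" %in% colnames(man) &&
        nzchar(man$boundary_scaffold[r])) {
      bnd["scaffold"] <- resolve(man$boundary_scaffold[r])
    }
    if ("boundary_capsule_outer" %in% colnames(man) &&
        nzchar(man$boundary_capsule_outer[r])) {
      bnd["capsule_outer"] <- resolve(man$boundary_capsule_outer[r])
    }
    if (length(bnd)) paths$boundaries <- bnd
    if ("tissue_roi" %in% colnames(man) && nzchar(man$tissue_roi[r])) {
      paths$tissue_roi <- resolve(man$tissue_roi[r])
    }
    samples[[man$sample_id[r]]] <-
      read_sample(paths, man$sample_id[r], man$condition[r])
  }
  list(samples = samples,
       manifest = man[, c("sample_id", "condition")])
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or manifest-loaded study and writes
#' the result bundle as CSV files plus `run_metadata.json` under
#' `cfg$out_dir`. Outputs: `qc.csv`, `qc_comparison.csv`, `clusters.csv`,
#' `markers.csv`, `de.csv`, `frequencies.csv`, `frequency_comparison.csv`,
#' `distances.csv`, `regions.csv`, `coloc_total.csv`, `coloc_mean.csv`,
#' `coloc_edges.csv`, `enrichment.csv`, `embedding.csv`.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the result bundle as a named list.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()

  .log_stage("load", if (cfg$simulate) "simulating study" else cfg$manifest)
  if (cfg$simulate) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- .derive_seed(cfg$seed, 1L)
    study <- simulate_study(sim_cfg)
    samples <- study$samples
    manifest <- study$manifest
    truths <- study$truths
  } else {
    if (is.null(cfg$manifest)) stop("pipeline: no manifest and simulate = FALSE")
    loaded <- .read_manifest_samples(cfg$manifest)
    samples <- loaded$samples
    manifest <- loaded$manifest
    truths <- NULL
  }
  conditions <- stats::setNames(manifest$condition, manifest$sample_id)
  groups <- unique(manifest$condition)
  ref_group <- if ("skin" %in% groups) "skin" else groups[1]
  alt_group <- setdiff(groups, ref_group)[1]

  .log_stage("qc", "computing per-sample metrics")
  qc <- do.call(rbind, lapply(samples, compute_qc,
                              qv_threshold = cfg$qv_threshold))
  rownames(qc) <- NULL
  bundle$qc <- qc
  qc_cmp <- NULL
  if (!is.na(alt_group) &&
      sum(conditions == ref_group) >= 2 && sum(conditions == alt_group) >= 2) {
    qc_cmp <- do.call(rbind, lapply(
      c("frac_high_quality", "frac_transcripts_in_cells",
        "frac_cells_no_transcripts", "transcripts_per_um2", "cells_per_mm2"),
      function(m) compare_metric(qc[qc$condition == ref_group, ],
                                 qc[qc$condition == alt_group, ], m)))
  }
  bundle$qc_comparison <- qc_cmp

  .log_stage("cluster", "normalizing and clustering all cells")
  counts <- do.call(cbind, lapply(samples, function(s) s$counts))
  expr <- normalize_counts(counts)
  counts <- counts[, colnames(expr), drop = FALSE]
  cell_samples <- stats::setNames(
    rep(manifest$sample_id, vapply(samples, function(s) nrow(s$cells),
                                   integer(1))),
    unlist(lapply(samples, function(s) s$cells$cell_id)))
  cl_cfg <- cfg$clustering
  cl_cfg$seed <- .derive_seed(cfg$seed, 2L)
  global <- embed_and_cluster(expr, cl_cfg, level = "global")
  bundle$clusters <- data.frame(
    cell_id = names(global$assignment$labels),
    sample_id = unname(cell_samples[names(global$assignment$labels)]),
    cluster = unname(global$assignment$labels), stringsAsFactors = FALSE)
  bundle$embedding <- global$embedding

  .log_stage("markers", "per-cluster marker detection")
  k_global <- sort(unique(global$assignment$labels))
  markers <- do.call(rbind, lapply(k_global, function(cl) {
    n_in <- sum(global$assignment$labels == cl)
    if (n_in < 3 || n_in == length(global$assignment$labels)) return(NULL)
    find_markers(expr, counts, global$assignment, cl,
                 min_pct = cfg$min_pct, min_log2fc = cfg$min_log2fc)
  }))
  bundle$markers <- markers

  .log_stage("de", ref_group, " vs ", alt_group)
  de <- NULL
  if (!is.na(alt_group)) {
    de <- differential_expression(
      expr, counts, cell_samples,
      manifest$sample_id[manifest$condition == ref_group],
      manifest$sample_id[manifest$condition == alt_group],
      fc_threshold = cfg$fc_threshold,
      neglog10p_threshold = cfg$neglog10p_threshold)
  }
  bundle$de <- de

  .log_stage("freq", "cluster frequencies and group comparison")
  freqs <- cluster_frequencies(global$assignment, cell_samples)
  bundle$frequencies <- freqs
  freq_cmp <- NULL
  target <- cfg$subcluster_target
  if (!is.na(alt_group) &&
      sum(conditions == ref_group) >= 2 && sum(conditions == alt_group) >= 2) {
    freq_cmp <- compare_frequencies(freqs, conditions, ref_group, alt_group)
    bundle$frequency_comparison <- freq_cmp$table
    if (identical(target, "auto")) {
      tab <- freq_cmp$table
      up <- tab[tab$significant_up, , drop = FALSE]
      target <- if (nrow(up)) {
        up$cluster[which.max(up$mean_b - up$mean_a)]
      } else {
        warning("no significantly implant-enriched cluster; subclustering ",
                "the largest cluster")
        k_global[1]
      }
    }
  } else if (identical(target, "auto")) {
    target <- k_global[1]
  }

  .log_stage("subcluster", "target cluster ", target)
  sub_cfg <- cl_cfg
  sub_cfg$seed <- .derive_seed(cfg$seed, 3L)
  sub <- subcluster(expr, global$assignment, target, sub_cfg)
  sub_freqs <- cluster_frequencies(sub$assignment, cell_samples)
  included <- sort(unique(sub$assignment$labels))
  if (!is.na(alt_group) &&
      sum(conditions == ref_group) >= 2 && sum(conditions == alt_group) >= 2) {
    sub_cmp <- compare_frequencies(sub_freqs, conditions, ref_group,
                                   alt_group)
    if (length(sub_cmp$significant_up)) {
      included <- sub_cmp$significant_up
    } else {
      warning("no subcluster passes the implant-enrichment gate; ",
              "including all subclusters in colocalization")
    }
  }

  .log_stage("distance", "signed distances and regions (implanted samples)")
  dist_tables <- list()
  for (sid in manifest$sample_id[manifest$condition != "skin"]) {
    s <- samples[[sid]]
    if (!"scaffold" %in% names(s$boundaries)) {
      stop("pipeline stage 'distance': sample '", sid,
           "' has no scaffold boundary")
    }
    cap <- s$boundaries[["capsule_outer"]]
    rcfg <- cfg$region
    if (!is.null(cap)) rcfg <- region_config("outer_boundary",
                                             cfg$region$capsule_thickness)
    dt <- assign_regions(s$cells, s$boundaries[["scaffold"]], rcfg,
                         capsule_outer = cap)
    dt <- cbind(sample_id = sid, dt)
    dist_tables[[sid]] <- dt
  }
  distances <- do.call(rbind, c(dist_tables, list(make.row.names = FALSE)))
  bundle$distances <- distances

  sub_in_pcl <- sub$assignment$labels[
    names(sub$assignment$labels) %in% distances$cell_id]
  regions <- NULL
  if (length(sub_in_pcl)) {
    regions <- subcluster_region(
      distances, cluster_assignment(sub$assignment$level, sub_in_pcl))
  }
  bundle$regions <- regions

  .log_stage("coloc", "radius ", cfg$radius, " um, ", length(included),
             " subclusters")
  coloc_mats <- list()
  for (sid in names(dist_tables)) {
    s <- samples[[sid]]
    ids <- intersect(s$cells$cell_id, names(sub$assignment$labels))
    ids <- ids[sub$assignment$labels[ids] %in% included]
    if (length(ids) < 2) next
    cells_sub <- s$cells[s$cells$cell_id %in% ids, , drop = FALSE]
    coloc_mats[[sid]] <- colocalization_matrix(cells_sub, sub$assignment,
                                               included, radius = cfg$radius)
  }
  coloc <- NULL
  if (length(coloc_mats)) {
    subs <- as.character(sort(unique(included)))
    tot <- matrix(0, length(subs), length(subs),
                  dimnames = list(subs, subs))
    n_src <- stats::setNames(rep(0, length(subs)), subs)
    for (m in coloc_mats) {
      tot[m$subclusters, m$subclusters] <-
        tot[m$subclusters, m$subclusters] + m$total_counts
      n_src[m$subclusters] <- n_src[m$subclusters] + m$n_source_cells
    }
    mean_pc <- sweep(tot, 1, pmax(n_src, 1), "/")
    coloc <- structure(list(level = sub$assignment$level,
                            radius = cfg$radius, subclusters = subs,
                            total_counts = tot, mean_per_cell = mean_pc,
                            n_source_cells = n_src),
                       class = "colocalization_matrix")
  }
  bundle$coloc <- coloc

  .log_stage("enrich", "cluster annotation")
  collection <- NULL
  if (!is.null(cfg$gene_sets)) {
    collection <- read_gene_sets(cfg$gene_sets)
  } else if (!is.null(truths)) {
    panel <- truths[[1]]$genes
    sets <- lapply(split(panel$gene[panel$role == "marker"],
                         panel$target[panel$role == "marker"]), identity)
    collection <- gene_set_collection(sets)
  }
  enrichment <- NULL
  if (!is.null(collection) && !is.null(markers) && nrow(markers)) {
    mt <- split(markers$gene, markers$cluster)
    mt <- mt[vapply(mt, length, integer(1)) > 0]
    ann <- annotate_clusters(mt, collection, universe = rownames(counts))
    enrichment <- ann$records
    bundle$annotation <- ann$annotation
  }
  bundle$enrichment <- enrichment

  .log_stage("write", cfg$out_dir)
  out <- function(x, name) {
    if (!is.null(x)) write_table(x, file.path(cfg$out_dir, name))
  }
  out(bundle$qc, "qc.csv")
  out(bundle$qc_comparison, "qc_comparison.csv")
  out(bundle$clusters, "clusters.csv")
  out(bundle$markers, "markers.csv")
  out(bundle$de, "de.csv")
  out(bundle$frequencies, "frequencies.csv")
  out(bundle$frequency_comparison, "frequency_comparison.csv")
  out(bundle$distances, "distances.csv")
  out(bundle$regions, "regions.csv")
  if (!is.null(coloc)) {
    ex <- export_interaction(coloc)
    out(data.frame(source = coloc$subclusters,
                   as.data.frame(coloc$total_counts), check.names = FALSE),
        "coloc_total.csv")
    out(data.frame(source = coloc$subclusters,
                   as.data.frame(coloc$mean_per_cell), check.names = FALSE),
        "coloc_mean.csv")
    out(ex$edges, "coloc_edges.csv")
  }
  out(bundle$enrichment, "enrichment.csv")
  out(bundle$embedding, "embedding.csv")
  meta <- list(package = "stimplant",
               version = as.character(utils::packageVersion("stimplant")),
               seed = cfg$seed, qv_threshold = cfg$qv_threshold,
               radius = cfg$radius,
               clustering = unclass(cfg$clustering),
               subcluster_target = as.character(target),
               included_subclusters = as.character(included),
               n_samples = length(samples),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}
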