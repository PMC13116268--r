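# Synthetic foreign-body-response data generator. Emulates a paired study of
# control skin sections and sections implanted with an elliptical scaffold:
# region-structured cell density (implanted sections about twice as dense
# overall as control skin), immune-enriched cluster composition inside the
# implant, negative-binomial counts with planted marker fold-changes,
# transcripts scattered around cell centroids with a high/low quality-value
# mixture, and full per-cell / per-gene ground truth.

.derive_seed <- function(seed, idx) {
  s <- (as.numeric(seed) %% 2147483647) * 100003 + idx * 7919
  as.integer(s %% 2147483646) + 1L
}

# ellipse discretized counter-clockwise, closing vertex not repeated
.ellipse_polygon <- function(center, semiaxes, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + semiaxes[1] * cos(th),
        center[2] + semiaxes[2] * sin(th))
}

# outward normal offset of the ellipse by `t` (the locus of points at
# distance t from a smooth convex curve)
.ellipse_offset_polygon <- function(center, semiaxes, t, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nx <- semiaxes[2] * cos(th)
  ny <- semiaxes[1] * sin(th)
  nn <- sqrt(nx^2 + ny^2)
  cbind(center[1] + semiaxes[1] * cos(th) + t * nx / nn,
        center[2] + semiaxes[2] * sin(th) + t * ny / nn)
}

# distance of points to the ellipse outline via dense boundary sampling;
# this analytic-sampling route is deliberately independent of the polygon
# segment-distance code in the spatial metrics
.ellipse_outline_distance <- function(points, center, semiaxes,
                                      n_samples = 4096) {
  th <- seq(0, 2 * pi, length.out = n_samples + 1)[-(n_samples + 1)]
  bx <- center[1] + semiaxes[1] * cos(th)
  by <- center[2] + semiaxes[2] * sin(th)
  px <- points[, 1]
  py <- points[, 2]
  d2 <- rep(Inf, length(px))
  for (s in seq_len(n_samples)) {  # running minimum, one boundary sample at a time
    d2 <- pmin(d2, (px - bx[s])^2 + (py - by[s])^2)
  }
  sqrt(d2)
}

.ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Simulation configuration
#'
#' The default world: a 1400 x 1000 µm field; an elliptical scaffold
#' (semi-axes 350 x 180 µm) with a 100 µm fibrotic capsule; native skin at
#' 1000 cells/mm² with implant-region densities solved so that the overall
#' implanted-to-skin cell density ratio equals `density_ratio` (default
#' 2.02); five cell types whose implant-region composition is solved from
#' the stated condition-level fold changes (macrophages 2.6-fold up,
#' neutrophils 26-fold up, keratinocytes 2.7-fold down in implanted vs
#' skin sections); negative-binomial counts with planted per-type marker
#' genes, region-linked macrophage subtype markers and implant-response
#' genes; and an 85.2% / 14.8% high/low transcript-quality mixture.
#'
#' @param field_size (W, H) of the imaged field, µm.
#' @param scaffold_center ellipse center, µm; default field center.
#' @param scaffold_semiaxes ellipse semi-axes, µm.
#' @param capsule_thickness capsule band thickness, µm.
#' @param skin_density native-skin cell density, cells/mm².
#' @param density_ratio target overall cell-density ratio of implanted
#'   sections over skin sections.
#' @param capsule_density_factor capsule density as a multiple of the
#'   scaffold-body density.
#' @param skin_composition named probability vector over cell types in
#'   native skin (must sum to 1).
#' @param condition_folds named vector of condition-level frequency fold
#'   changes (implanted over skin) enforced in expectation for the named
#'   types; remaining probability mass is split among the other types in
#'   their skin proportions.
#' @param n_genes total panel size; must accommodate all planted genes.
#' @param n_marker_genes marker genes per cell type.
#' @param marker_log2fc,marker_pct fold change and expressing fraction of
#'   type markers.
#' @param subtype_types cell types that split into region-linked subtypes
#'   (body/capsule/skin) in implanted sections.
#' @param n_subtype_genes,subtype_log2fc,subtype_pct subtype marker panel.
#' @param n_response_genes,response_log2fc genes upregulated in every cell
#'   inside the implant (body or capsule) of implanted sections.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_mean expected counts per gene per cell before library
#'   and fold effects.
#' @param libsize_sigma log-normal sd of the per-cell library factor.
#' @param qv_high_frac probability a transcript is high quality.
#' @param qv_high_range,qv_low_range quality-value ranges of the two
#'   mixture components.
#' @param unassigned_frac expected extracellular transcripts as a fraction
#'   of assigned transcripts.
#' @param transcript_scatter max distance of a transcript from its cell
#'   centroid, µm.
#' @param n_samples_per_condition samples per condition in a study.
#' @param seed study seed; per-sample seeds are derived from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    field_size = c(1400, 1000),
    scaffold_center = NULL,
    scaffold_semiaxes = c(350, 180),
    capsule_thickness = 100,
    skin_density = 1000,
    density_ratio = 2.02,
    capsule_density_factor = 1.2,
    skin_composition = c(fibroblast = 0.30, keratinocyte = 0.35,
                         macrophage = 0.08, endothelial = 0.266,
                         neutrophil = 0.004),
    condition_folds = c(macrophage = 2.6, neutrophil = 26,
                        keratinocyte = 1 / 2.7),
    n_genes = 120,
    n_marker_genes = 8, marker_log2fc = 3, marker_pct = 0.9,
    subtype_types = "macrophage",
    n_subtype_genes = 6, subtype_log2fc = 2.5, subtype_pct = 0.9,
    n_response_genes = 10, response_log2fc = 2,
    nb_dispersion = 0.5,
    baseline_mean = 0.4,
    libsize_sigma = 0.3,
    qv_high_frac = 0.852,
    qv_high_range = c(20, 40), qv_low_range = c(4, 20),
    unassigned_frac = 0.12,
    transcript_scatter = 10,
    n_samples_per_condition = 4,
    seed = 1) {
  if (is.null(scaffold_center)) scaffold_center <- field_size / 2
  if (abs(sum(skin_composition) - 1) > 1e-9) {
    stop("skin_composition must sum to 1")
  }
  if (!all(names(condition_folds) %in% names(skin_composition))) {
    stop("condition_folds names must be cell types of skin_composition")
  }
  if (qv_high_frac < 0 || qv_high_frac > 1) stop("qv_high_frac not in [0,1]")
  if (skin_density < 0) stop("densities must be >= 0")
  reach <- scaffold_semiaxes + capsule_thickness
  if (any(scaffold_center - reach < 0) ||
      any(scaffold_center + reach > field_size)) {
    stop("degenerate geometry: scaffold plus capsule exceeds the field")
  }
  cfg <- list(field_size = field_size, scaffold_center = scaffold_center,
              scaffold_semiaxes = scaffold_semiaxes,
              capsule_thickness = capsule_thickness,
              skin_density = skin_density, density_ratio = density_ratio,
              capsule_density_factor = capsule_density_factor,
              skin_composition = skin_composition,
              condition_folds = condition_folds,
              n_genes = as.integer(n_genes),
              n_marker_genes = as.integer(n_marker_genes),
              marker_log2fc = marker_log2fc, marker_pct = marker_pct,
              subtype_types = subtype_types,
              n_subtype_genes = as.integer(n_subtype_genes),
              subtype_log2fc = subtype_log2fc, subtype_pct = subtype_pct,
              n_response_genes = as.integer(n_response_genes),
              response_log2fc = response_log2fc,
              nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
              libsize_sigma = libsize_sigma, qv_high_frac = qv_high_frac,
              qv_high_range = qv_high_range, qv_low_range = qv_low_range,
              unassigned_frac = unassigned_frac,
              transcript_scatter = transcript_scatter,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  .gene_panel(cfg)  # errors early when n_genes cannot host the planted genes
  cfg
}

# The gene panel: per-type markers, region-linked subtype markers,
# implant-response genes, housekeeping filler.
.gene_panel <- function(cfg) {
  types <- names(cfg$skin_composition)
  rows <- list()
  for (ty in types) {
    if (cfg$n_marker_genes > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = sprintf("%s_m%02d", ty, seq_len(cfg$n_marker_genes)),
        role = "marker", target = ty, log2fc = cfg$marker_log2fc,
        pct = cfg$marker_pct, stringsAsFactors = FALSE)
    }
  }
  for (ty in cfg$subtype_types) {
    for (reg in c("body", "capsule", "skin")) {
      if (cfg$n_subtype_genes > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = sprintf("%s_%s_s%02d", ty, reg,
                         seq_len(cfg$n_subtype_genes)),
          role = "subtype_marker", target = paste(ty, reg, sep = "_"),
          log2fc = cfg$subtype_log2fc, pct = cfg$subtype_pct,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$n_response_genes > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      gene = sprintf("implant_r%02d", seq_len(cfg$n_response_genes)),
      role = "response", target = "implant", log2fc = cfg$response_log2fc,
      pct = 1, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  n_left <- cfg$n_genes - nrow(panel)
  if (n_left < 0) {
    stop("n_genes = ", cfg$n_genes, " cannot host the ", nrow(panel),
         " planted genes")
  }
  if (n_left > 0) {
    panel <- rbind(panel, data.frame(
      gene = sprintf("hk_g%03d", seq_len(n_left)), role = "baseline",
      target = "", log2fc = 0, pct = 1, stringsAsFactors = FALSE))
  }
  panel
}

# Region areas (µm²) and the solved per-region densities (cells/µm²) for an
# implanted section.
.implant_geometry <- function(cfg) {
  a <- cfg$scaffold_semiaxes[1]
  b <- cfg$scaffold_semiaxes[2]
  t <- cfg$capsule_thickness
  A_field <- prod(cfg$field_size)
  A_body <- pi * a * b
  L <- .ramanujan_perimeter(a, b)
  A_capsule <- L * t + pi * t^2
  A_skin <- A_field - A_body - A_capsule
  d_skin <- cfg$skin_density / 1e6  # cells per µm²
  fc <- cfg$capsule_density_factor
  # overall implanted density = density_ratio * skin density
  d_body <- d_skin * (cfg$density_ratio * A_field - A_skin) /
    (A_body + fc * A_capsule)
  if (d_body < 0) stop("density_ratio unreachable with this geometry")
  list(areas = c(scaffold_body = A_body, capsule = A_capsule, skin = A_skin),
       densities = c(scaffold_body = d_body, capsule = fc * d_body,
                     skin = d_skin))
}

# Cluster composition of the implant regions solved from the condition-level
# fold targets; remaining mass split among unconstrained types in skin
# proportions.
.implant_composition <- function(cfg, geom) {
  exp_counts <- geom$areas * geom$densities
  f_skin <- exp_counts[["skin"]] / sum(exp_counts)
  f_impl <- 1 - f_skin
  comp <- cfg$skin_composition
  p_impl <- stats::setNames(numeric(length(comp)), names(comp))
  for (ty in names(cfg$condition_folds)) {
    p <- comp[[ty]] * (cfg$condition_folds[[ty]] - f_skin) / f_impl
    p_impl[ty] <- max(0, p)
  }
  fixed <- names(cfg$condition_folds)
  if (sum(p_impl[fixed]) > 1) {
    stop("condition_folds infeasible: constrained types exceed probability 1")
  }
  free <- setdiff(names(comp), fixed)
  p_impl[free] <- (1 - sum(p_impl[fixed])) * comp[free] / sum(comp[free])
  p_impl
}

#' Simulate one spatial sample with ground truth
#'
#' Cells are placed by a homogeneous Poisson process per region (skin
#' sections: skin density everywhere, every cell in region `"skin"`), a
#' cell type is drawn from the region's composition, counts are negative
#' binomial with a log-normal per-cell library factor and the planted
#' marker/subtype/response fold changes, and counts are expanded into
#' transcripts scattered uniformly within `transcript_scatter` µm of the
#' cell centroid with the configured quality mixture, plus a Poisson number
#' of unassigned extracellular transcripts. Implanted sections carry the
#' scaffold and capsule-outer boundary polygons; every sample carries the
#' field rectangle as `tissue_roi`.
#'
#' @param cfg a [simulation_config()].
#' @param condition `"skin"` or `"PCL"`.
#' @param seed integer seed; identical (cfg, condition, seed, sample_id)
#'   reproduce the sample exactly.
#' @param sample_id identifier stamped on cells and transcripts.
#' @return List with `sample` (a validated [spatial_sample()]) and `truth`
#'   (list: `cells` data frame with true region/cluster/subcluster, `genes`
#'   data frame with planted roles and fold changes, `densities`,
#'   `composition`, `config`).
#' @export
simulate_sample <- function(cfg, condition = c("PCL", "skin"), seed = 1,
                            sample_id = NULL) {
  condition <- match.arg(condition)
  if (is.null(sample_id)) sample_id <- condition
  set.seed(seed)
  W <- cfg$field_size[1]
  H <- cfg$field_size[2]
  if (condition == "PCL") {
    geom <- .implant_geometry(cfg)
    dens <- geom$densities
    dmax <- max(dens)
    n_cand <- stats::rpois(1, dmax * W * H)
    px <- stats::runif(n_cand, 0, W)
    py <- stats::runif(n_cand, 0, H)
    # analytic region truth: ellipse containment + sampled-outline distance
    u <- ((px - cfg$scaffold_center[1]) / cfg$scaffold_semiaxes[1])^2 +
      ((py - cfg$scaffold_center[2]) / cfg$scaffold_semiaxes[2])^2
    inside <- u < 1
    dist_out <- .ellipse_outline_distance(cbind(px, py), cfg$scaffold_center,
                                          cfg$scaffold_semiaxes)
    region <- ifelse(inside, "scaffold_body",
                     ifelse(dist_out <= cfg$capsule_thickness,
                            "capsule", "skin"))
    keep <- stats::runif(n_cand) < dens[region] / dmax
    px <- px[keep]; py <- py[keep]; region <- region[keep]
    comp_impl <- .implant_composition(cfg, geom)
    composition <- list(scaffold_body = comp_impl, capsule = comp_impl,
                        skin = cfg$skin_composition)
    densities <- dens * 1e6
  } else {
    n_cells <- stats::rpois(1, cfg$skin_density / 1e6 * W * H)
    px <- stats::runif(n_cells, 0, W)
    py <- stats::runif(n_cells, 0, H)
    region <- rep("skin", n_cells)
    composition <- list(skin = cfg$skin_composition)
    densities <- c(skin = cfg$skin_density)
  }
  n <- length(px)
  if (n == 0) stop("simulate_sample: zero cells generated")
  types <- names(cfg$skin_composition)
  cluster <- character(n)
  for (reg in unique(region)) {
    idx <- which(region == reg)
    cluster[idx] <- sample(types, length(idx), replace = TRUE,
                           prob = composition[[reg]])
  }
  # region-linked subtypes (implant sections place them by true region)
  region_short <- c(scaffold_body = "body", capsule = "capsule",
                    skin = "skin")
  subcluster <- ifelse(
    cluster %in% cfg$subtype_types,
    paste(cluster, region_short[region], sep = "_"), cluster)

  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n))
  cells <- data.frame(cell_id = cell_id, x = px, y = py,
                      area = stats::rlnorm(n, log(100), 0.25),
                      stringsAsFactors = FALSE)

  panel <- .gene_panel(cfg)
  G <- nrow(panel)
  lib <- stats::rlnorm(n, -cfg$libsize_sigma^2 / 2, cfg$libsize_sigma)
  mu <- matrix(cfg$baseline_mean, G, n) * rep(lib, each = G)
  for (g in seq_len(G)) {
    role <- panel$role[g]
    if (role == "baseline") next
    hit <- if (role == "marker") {
      cluster == panel$target[g]
    } else if (role == "subtype_marker") {
      subcluster == panel$target[g]
    } else {
      condition == "PCL" & region %in% c("scaffold_body", "capsule")
    }
    if (!any(hit)) next
    expressing <- hit & (stats::runif(n) < panel$pct[g])
    mu[g, expressing] <- mu[g, expressing] * 2^panel$log2fc[g]
  }
  counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                  size = 1 / cfg$nb_dispersion), G, n,
                   dimnames = list(panel$gene, cell_id))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")

  # expand counts into transcript records around each centroid
  trip <- Matrix::summary(counts)
  gi <- rep(trip$i, trip$x)
  ci <- rep(trip$j, trip$x)
  n_tx <- length(gi)
  rr <- cfg$transcript_scatter * sqrt(stats::runif(n_tx))
  th <- stats::runif(n_tx, 0, 2 * pi)
  tx <- px[ci] + rr * cos(th)
  ty <- py[ci] + rr * sin(th)
  n_extra <- stats::rpois(1, cfg$unassigned_frac * n_tx)
  gene_freq <- tabulate(gi, nbins = G) + 1
  gx <- sample.int(G, n_extra, replace = TRUE, prob = gene_freq)
  all_gene <- panel$gene[c(gi, gx)]
  all_x <- c(tx, stats::runif(n_extra, 0, W))
  all_y <- c(ty, stats::runif(n_extra, 0, H))
  all_cell <- c(cell_id[ci], rep("unassigned", n_extra))
  m <- length(all_gene)
  high <- stats::runif(m) < cfg$qv_high_frac
  qv <- ifelse(high,
               stats::runif(m, cfg$qv_high_range[1], cfg$qv_high_range[2]),
               stats::runif(m, cfg$qv_low_range[1], cfg$qv_low_range[2]))
  transcripts <- data.frame(
    transcript_id = sprintf("%s_t%07d", sample_id, seq_len(m)),
    gene = all_gene, x = pmin(pmax(all_x, 0), W),
    y = pmin(pmax(all_y, 0), H), qv = qv, cell_id = all_cell,
    stringsAsFactors = FALSE)

  boundaries <- list()
  if (condition == "PCL") {
    boundaries$scaffold <- boundary_annotation(
      "scaffold", .ellipse_polygon(cfg$scaffold_center,
                                   cfg$scaffold_semiaxes))
    boundaries$capsule_outer <- boundary_annotation(
      "capsule_outer", .ellipse_offset_polygon(cfg$scaffold_center,
                                               cfg$scaffold_semiaxes,
                                               cfg$capsule_thickness))
  }
  roi <- boundary_annotation("tissue_roi",
                             rbind(c(0, 0), c(W, 0), c(W, H), c(0, H)))
  sample <- spatial_sample(sample_id, condition, transcripts, cells, counts,
                           boundaries = boundaries, tissue_roi = roi)
  ord <- order(cells$cell_id)
  truth <- list(cells = data.frame(cell_id = cell_id[ord],
                                   region = region[ord],
                                   cluster = cluster[ord],
                                   subcluster = subcluster[ord],
                                   stringsAsFactors = FALSE),
                genes = panel, densities = densities,
                composition = composition, config = cfg)
  list(sample = sample, truth = truth)
}

#' Simulate a full two-condition study
#'
#' `n_samples_per_condition` skin and implanted sections with per-sample
#' seeds derived deterministically from the study seed, plus a manifest.
#'
#' @param cfg a [simulation_config()].
#' @return List with `samples` (named list of [spatial_sample()]), `truths`
#'   (matching ground-truth lists) and `manifest` (data frame `sample_id,
#'   condition, seed`).
#' @export
simulate_study <- function(cfg) {
  samples <- list()
  truths <- list()
  rows <- list()
  idx <- 0
  for (condition in c("skin", "PCL")) {
    for (i in seq_len(cfg$n_samples_per_condition)) {
      idx <- idx + 1
      sid <- sprintf("%s%d", condition, i)
      sd <- .derive_seed(cfg$seed, idx)
      res <- simulate_sample(cfg, condition, seed = sd, sample_id = sid)
      samples[[sid]] <- res$sample
      truths[[sid]] <- res$truth
      rows[[idx]] <- data.frame(sample_id = sid, condition = condition,
                                seed = sd, stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, truths = truths,
       manifest = do.call(rbind, rows))
}

#' Planted-marker count matrix for filter power testing
#'
#' A two-cluster negative-binomial count matrix with a designated fraction
#' of cells forming a target cluster in which `n_markers` genes are
#' upregulated by `log2fc` in a fraction `pct` of cells. Cluster labels
#' follow the size-ordering convention (0 = larger background cluster,
#' 1 = planted cluster).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_markers planted marker genes (named `mk_*`; the rest `bg_*`).
#' @param log2fc,pct planted fold change and expressing fraction.
#' @param cluster_frac fraction of cells in the planted cluster.
#' @param baseline_mean,dispersion,libsize_sigma negative-binomial world.
#' @param seed RNG seed.
#' @return List with `counts` (sparse), `labels` (named 0/1 vector),
#'   `marker_genes`.
#' @export
simulate_marker_matrix <- function(n_cells = 500, n_genes = 300,
                                   n_markers = 20, log2fc = 2, pct = 0.8,
                                   cluster_frac = 0.3, baseline_mean = 1,
                                   dispersion = 0.5, libsize_sigma = 0.3,
                                   seed = 1) {
  set.seed(seed)
  n_target <- round(n_cells * cluster_frac)
  labels <- c(rep(1L, n_target), rep(0L, n_cells - n_target))
  cell_id <- sprintf("c%04d", seq_len(n_cells))
  names(labels) <- cell_id
  genes <- c(sprintf("mk_%03d", seq_len(n_markers)),
             sprintf("bg_%03d", seq_len(n_genes - n_markers)))
  lib <- stats::rlnorm(n_cells, -libsize_sigma^2 / 2, libsize_sigma)
  mu <- matrix(baseline_mean, n_genes, n_cells) * rep(lib, each = n_genes)
  for (g in seq_len(n_markers)) {
    expressing <- labels == 1L & stats::runif(n_cells) < pct
    mu[g, expressing] <- mu[g, expressing] * 2^log2fc
  }
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = 1 / dispersion),
                   n_genes, n_cells, dimnames = list(genes, cell_id))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       labels = labels, marker_genes = genes[seq_len(n_markers)])
}
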