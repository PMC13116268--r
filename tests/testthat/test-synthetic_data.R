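small_cfg <- function(...) {
  simulation_config(field_size = c(800, 600), scaffold_semiaxes = c(200, 120),
                    skin_density = 800, n_genes = 60, n_marker_genes = 4,
                    n_subtype_genes = 3, n_response_genes = 4,
                    baseline_mean = 0.3, ...)
}

test_that("identical config and seed reproduce a sample exactly", {
  cfg <- small_cfg()
  a <- simulate_sample(cfg, "PCL", seed = 5, sample_id = "p")
  b <- simulate_sample(cfg, "PCL", seed = 5, sample_id = "p")
  expect_identical(a$sample$transcripts, b$sample$transcripts)
  expect_identical(a$sample$cells, b$sample$cells)
  expect_identical(as.matrix(a$sample$counts), as.matrix(b$sample$counts))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("every emitted sample passes validation and matches its truth rows", {
  cfg <- small_cfg(n_samples_per_condition = 1)
  st <- simulate_study(cfg)
  for (sid in names(st$samples)) {
    expect_silent(validate_spatial_sample(st$samples[[sid]]))
    expect_identical(st$samples[[sid]]$cells$cell_id,
                     st$truths[[sid]]$cells$cell_id)
  }
  skin <- st$samples$skin1
  expect_length(skin$boundaries, 0)
  expect_true(all(st$truths$skin1$cells$region == "skin"))
  pcl <- st$samples$PCL1
  expect_setequal(names(pcl$boundaries), c("scaffold", "capsule_outer"))
})

test_that("realized per-region counts follow the Poisson intensities", {
  cfg <- simulation_config()
  res <- simulate_sample(cfg, "PCL", seed = 17, sample_id = "p")
  geom <- stimplant:::.implant_geometry(cfg)
  lambda <- geom$areas * geom$densities  # expected cells per region
  realized <- table(res$truth$cells$region)[names(lambda)]
  for (reg in names(lambda)) {
    expect_lt(abs(realized[[reg]] - lambda[[reg]]), 4 * sqrt(lambda[[reg]]))
  }
  # overall density ratio ~ density_ratio by construction
  skin <- simulate_sample(cfg, "skin", seed = 18, sample_id = "s")
  ratio <- nrow(res$sample$cells) / nrow(skin$sample$cells)
  expect_lt(abs(ratio - cfg$density_ratio), 0.25)
})

test_that("the quality-value mixture recovers qv_high_frac", {
  cfg <- small_cfg(qv_high_frac = 0.852)
  res <- simulate_sample(cfg, "PCL", seed = 19, sample_id = "p")
  qc <- compute_qc(res$sample, qv_threshold = 20)
  expect_gt(qc$n_transcripts, 5000)
  expect_lt(abs(qc$frac_high_quality - 0.852), 0.02)
})

test_that("ground-truth regions agree with assign_regions off-boundary", {
  res <- simulate_sample(small_cfg(), "PCL", seed = 23, sample_id = "p")
  s <- res$sample
  dt <- assign_regions(s$cells, s$boundaries$scaffold,
                       region_config("outer_boundary"),
                       capsule_outer = s$boundaries$capsule_outer)
  d_sc <- abs(signed_distance(cbind(s$cells$x, s$cells$y),
                              s$boundaries$scaffold))
  d_cap <- abs(signed_distance(cbind(s$cells$x, s$cells$y),
                               s$boundaries$capsule_outer))
  far <- d_sc > 1 & d_cap > 1
  expect_gt(sum(far), 100)
  expect_equal(mean(dt$region[far] == res$truth$cells$region[far]), 1)
})

test_that("degenerate geometry is rejected", {
  expect_error(simulation_config(field_size = c(500, 400),
                                 scaffold_semiaxes = c(300, 100)),
               "degenerate geometry")
})

test_that("planted markers are recovered by find_markers on one seed", {
  w <- simulate_marker_matrix(seed = 3)
  expr <- normalize_counts(w$counts)
  mk <- find_markers(expr, w$counts, cluster_assignment("global", w$labels),
                     1, min_pct = 0.5, min_log2fc = 0.25)
  hits <- intersect(mk$gene, w$marker_genes)
  fps <- setdiff(mk$gene, w$marker_genes)
  expect_gte(length(hits), 19)
  expect_lt(length(fps), 0.05 * (300 - 20))
})

test_that("a study has the right shape and deterministic per-sample seeds", {
  cfg <- small_cfg(n_samples_per_condition = 4, seed = 99)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$manifest), 8)
  expect_equal(sum(st$manifest$condition == "PCL"), 4)
  expect_equal(length(unique(st$manifest$seed)), 8)
  st2 <- simulate_study(cfg)
  expect_identical(st$manifest, st2$manifest)
  expect_identical(st$samples$PCL2$transcripts, st2$samples$PCL2$transcripts)
})

test_that("the planted frequency shifts are recovered at study level", {
  cfg <- simulation_config(field_size = c(800, 600),
                           scaffold_semiaxes = c(200, 120),
                           skin_density = 800, n_genes = 30,
                           n_marker_genes = 2, n_subtype_genes = 1,
                           n_response_genes = 2, baseline_mean = 0.05,
                           n_samples_per_condition = 4, seed = 7)
  st <- simulate_study(cfg)
  truth <- do.call(rbind, lapply(st$truths, function(t) t$cells))
  labels <- setNames(truth$cluster, truth$cell_id)
  cell_samples <- setNames(
    rep(st$manifest$sample_id,
        vapply(st$samples, function(s) nrow(s$cells), integer(1))),
    unlist(lapply(st$samples, function(s) s$cells$cell_id)))
  freqs <- cluster_frequencies(cluster_assignment("truth", labels),
                               cell_samples)
  groups <- setNames(st$manifest$condition, st$manifest$sample_id)
  cmp <- compare_frequencies(freqs, groups, "skin", "PCL")
  mac <- cmp$table[cmp$table$cluster == "macrophage", ]
  expect_lt(abs(mac$fold_change - 2.6), 0.6)
  expect_true("macrophage" %in% cmp$significant_up)
  ker <- cmp$table[cmp$table$cluster == "keratinocyte", ]
  expect_lt(ker$fold_change, 1)  # 2.7-fold decrease direction
})
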