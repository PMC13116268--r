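square10 <- boundary_annotation(
  "scaffold", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))

test_that("signed distance on the unit-10 square matches hand geometry", {
  pts <- rbind(c(5, 5), c(15, 5), c(10, 5), c(5, -3), c(-4, -3))
  d <- signed_distance(pts, square10)
  expect_equal(d[1], -5)   # center: inside, nearest edge 5 away
  expect_equal(d[2], 5)    # outside, nearest edge x = 10
  expect_equal(d[3], 0)    # exactly on the boundary
  expect_equal(d[4], 3)    # below the bottom edge
  expect_equal(d[5], 5)    # nearest vertex (0,0): corner behavior
})

test_that("signed distance agrees with the dense-sampling oracle", {
  set.seed(101)
  poly <- random_simple_polygon(12)
  b <- boundary_annotation("b", poly)
  pts <- cbind(runif(300, -120, 120), runif(300, -120, 120))
  d <- signed_distance(pts, b)
  oracle <- oracle_signed_distance(pts, b$vertices, samples_per_edge = 2000)
  off <- abs(oracle) > 0.05  # off-boundary points
  expect_true(all(sign(d[off]) == sign(oracle[off])))
  expect_lt(max(abs(abs(d) - abs(oracle))), 0.01)
})

test_that("distances are rigid-motion invariant and scale linearly", {
  set.seed(103)
  poly <- random_simple_polygon(9)
  pts <- cbind(runif(100, -150, 150), runif(100, -150, 150))
  d0 <- signed_distance(pts, boundary_annotation("b", poly))
  # translation + rotation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(37, -12)
  tf <- function(m) sweep(m %*% R, 2, shift, "+")
  d1 <- signed_distance(tf(pts), boundary_annotation("b", tf(poly)))
  expect_equal(d1, d0, tolerance = 1e-9)
  # scaling
  d2 <- signed_distance(pts * 3.5, boundary_annotation("b", poly * 3.5))
  expect_equal(d2, d0 * 3.5, tolerance = 1e-9)
})

test_that("multi-part scaffolds use the nearest component, inside any is negative", {
  sq1 <- boundary_annotation("s1", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  sq2 <- boundary_annotation("s2", rbind(c(30, 0), c(40, 0), c(40, 10), c(30, 10)))
  pts <- rbind(c(5, 5), c(35, 5), c(20, 5))
  d <- signed_distance(pts, list(sq1, sq2))
  expect_equal(d, c(-5, -5, 10))

  # open polyline rejected
  open_b <- boundary_annotation("line", rbind(c(0, 0), c(1, 0)), closed = FALSE)
  expect_error(signed_distance(pts, open_b), "closed")
})

test_that("region rules: sign, fixed band, tie at d = 0", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:4),
                      x = c(5, 10, 50, 160), y = c(5, 5, 5, 5))
  cfg <- region_config("fixed_thickness", 100)
  dt <- assign_regions(cells, square10, cfg)
  expect_equal(dt$region, c("scaffold_body", "capsule", "capsule", "skin"))
  expect_equal(dt$distance, c(-5, 0, 40, 150))
  # d = 0 is capsule, d = 150 > thickness is skin, d = 40 capsule
  # region is a partition
  expect_equal(nrow(dt), nrow(cells))
  expect_false(any(is.na(dt$region)))
})

test_that("outer-boundary capsule mode uses the annotated polygon", {
  outer <- boundary_annotation(
    "capsule_outer", rbind(c(-20, -20), c(30, -20), c(30, 30), c(-20, 30)))
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      x = c(5, 20, 60), y = c(5, 5, 5))
  dt <- assign_regions(cells, square10, region_config("outer_boundary"),
                       capsule_outer = outer)
  expect_equal(dt$region, c("scaffold_body", "capsule", "skin"))
  # capsule_outer not enclosing the scaffold is a geometry error
  bad <- boundary_annotation("capsule_outer",
                             rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8)))
  expect_error(assign_regions(cells, square10,
                              region_config("outer_boundary"),
                              capsule_outer = bad),
               "enclose")
  # missing capsule_outer in that mode
  expect_error(assign_regions(cells, square10,
                              region_config("outer_boundary")),
               "required")
})

test_that("shrinking the capsule band never moves skin cells into the capsule", {
  set.seed(107)
  cells <- data.frame(cell_id = sprintf("c%03d", 1:200),
                      x = runif(200, -50, 60), y = runif(200, -50, 60))
  thick <- c(40, 30, 20, 10)
  prev <- NULL
  for (t in thick) {
    dt <- assign_regions(cells, square10, region_config("fixed_thickness", t))
    if (!is.null(prev)) {
      moved <- prev$region == "skin" & dt$region == "capsule"
      expect_false(any(moved))
    }
    prev <- dt
  }
})

test_that("subcluster_region takes the majority region with the median tie-break", {
  dt <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    distance = c(seq(-50, -5, length.out = 10),   # 10 cells inside
                 c(10, 20, 30, 40, 50, 120, 130, 140, 150, 160)),
    region = c(rep("scaffold_body", 10), rep("capsule", 5), rep("skin", 5)),
    stringsAsFactors = FALSE)
  labels <- setNames(c(rep(0L, 10), rep(1L, 10)), dt$cell_id)
  res <- subcluster_region(dt, cluster_assignment("sub", labels))
  expect_equal(res$region[res$cluster == 0], "scaffold_body")
  # cluster 1: 5 capsule vs 5 skin; median distance (85) nearest cell is 50
  # (capsule) or 120 (skin) -> 50 is closer? |50-85|=35, |120-85|=35: tie on
  # distance, smallest cell_id wins -> c15 (capsule)
  expect_equal(res$region[res$cluster == 1], "capsule")
  expect_equal(res$n_cells, c(10L, 10L))
  expect_equal(res$median_distance[1], median(dt$distance[1:10]))
  # empty subcluster errors
  labels2 <- setNames(rep(2L, 3), c("x1", "x2", "x3"))
  expect_error(subcluster_region(dt, cluster_assignment("sub", labels2)),
               "no cells")
})

test_that("planted region-specific subclusters are labelled perfectly", {
  res <- simulate_sample(simulation_config(), "PCL", seed = 11,
                         sample_id = "p1")
  s <- res$sample
  truth <- res$truth$cells
  dt <- assign_regions(s$cells, s$boundaries$scaffold,
                       region_config("outer_boundary"),
                       capsule_outer = s$boundaries$capsule_outer)
  # macrophage subtypes are planted by region: their majority label must
  # match the region encoded in the subtype name
  macs <- truth[grepl("^macrophage_", truth$subcluster), ]
  labels <- setNames(macs$subcluster, macs$cell_id)
  sr <- subcluster_region(dt[dt$cell_id %in% macs$cell_id, ],
                          cluster_assignment("macs", labels))
  expected <- c(macrophage_body = "scaffold_body",
                macrophage_capsule = "capsule", macrophage_skin = "skin")
  expect_equal(sr$region, unname(expected[sr$cluster]))
})
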