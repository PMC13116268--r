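# Localization analysis: signed perpendicular distance of every cell to the
# scaffold surface (negative = inside the scaffold), assignment of each cell
# to one of three regions (scaffold body, fibrotic capsule, native skin) and
# per-subcluster region summaries for violin-style distance profiles.

#' Region-assignment configuration
#'
#' The capsule can be delimited either by a manually annotated outer
#' boundary (mirroring trichrome-guided annotation) or, annotation-free, as
#' a fixed-thickness band outside the scaffold surface.
#'
#' @param capsule_mode `"fixed_thickness"` (default) or `"outer_boundary"`.
#' @param capsule_thickness band thickness in µm for the fixed mode
#'   (default 100).
#' @return A `region_config` list.
#' @export
region_config <- function(capsule_mode = c("fixed_thickness",
                                           "outer_boundary"),
                          capsule_thickness = 100) {
  capsule_mode <- match.arg(capsule_mode)
  if (capsule_mode == "fixed_thickness" && capsule_thickness <= 0) {
    stop("capsule_thickness must be > 0 in fixed_thickness mode")
  }
  structure(list(capsule_mode = capsule_mode,
                 capsule_thickness = capsule_thickness),
            class = "region_config")
}

#' Signed perpendicular distance to a boundary
#'
#' Magnitude is the minimum Euclidean distance from each point to any
#' boundary segment (the perpendicular foot where it exists, else the
#' nearest vertex); the sign is negative iff the point lies inside the
#' polygon (even-odd rule) and exactly 0 on the boundary. A list of
#' boundaries is treated as a multi-part scaffold: magnitude to the nearest
#' component, negative inside any component.
#'
#' @param points two-column matrix (or data frame) of (x, y) µm query
#'   points.
#' @param boundary a closed [boundary_annotation()] or a list of them.
#' @return Numeric vector of signed distances in µm.
#' @export
signed_distance <- function(points, boundary) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  parts <- if (inherits(boundary, "boundary_annotation")) list(boundary)
           else boundary
  if (!length(parts)) stop("signed_distance: no boundary given")
  dmin <- rep(Inf, nrow(points))
  inside <- rep(FALSE, nrow(points))
  for (b in parts) {
    if (!inherits(b, "boundary_annotation") || !isTRUE(b$closed)) {
      stop("geometry error: signed_distance requires closed boundary polygons")
    }
    dmin <- pmin(dmin, points_outline_distance(points, b$vertices))
    inside <- inside | point_in_polygon(points, b$vertices)
  }
  ifelse(inside & dmin > 0, -dmin, dmin)
}

#' Assign cells to scaffold body, capsule, or native skin
#'
#' Region rules on the signed distance d to the scaffold surface:
#' `scaffold_body` when d < 0; otherwise `capsule` when the cell is inside
#' the capsule outer boundary (outer_boundary mode) or when
#' 0 <= d <= thickness (fixed mode); otherwise `skin`. Cells exactly on the
#' scaffold surface (d = 0) belong to the capsule — the surface is the
#' body/capsule interface.
#'
#' @param cells data frame with `cell_id, x, y` columns.
#' @param scaffold scaffold surface: a closed [boundary_annotation()] or a
#'   list of them (fragmented cross-section).
#' @param cfg a [region_config()].
#' @param capsule_outer closed [boundary_annotation()] of the capsule outer
#'   edge; required in `outer_boundary` mode and checked to enclose every
#'   scaffold vertex.
#' @return Data frame (`distance_table`): `cell_id, distance, region` with
#'   `region` in `{scaffold_body, capsule, skin}`.
#' @export
assign_regions <- function(cells, scaffold, cfg = region_config(),
                           capsule_outer = NULL) {
  pts <- cbind(cells$x, cells$y)
  d <- signed_distance(pts, scaffold)
  if (cfg$capsule_mode == "outer_boundary") {
    if (is.null(capsule_outer)) {
      stop("capsule_outer boundary required in outer_boundary mode")
    }
    parts <- if (inherits(scaffold, "boundary_annotation")) list(scaffold)
             else scaffold
    for (b in parts) {
      if (!all(point_in_polygon(b$vertices, capsule_outer$vertices))) {
        stop("geometry error: capsule_outer does not enclose the scaffold")
      }
    }
    in_cap <- point_in_polygon(pts, capsule_outer$vertices) |
      points_outline_distance(pts, capsule_outer$vertices) == 0
    region <- ifelse(d < 0, "scaffold_body",
                     ifelse(in_cap, "capsule", "skin"))
  } else {
    region <- ifelse(d < 0, "scaffold_body",
                     ifelse(d <= cfg$capsule_thickness, "capsule", "skin"))
  }
  data.frame(cell_id = cells$cell_id, distance = d, region = region,
             stringsAsFactors = FALSE)
}

#' Region label and distance summary per subcluster
#'
#' Each subcluster is labelled with the majority region of its cells; ties
#' are broken by the region of the median-distance cell (the cell whose
#' signed distance is closest to the subcluster median, smallest cell id on
#' a further tie). Distance summaries (median, quartiles) feed violin-style
#' localization profiles.
#'
#' @param distance_table output of [assign_regions()].
#' @param assignment a [cluster_assignment()]; every assigned cell must
#'   appear in `distance_table`.
#' @return Data frame per subcluster: `level, cluster, region, n_cells,
#'   median_distance, q25, q75, n_scaffold_body, n_capsule, n_skin`.
#' @export
subcluster_region <- function(distance_table, assignment) {
  dt <- distance_table
  rownames(dt) <- dt$cell_id
  regions <- c("scaffold_body", "capsule", "skin")
  out <- lapply(sort(unique(assignment$labels)), function(cl) {
    ids <- names(assignment$labels)[assignment$labels == cl]
    ids <- ids[ids %in% dt$cell_id]
    if (!length(ids)) {
      stop("subcluster_region: subcluster '", cl,
           "' has no cells with a distance")
    }
    sub <- dt[ids, , drop = FALSE]
    counts <- vapply(regions, function(r) sum(sub$region == r), integer(1))
    top <- regions[counts == max(counts)]
    if (length(top) > 1) {
      md <- stats::median(sub$distance)
      cand <- sub[order(abs(sub$distance - md), sub$cell_id), , drop = FALSE]
      top <- cand$region[1]
    }
    data.frame(level = assignment$level, cluster = cl, region = top,
               n_cells = nrow(sub),
               median_distance = stats::median(sub$distance),
               q25 = unname(stats::quantile(sub$distance, 0.25)),
               q75 = unname(stats::quantile(sub$distance, 0.75)),
               n_scaffold_body = counts[["scaffold_body"]],
               n_capsule = counts[["capsule"]],
               n_skin = counts[["skin"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
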