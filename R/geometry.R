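# Plane-geometry primitives shared by io_formats (polygon validation) and the
# spatial metrics. Coordinates are micrometres throughout; y increases upward.

#' Signed area of a polygon
#'
#' Shoelace formula. Positive for counter-clockwise vertex order. The closing
#' vertex must not be repeated.
#'
#' @param vertices two-column numeric matrix of (x, y) vertices.
#' @return Signed area in squared coordinate units.
#' @keywords internal
polygon_signed_area <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon
#' @inheritParams polygon_signed_area
#' @return Non-negative area.
#' @keywords internal
polygon_area <- function(vertices) abs(polygon_signed_area(vertices))

# orientation of the triple (p, q, r): >0 counter-clockwise, <0 clockwise,
# 0 collinear
.orient <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

# TRUE when segment (p1,p2) and (p3,p4) intersect, including touching.
.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(ax, ay, bx, by, cx, cy) {
    # c collinear with a-b assumed; TRUE if c within the bounding box
    min(ax, bx) <= cx && cx <= max(ax, bx) &&
      min(ay, by) <= cy && cy <= max(ay, by)
  }
  if (d1 == 0 && on_seg(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) return(TRUE)
  if (d2 == 0 && on_seg(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) return(TRUE)
  if (d3 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) return(TRUE)
  if (d4 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])) return(TRUE)
  FALSE
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Checks every pair of non-adjacent edges; adjacent edges share exactly one
#' endpoint by construction and are skipped.
#'
#' @inheritParams polygon_signed_area
#' @return Logical scalar.
#' @keywords internal
polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3) return(FALSE)
  nx <- c(2:n, 1)
  ax <- vertices[, 1]; ay <- vertices[, 2]
  bx <- ax[nx]; by <- ay[nx]
  orient <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  for (i in seq_len(n - 1)) {
    # non-adjacent candidate edges j > i (adjacent edges share a vertex)
    j <- (i + 1):n
    j <- j[j != i + 1 & !(i == 1 & j == n)]
    if (!length(j)) next
    d1 <- orient(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
    d2 <- orient(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
    d3 <- orient(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
    d4 <- orient(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
    proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
    if (any(proper)) return(FALSE)
    # collinear touching cases: an endpoint of one edge on the other edge
    deg <- which(d1 == 0 | d2 == 0 | d3 == 0 | d4 == 0)
    for (jj in j[deg]) {
      if (.segments_intersect(vertices[i, ], vertices[nx[i], ],
                              vertices[jj, ], vertices[nx[jj], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting. Points exactly on an edge are classified by the
#' crossing parity of the horizontal ray and may land on either side; callers
#' needing the on-boundary convention should combine with a zero-distance
#' test (see [signed_distance()]).
#'
#' @param points two-column matrix of query points.
#' @param vertices polygon vertices, closing vertex not repeated.
#' @return Logical vector, TRUE when inside.
#' @keywords internal
point_in_polygon <- function(points, vertices) {
  px <- points[, 1]
  py <- points[, 2]
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Minimum distance from points to a polygon outline
#'
#' Point-to-segment minimum over all edges: the perpendicular foot where it
#' falls within a segment, else the nearest segment endpoint.
#'
#' @inheritParams point_in_polygon
#' @param closed when TRUE the edge from the last to the first vertex is
#'   included.
#' @return Numeric vector of non-negative distances.
#' @keywords internal
points_outline_distance <- function(points, vertices, closed = TRUE) {
  px <- points[, 1]
  py <- points[, 2]
  n <- nrow(vertices)
  dmin <- rep(Inf, length(px))
  last <- if (closed) n else n - 1
  for (i in seq_len(last)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vertices[i, 1]; ay <- vertices[i, 2]
    bx <- vertices[j, 1]; by <- vertices[j, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- ((px - ax) * dx + (py - ay) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Convex hull area of a point cloud
#'
#' @param points two-column matrix of points.
#' @return Area of the convex hull, 0 when degenerate (collinear or < 3
#'   points).
#' @keywords internal
convex_hull_area <- function(points) {
  pts <- unique(points)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  polygon_area(pts[h, , drop = FALSE])
}
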