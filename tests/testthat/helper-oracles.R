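# Independent oracles, deliberately coded without touching the package's
# internals: scalar even-odd point-in-polygon, dense boundary-sampling
# distance, O(n^2) neighbor counting, brute-force Benjamini-Hochberg, and a
# textbook pooled-variance t.

# scalar even-odd crossing test (different formulation from the package's
# vectorized ray cast)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
  }
  inside
}

# minimum distance to the outline by dense per-edge sampling
oracle_outline_distance <- function(points, poly, samples_per_edge = 1e4) {
  n <- nrow(poly)
  dmin <- rep(Inf, nrow(points))
  t <- seq(0, 1, length.out = samples_per_edge)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    bx <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
    by <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
    for (chunk in split(seq_along(bx), ceiling(seq_along(bx) / 2000))) {
      d2 <- outer(points[, 1], bx[chunk], "-")^2 +
        outer(points[, 2], by[chunk], "-")^2
      dmin <- pmin(dmin, sqrt(apply(d2, 1, min)))
    }
  }
  dmin
}

oracle_signed_distance <- function(points, poly, samples_per_edge = 1e4) {
  d <- oracle_outline_distance(points, poly, samples_per_edge)
  s <- vapply(seq_len(nrow(points)), function(i) {
    if (oracle_point_in_polygon(points[i, 1], points[i, 2], poly)) -1 else 1
  }, numeric(1))
  d * s
}

# O(n^2) directed neighbor-count matrix between subclusters, closed disc,
# self excluded
oracle_coloc_matrix <- function(xy, labels, radius, subs = sort(unique(labels))) {
  labels <- as.character(labels)
  subs <- as.character(subs)
  total <- matrix(0L, length(subs), length(subs),
                  dimnames = list(subs, subs))
  n <- nrow(xy)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    nb <- which(d <= radius)
    nb <- nb[nb != i]
    for (j in nb) total[labels[i], labels[j]] <- total[labels[i], labels[j]] + 1L
  }
  total
}

# brute-force BH: p_adj_i = min over j with p_j >= p_i of p_j * m / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  ranked <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(ranked[i:m]))
  }
  adj
}

# textbook pooled-variance two-sample t
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# star-shaped (hence simple) random polygon around a center
random_simple_polygon <- function(n_vertices, center = c(0, 0),
                                  r_range = c(40, 100)) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
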