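# On-disk dialects: transcripts/cells as headed CSV, counts as MTX triplet
# with gene/cell sidecar name files, boundaries as GeoJSON Polygon or CSV
# vertex lists, gene sets as GMT. All coordinates in micrometres.

#' Construct a boundary annotation
#'
#' A named polygon (or open polyline) in micrometre coordinates, e.g. the
#' manually-drawn scaffold surface or the outer boundary of the fibrotic
#' capsule. Closed polygons are stored without a repeated closing vertex and
#' normalized to counter-clockwise orientation; they must be simple
#' (non-self-intersecting) with at least 3 vertices.
#'
#' @param name label, e.g. `"scaffold"` or `"capsule_outer"`.
#' @param vertices two-column matrix or data frame of (x, y) vertices in µm.
#' @param closed logical; closed polygons get the validation above.
#' @return An object of class `boundary_annotation`.
#' @export
boundary_annotation <- function(name, vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (!all(is.finite(vertices))) {
    stop("geometry error: boundary '", name, "' has non-finite vertices")
  }
  n <- nrow(vertices)
  # drop an explicitly repeated closing vertex; closure is implicit
  if (n >= 2 && all(vertices[1, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- nrow(vertices)
  }
  if (closed) {
    if (n < 3) {
      stop("geometry error: closed boundary '", name,
           "' needs >= 3 vertices, got ", n)
    }
    if (!polygon_is_simple(vertices)) {
      stop("geometry error: boundary '", name, "' is self-intersecting")
    }
    if (polygon_signed_area(vertices) < 0) {
      vertices <- vertices[rev(seq_len(n)), , drop = FALSE]
    }
  }
  structure(list(name = name, vertices = vertices, closed = closed),
            class = "boundary_annotation")
}

#' @export
print.boundary_annotation <- function(x, ...) {
  cat(sprintf("<boundary_annotation '%s': %d vertices, %s>\n", x$name,
              nrow(x$vertices), if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Construct a spatial sample
#'
#' One tissue section: per-transcript table, per-cell table, gene-by-cell
#' count matrix, and zero or more annotated boundaries. This is the unit
#' every pipeline stage consumes. Extracellular transcripts carry the cell
#' id sentinel `"unassigned"`.
#'
#' @param sample_id sample identifier.
#' @param condition group label, e.g. `"skin"` or `"PCL"`.
#' @param transcripts data frame with columns
#'   `transcript_id, gene, x, y, qv, cell_id`.
#' @param cells data frame with columns `cell_id, x, y, area`.
#' @param counts gene-by-cell integer matrix (coerced to sparse `dgCMatrix`)
#'   with gene rownames and cell colnames.
#' @param boundaries named list of [boundary_annotation()] objects.
#' @param tissue_roi optional closed [boundary_annotation()] used as the area
#'   normalization for density metrics.
#' @return Validated object of class `spatial_sample`.
#' @export
spatial_sample <- function(sample_id, condition, transcripts, cells, counts,
                           boundaries = list(), tissue_roi = NULL) {
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  counts <- .as_dgc(counts)
  x <- structure(list(sample_id = sample_id, condition = condition,
                      transcripts = transcripts, cells = cells,
                      counts = counts, boundaries = boundaries,
                      tissue_roi = tissue_roi),
                 class = "spatial_sample")
  validate_spatial_sample(x)
  x
}

#' @export
print.spatial_sample <- function(x, ...) {
  cat(sprintf(
    "<spatial_sample '%s' (%s): %d cells, %d transcripts, %d genes, %d boundaries>\n",
    x$sample_id, x$condition, nrow(x$cells), nrow(x$transcripts),
    nrow(x$counts), length(x$boundaries)))
  invisible(x)
}

# general (never symmetric/triangular-packed) double CsparseMatrix; packed
# storage would drop dimnames and change the on-disk MTX dialect
.as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE, doDiag = FALSE)
  m <- methods::as(m, "generalMatrix")
  m <- methods::as(m, "dMatrix")
  methods::as(m, "CsparseMatrix")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing)) {
    stop("schema error: ", what, " table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Validate a spatial sample against its invariants
#'
#' Checks the table schemas, qv >= 0, finite coordinates, unique cell ids,
#' non-negative integer counts, that counts columns are a subset of the cell
#' table, and that every transcript's cell id is a known cell or the
#' `"unassigned"` sentinel.
#'
#' @param x a `spatial_sample`.
#' @return `x`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_spatial_sample <- function(x) {
  tr <- x$transcripts
  ce <- x$cells
  .require_columns(tr, c("transcript_id", "gene", "x", "y", "qv", "cell_id"),
                   "transcript")
  .require_columns(ce, c("cell_id", "x", "y", "area"), "cell")
  if (anyDuplicated(ce$cell_id)) {
    stop("referential error: duplicated cell_id in cell table: ",
         paste(utils::head(unique(ce$cell_id[duplicated(ce$cell_id)]), 5),
               collapse = ", "))
  }
  if (!all(is.finite(ce$x)) || !all(is.finite(ce$y))) {
    stop("schema error: non-finite cell centroid coordinates")
  }
  if (any(ce$area < 0)) stop("schema error: negative cell area")
  if (nrow(tr)) {
    if (!all(is.finite(tr$x)) || !all(is.finite(tr$y))) {
      stop("schema error: non-finite transcript coordinates")
    }
    if (any(tr$qv < 0)) stop("schema error: transcript qv < 0")
    unknown <- setdiff(unique(tr$cell_id), c(ce$cell_id, "unassigned"))
    if (length(unknown)) {
      stop("referential error: transcripts reference unknown cell id(s): ",
           paste(utils::head(unknown, 10), collapse = ", "))
    }
  }
  cm <- x$counts
  if (any(cm@x < 0)) stop("schema error: negative values in count matrix")
  if (any(cm@x != round(cm@x))) {
    stop("schema error: non-integer values in count matrix")
  }
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    stop("schema error: count matrix must carry gene rownames and cell colnames")
  }
  extra <- setdiff(colnames(cm), ce$cell_id)
  if (length(extra)) {
    stop("referential error: count matrix columns not in cell table: ",
         paste(utils::head(extra, 10), collapse = ", "))
  }
  for (b in x$boundaries) {
    if (!inherits(b, "boundary_annotation")) {
      stop("schema error: boundaries must be boundary_annotation objects")
    }
  }
  if (!is.null(x$tissue_roi) && !isTRUE(x$tissue_roi$closed)) {
    stop("geometry error: tissue_roi must be a closed polygon")
  }
  invisible(x)
}

#' Read a spatial sample from disk
#'
#' @param paths named list of file paths: `transcripts` (CSV), `cells` (CSV),
#'   `counts` (MTX triplet), `genes` and `cell_names` (one name per line,
#'   ordered as the MTX rows/columns), optional `boundaries` (named character
#'   vector of GeoJSON `.geojson`/`.json` or CSV vertex-list files) and
#'   optional `tissue_roi` (same formats).
#' @param sample_id sample identifier.
#' @param condition group label.
#' @return A validated [spatial_sample()].
#' @export
read_sample <- function(paths, sample_id, condition) {
  for (p in c(paths$transcripts, paths$cells, paths$counts, paths$genes,
              paths$cell_names, unlist(paths$boundaries), paths$tissue_roi)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  tr <- utils::read.csv(paths$transcripts, stringsAsFactors = FALSE)
  .require_columns(tr, c("transcript_id", "gene", "x", "y", "qv", "cell_id"),
                   "transcript")
  ce <- utils::read.csv(paths$cells, stringsAsFactors = FALSE)
  .require_columns(ce, c("cell_id", "x", "y", "area"), "cell")
  # coerce to a general matrix before naming: MatrixMarket files may use the
  # packed symmetric format (writers auto-detect value symmetry)
  cm <- .as_dgc(Matrix::readMM(paths$counts))
  genes <- readLines(paths$genes)
  cell_names <- readLines(paths$cell_names)
  if (nrow(cm) != length(genes) || ncol(cm) != length(cell_names)) {
    stop("schema error: MTX dimensions (", nrow(cm), " x ", ncol(cm),
         ") do not match sidecar name files (", length(genes), " genes, ",
         length(cell_names), " cells)")
  }
  dimnames(cm) <- list(genes, cell_names)
  boundaries <- list()
  for (nm in names(paths$boundaries)) {
    boundaries[[nm]] <- read_boundary(paths$boundaries[[nm]], name = nm)
  }
  roi <- if (!is.null(paths$tissue_roi)) {
    read_boundary(paths$tissue_roi, name = "tissue_roi")
  }
  spatial_sample(sample_id, condition, tr, ce, cm,
                 boundaries = boundaries, tissue_roi = roi)
}

#' Read a boundary polygon from GeoJSON or a CSV vertex list
#'
#' GeoJSON may be a `Polygon` geometry, a `Feature`, or a `FeatureCollection`
#' (first feature used; only the exterior ring is read). CSV needs `x,y`
#' columns.
#'
#' @param path file path; `.geojson`/`.json` selects GeoJSON, anything else
#'   CSV.
#' @param name label for the resulting annotation.
#' @param closed passed to [boundary_annotation()] for CSV input; GeoJSON
#'   polygons are always closed.
#' @return A [boundary_annotation()].
#' @export
read_boundary <- function(path, name, closed = TRUE) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (identical(g$type, "FeatureCollection")) {
      coords <- g$features$geometry$coordinates[[1]]
    } else if (identical(g$type, "Feature")) {
      coords <- g$geometry$coordinates
    } else if (identical(g$type, "Polygon")) {
      coords <- g$coordinates
    } else {
      stop("geometry error: unsupported GeoJSON type '", g$type, "' in ", path)
    }
    ring <- if (is.list(coords)) coords[[1]] else coords[1, , ]
    boundary_annotation(name, ring, closed = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .require_columns(df, c("x", "y"), "boundary vertex")
    boundary_annotation(name, cbind(df$x, df$y), closed = closed)
  }
}

#' Write a boundary polygon as GeoJSON
#'
#' @param boundary a [boundary_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_boundary_geojson <- function(boundary, path) {
  v <- boundary$vertices
  ring <- rbind(v, v[1, , drop = FALSE])  # GeoJSON repeats the closing vertex
  obj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a tabular result as CSV
#'
#' Deterministic encoding used by every pipeline output: header row, UTF-8,
#' '.' decimal separator, rows in the order given, `NA`/`NaN` serialized as
#' empty fields.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#'
#' Empty fields in numeric columns come back as `NaN` (the package-wide
#' convention for undefined statistics such as zero-variance p-values).
#'
#' @param path input path.
#' @return data frame.
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]][is.na(df[[j]])] <- NaN
  }
  df
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (set name to gene symbols);
#'   genes are deduplicated within each set.
#' @param universe optional character vector naming the background gene
#'   universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list(), universe = NULL) {
  if (length(sets) && anyDuplicated(names(sets))) {
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets>\n", length(x$sets)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Lines with
#' fewer than 3 fields and duplicated set names are errors; genes are
#' deduplicated within a set. An empty file yields an empty collection.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("GMT parse error: line(s) ", paste(which(nf < 3), collapse = ", "),
         " have fewer than 3 tab-separated fields")
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets)
}

#' Write a gene set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path, description = "na") {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, description, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a spatial sample to disk in the package's dialects
#'
#' Emits `transcripts.csv`, `cells.csv`, `counts.mtx`, `genes.txt`,
#' `cells.txt`, one GeoJSON per boundary and `tissue_roi.geojson` when
#' present, all under `dir`.
#'
#' @param sample a [spatial_sample()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, shaped as [read_sample()] input.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    transcripts = file.path(dir, "transcripts.csv"),
    cells = file.path(dir, "cells.csv"),
    counts = file.path(dir, "counts.mtx"),
    genes = file.path(dir, "genes.txt"),
    cell_names = file.path(dir, "cells.txt"))
  write_table(sample$transcripts, paths$transcripts)
  write_table(sample$cells, paths$cells)
  Matrix::writeMM(sample$counts, paths$counts)
  writeLines(rownames(sample$counts), paths$genes)
  writeLines(colnames(sample$counts), paths$cell_names)
  if (length(sample$boundaries)) {
    bpaths <- character(0)
    for (nm in names(sample$boundaries)) {
      p <- file.path(dir, paste0("boundary_", nm, ".geojson"))
      write_boundary_geojson(sample$boundaries[[nm]], p)
      bpaths[nm] <- p
    }
    paths$boundaries <- bpaths
  }
  if (!is.null(sample$tissue_roi)) {
    paths$tissue_roi <- file.path(dir, "tissue_roi.geojson")
    write_boundary_geojson(sample$tissue_roi, paths$tissue_roi)
  }
  paths
}
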