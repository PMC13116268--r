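# Hand-built miniature fixtures, written programmatically at test time.

# 3 cells, 10 transcripts, a unit-square-ish scaffold boundary
tiny_sample <- function(sample_id = "t1", condition = "skin") {
  cells <- data.frame(
    cell_id = c("c1", "c2", "c3"),
    x = c(10, 50, 90), y = c(10, 50, 90), area = c(80, 100, 120),
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = sprintf("tx%02d", 1:10),
    gene = c("gA", "gA", "gB", "gB", "gB", "gC", "gA", "gC", "gB", "gA"),
    x = c(10, 11, 50, 51, 49, 90, 91, 10, 50, 30),
    y = c(10, 11, 50, 51, 49, 90, 91, 12, 52, 30),
    qv = c(25, 30, 15, 40, 22, 18, 35, 21, 26, 10),
    cell_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c3", "c1", "c2",
                "unassigned"),
    stringsAsFactors = FALSE)
  counts <- matrix(c(3, 0, 1,
                     0, 4, 0,
                     1, 0, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("c1", "c2", "c3")))
  spatial_sample(sample_id, condition, transcripts, cells, counts)
}

# write a tiny sample's files to a temp dir, returning read_sample() paths
tiny_sample_files <- function(dir = tempfile("tiny_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- tiny_sample()
  write_sample(s, dir)
}

unit_square <- function(side = 10) {
  boundary_annotation("scaffold",
                      rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

# small expression world for marker tests: returns expr + counts + labels
two_group_expression <- function(n_in = 30, n_out = 70, n_genes = 20,
                                 seed = 42) {
  set.seed(seed)
  n <- n_in + n_out
  cell_id <- sprintf("c%03d", seq_len(n))
  genes <- sprintf("g%03d", seq_len(n_genes))
  counts <- matrix(rpois(n_genes * n, 1), n_genes, n,
                   dimnames = list(genes, cell_id))
  labels <- setNames(c(rep(1L, n_in), rep(0L, n_out)), cell_id)
  list(counts = counts, labels = labels, cell_id = cell_id, genes = genes)
}
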