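---
title: "Methods: spatial transcriptomic evaluation of implanted biomaterials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial transcriptomic evaluation of implanted biomaterials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In-vivo evaluation of an implanted biomaterial has classically relied on
histology: stains report end-stage outcomes (fibrotic encapsulation,
macrophage accumulation) but little about the cellular programs that led
there. Imaging-based in-situ transcriptomics measures hundreds of genes per
transcript-resolved position in the same paraffin sections, at single-cell
resolution. `stimplant` implements the analysis layer for that setting: a
paired design of control skin sections and sections implanted with a
polymer scaffold, with the scaffold surface annotated manually as a
polygon. The questions the package answers are (i) whether data quality is
comparable between conditions, (ii) which transcriptional populations and
subpopulations respond to the implant, (iii) where those subpopulations sit
relative to the scaffold surface, and (iv) which subpopulations are spatial
neighbors of which.

## Data model and conventions

All coordinates are micrometres with an arbitrary origin and y increasing
upward. A `spatial_sample` bundles the per-transcript table (position,
gene, Phred-like quality value `qv`, assigned cell or the `"unassigned"`
sentinel for extracellular transcripts), the per-cell table (centroid,
area), the sparse gene-by-cell count matrix, and named boundary polygons.
Polygons are stored without a repeated closing vertex, normalized to
counter-clockwise orientation on load, and must be simple; these
normalizations make point-in-polygon and area code single-cased. The
`"unassigned"` sentinel (rather than a missing value) exists because the
transcript-to-cell assignment rate is itself a QC metric.

## Quality control

`compute_qc()` reports the high/low quality split at a configurable
threshold (default `qv >= 20`, the platform convention; the motivating
workflow never states its cutoff), assignment rates, and densities. The
normalization area is the `tissue_roi` polygon when present, else the
convex hull of cell centroids — the hull makes control and implant sections
comparable without extra annotation, at the price of a slight underestimate
of the imaged area near section margins. Group comparisons use the
unpaired, equal-variance Student's *t* (the named test of the motivating
workflow), with Welch available by flag. A zero-variance comparison returns
`t = 0, p = 1` with a warning rather than failing, so degenerate synthetic
fixtures cannot crash a pipeline.

## Normalization, clustering, subclustering

Counts are scaled per cell to the median total count and
`log(1 + x)`-transformed; zero-total cells are excluded with a warning.
Cells are standardized per gene, projected onto the leading principal
components (default 15), and connected in a k-nearest-neighbor graph
(k = 20, Euclidean in PC space). Edges are weighted by the Jaccard overlap
of neighbor sets (shared-nearest-neighbor weighting) and the graph is
partitioned with Louvain at resolution 0.8. Two numerical choices deserve
a note:

- **No SNN pruning.** The reference toolchain prunes Jaccard weights below
  1/15. Under `igraph`'s Louvain that pruning fragments a homogeneous
  population (500 i.i.d. noise cells split into 4–8 communities at
  resolution 0.8); keeping all weighted edges brings the null down to ~3
  and recovers well-separated blobs exactly. The package therefore keeps
  every positive-weight edge.
- **Embedding = first two PCs.** The 2-D embedding exported for
  visualization carries no contract beyond determinism; no UMAP
  implementation is available in the supported dependency set, and the PC
  plane is deterministic, seed-free, and adequate for the export hook that
  external trajectory tools consume.

Cluster indices are 0..K−1 ordered by decreasing size with ties broken by
the lexicographically smallest member cell id, so names are stable across
seeds. `subcluster()` reruns the identical procedure on one cluster's
cells, recording lineage in the level name (`"global.2"`).

## Markers, differential expression, frequencies

"Expressing" means raw count > 0: in-situ panels are sparse and curated, so
any detection is treated as evidence. Markers of a cluster must satisfy
`pct_in >= 0.5` and `log2FC > 0.25`, the filter of the motivating workflow.
log2FC is computed with pseudocount 1 on de-logged normalized means,
`log2((mean_in + 1)/(mean_out + 1))` — stated explicitly because it
compresses fold changes near zero (a true 4-fold change at baseline mean 1
appears as ~1.3, not 2). The per-gene test is the two-sided Wilcoxon
rank-sum on normalized values (the reference toolchain's default; Student's
*t* by flag), BH-adjusted over all tested genes. The volcano significance
flag uses the raw p-value (`log2FC >= 1` and `-log10 p >= 2`, both
inclusive) to match the published thresholding convention; `p_adj` is
reported alongside. Cluster frequencies are per-sample fractions with
explicit zero rows; group comparison is one Student's *t* per cluster, and
the "significantly more frequent in the implanted condition" subset
(`p < 0.05`, `mean_PCL > mean_skin`, raw p — whether the motivating
workflow corrected across clusters is unstated, so both raw and BH values
are reported) is the gate feeding colocalization.

## Localization

The signed distance of a cell to the scaffold surface is the minimum
point-to-segment Euclidean distance over the boundary polygon(s) —
the perpendicular foot where it exists, the nearest vertex at corners —
negative iff the cell is inside (even-odd rule), exactly 0 on the surface.
Cells at distance 0 belong to the **capsule**: the surface is defined as
the body/capsule interface and a documented tie rule beats an unstated
one. A fragmented scaffold cross-section (list of polygons) uses the
nearest component, negative inside any. Regions: `scaffold_body` (d < 0),
`capsule` (inside the annotated capsule outer boundary, or
`0 <= d <= thickness` in the annotation-free mode; the 100 µm default
thickness is an implementation choice — the motivating workflow drew the
capsule manually and states no number), `skin` otherwise. A subcluster's
region label is the majority region of its cells, ties broken by the
region of the cell nearest the median distance.

## Colocalization

Around every cell of a source subcluster a closed disc of radius 25 µm is
drawn and member cells of each target subcluster inside it are counted
(boundary inclusive; a cell is never its own neighbor). The directed
total-count matrix is symmetric off the diagonal by the pairwise nature of
radius inclusion, and its diagonal is twice the number of within-cluster
pairs — both properties are asserted in the suite. Neighbor search uses a
uniform grid with bin width = radius, chosen because it reproduces the
O(n²) computation *exactly* (same floating-point comparisons), which the
acceptance suite verifies elementwise against an independent brute-force
oracle. Because the aggregation behind published "interaction strength"
heatmaps is typically unstated, both the total and the per-source-cell
mean matrices are exported.

## Enrichment

Over-representation uses the one-sided hypergeometric tail (equivalent to
one-sided Fisher), the simplest exact and reproducible test; rank-based
web-service variants are deliberately out of scope and annotations against
hosted databases are not claimed to be bit-reproducible. The default
universe is the measured panel, not the genome: in-situ panels are small
and curated, so panel-as-universe is the defensible null. Cluster
annotation takes the smallest-p set, ties broken by larger overlap then
lexicographic name.

## The synthetic world

The generator emulates the paired design at a scale a laptop can iterate
on. Its defaults are the stated conditions of the motivating workflow
wherever one exists, chosen once and not revisited:

- field 1400 × 1000 µm with an elliptical scaffold (semi-axes
  350 × 180 µm) and a 100 µm capsule; cells from a homogeneous Poisson
  process per region, with native skin at 1000 cells/mm² and implant-region
  densities solved so the expected implanted/skin overall density ratio is
  **2.02**;
- five cell types; implant-region composition solved from the
  condition-level frequency folds **2.6** (macrophages, up), **26**
  (neutrophils, up) and **2.7** (keratinocytes, down);
- macrophages split into region-linked subtypes (body/capsule/skin) with
  their own markers, giving subclustering and localization something real
  to recover;
- negative-binomial counts (dispersion 0.5, log-normal library factors,
  σ = 0.3, baseline mean 0.4 counts/gene/cell — typical of curated in-situ
  panels), type markers at log2FC 3 in 90 % of member cells;
- transcripts scattered uniformly within 10 µm of the parent centroid,
  **85.2 %** drawn from the high-quality value range, plus ~12 % unassigned
  extracellular transcripts.

Region ground truth is computed analytically (ellipse containment plus a
densely sampled outline distance), a route independent of the polygon
segment-distance code it is later compared against; the emitted boundary
polygons discretize the ellipse finely enough (256 vertices, < 0.1 µm
deviation) that agreement is exact for cells more than 1 µm from a
boundary. What the generator does **not** model: segmentation errors,
doublets, decoding noise structure, 3-D tissue, spatial expression
gradients within a region. A green recovery test therefore establishes
that the estimators are correct and well-powered under the stated world,
not that they are robust to real segmentation artifacts.

## Determinism and degenerate inputs

Every stochastic step takes a seed; per-sample and per-stage seeds are
derived deterministically from the study/pipeline seed, and an identical
configuration reruns bit-identically (asserted on the written CSVs).
Degenerate inputs fail fast with named errors: zero transcripts, collinear
centroid hulls without an ROI, clusters too small for a rank test (< 3
cells) or for a kNN graph (< k + 1), capsule boundaries that do not
enclose the scaffold, self-intersecting polygons.

## Known limitations

- Louvain is delegated to `igraph`; community structure at a fixed
  resolution is implementation-sensitive, so cross-toolchain label
  reproduction is not claimed (cluster *counts* and planted-structure
  recovery are).
- The Wilcoxon normal approximation is used throughout (`exact = FALSE`
  behavior at these sample sizes); p-values for very small clusters are
  conservative.
- Colocalization counts centroids, the only per-cell point in the data
  model; membrane contact is not inferred.
- The pipeline's config file is JSON (no TOML parser in the supported
  dependency set); the schema mirrors `pipeline_config()` one-to-one.
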