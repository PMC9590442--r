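---
title: "Methods: multiscale aggregation and two-track clustering for submicrometer spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale aggregation and two-track clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspot)
```

## The problem

Array-based spatial transcriptomics platforms differ by orders of magnitude
in resolution: spot arrays resolve ~100 μm, bead arrays ~10 μm, and
flow-cell-derived platforms such as Seq-Scope place spatial barcodes less
than a micrometre apart — more than a million barcodes per mm². At that
density two things break in conventional toolchains. First, the spatial
coordinate of each barcode is not supplied as an array layout file; it has
to be recovered from the sequencing run itself, because each barcode's
position is encoded in the Illumina read identifier of the first-round
("1st-seq") reads that created it. Second, each individual barcode captures
only a handful of UMIs, far too few to be treated as a cell-like unit, so
every downstream method needs spatial aggregation — but naive aggregation
throws away exactly the resolution the platform paid for.

subspot implements the full chain: coordinate extraction and error-corrected
barcode maps, sparse spatial expression matrices in the 10x exchange format,
spatial QC, two complementary aggregation geometries, clustering with
fine-scale label projection, and raw-resolution RGB rendering. A synthetic
generator reproduces the data regime at desk scale so that every stage is
testable without any external download.

## Coordinate geometry and barcode maps

A 1st-seq read identifier has the colon-delimited form
`instrument:run:flowcell:lane:tile:x:y`. Tiles are placed on a global canvas
by a configurable `tile_layout()` (row-major grid by default): a read on
tile $(r, c)$ at local pixel $(x_\ell, y_\ell)$ maps to

$$x = c\,(W + g) + x_\ell\, u, \qquad y = r\,(H + g) + y_\ell\, u,$$

with tile extent $W \times H$, gap $g$, and scale $u$ length units per
pixel. The origin is top-left with $y$ increasing downward, and all global
coordinates are in length units (μm throughout this vignette). Because
instrument-specific tile layouts vary, the layout is user configuration,
not a built-in table.

`build_barcode_map()` collapses reads into one entry per barcode. Three
rules keep the map well defined:

* barcodes containing `N` are discarded (they cannot match anything
  exactly and inflate correction ambiguity);
* duplicate reads of one barcode at one coordinate collapse to one entry;
* a barcode observed at two distinct coordinates has no defined spatial
  origin, so the default collision policy drops it (counted in
  `n_collisions`); `"first"` keeps the first-seen coordinate for users who
  prefer recall over precision.

Error correction against a whitelist (`correct_barcode()`) accepts an exact
match, otherwise the *unique* whitelist member at Hamming distance 1, and
otherwise returns `NA`. Two or more distance-1 candidates are treated as
unrecoverable rather than guessed at. Indels and distance-2 matches are
deliberately out of scope: single substitutions dominate Illumina error
profiles, and the unique-distance-1 rule keeps correction deterministic and
idempotent.

## Matrix exchange format

Spatial expression matrices are stored as the 10x-style MatrixMarket triple
(genes as rows, barcodes as columns, 1-based integer coordinate entries)
plus a `coordinates.tsv` sidecar (`barcode`, `x`, `y`). Additional count
layers — spliced, unspliced, ambiguous from a Velocyto-style
quantification — are sibling subdirectories holding their own `matrix.mtx`
of identical shape. When both a sidecar and position-encoding barcode names
(`lane_tile_x_y`) are present, the sidecar wins: explicit data beats
convention. Inside R the container is `spatial_matrix`, which keeps all
layers dimension-aligned; `tidy()` and `glance()` views expose it to
data-frame workflows.

## Spatial QC

`density_raster()` accumulates UMI totals (or barcode counts) into square
cells by the same half-open floor rule used everywhere in the package,
so raster totals equal input totals exactly. Tissue detection
(`detect_tissue()`) is a declared, deterministic rule: threshold the raster
(by default at the median of nonzero cells; Otsu's method is available),
keep the largest 4-connected component, return its mask and bounding box.
4-connectivity is the conservative choice — it refuses to bridge diagonal
speckle into the tissue body. The per-barcode metrics (`per_barcode_qc()`)
are UMI total, genes detected, and mitochondrial fraction by
case-insensitive gene-name prefix (default `mt-`).

## Two aggregation geometries

Both binning tracks share one geometry primitive, a `bin_spec(side, step,
anchor)` with half-open membership $x \in [w, w + \text{side})$ on both
axes, so no barcode is ever double-counted within a track.

**Simple grid** (`simple_grid_bin()`, `step = side`): barcode $b$ at
$(x, y)$ joins bin $(\lfloor (x-x_0)/s \rfloor, \lfloor (y-y_0)/s \rfloor)$.
With `min_umi = 0` the grid conserves total UMIs exactly; a `min_umi`
threshold drops transcript-poor bins before clustering, where they only add
noise.

**Sliding window** (`sliding_window_bin()`, `step < side`): windows of edge
$s$ anchored at every $(x_0 + i\,\delta,\; y_0 + j\,\delta)$. We require
$s$ to be an integer multiple of $\delta$; then every interior barcode
falls in exactly $(s/\delta)^2$ windows and window centers are
$(s/\delta)^2$-fold denser per unit interior area than grid bins. With the
default Seq-Scope-scale choice $s = 10\,\mu m$, $\delta = 2\,\mu m$ this is
a 25-fold denser map whose per-window transcript content matches the grid's
— resolution is gained at the labelling stage without thinning counts.

The anchor defaults to the minimum corner of the tissue bounding box (or of
the data, when no mask is supplied). Edge windows that partially overlap the
extent are kept whenever they contain at least one barcode, preserving
signal at the tissue margin; windows containing no barcode are simply
absent. Bin identifiers `x<wx>_y<wy>_s<side>` make joins across runs
deterministic.

## Two-track clustering

Clustering needs transcript-rich units; fine labels need dense centers. The
two-track design separates the concerns: learn on the grid, label the
windows.

The reference pipeline (`fit_reference()`) on grid bins is:

1. log-normalization $v = \ln(1 + 10^4\, c / C_\text{bin})$ (the
   counts-per-10,000 convention of the single-cell ecosystem this package
   interoperates with);
2. highly variable gene selection by variance of $v$ (default 2000, capped
   at the gene count; ties break by gene order);
3. per-gene z-scoring with clipping at $\pm 10$ — clipping stops one
   extreme bin from dominating a principal component;
4. centred PCA (default 20 components; truncated SVD via irlba for large
   inputs, exact SVD otherwise). Loading signs are fixed by making the
   largest-magnitude entry of each column positive, so fits are
   reproducible across linear-algebra backends;
5. a shared-nearest-neighbor graph (default $k = 20$; edge weight the
   Jaccard overlap of the two $(k\!+\!1)$-neighborhoods, pruned below
   $1/15$);
6. Leiden community detection maximizing modularity at resolution 0.5
   under a fixed seed; clusters are renumbered by decreasing size.

Everything needed for out-of-sample projection — the HVG list, gene means
and standard deviations, loadings — is stored in the model.
`project_bins()` applies the identical transform to sliding-window bins
(genes absent from the query count as zero, the only imputation consistent
with no external information) and reproduces the reference embedding
exactly when fed the reference track. `transfer_labels()` assigns each
window the majority label among its $k = 5$ nearest reference bins in the
embedding (Euclidean); majority ties fall back to the single nearest
neighbor, keeping transfer fully deterministic. A kNN-majority contract was
chosen over anchor-based integration because it is the simplest projection
rule that is exactly reproducible and has no tunable alignment stage.

Degenerate inputs are rejected rather than repaired: zero-total bins must
be filtered before normalization (the error names the offending bin),
fitting requires more bins than `n_pcs` and than `k_neighbors`, and
constant genes can never enter the HVG set while alternatives exist (their
post-normalization standard deviation is zero, which would break
z-scoring).

## Rendering

`render_rgb()` rasterizes *raw barcode-level* counts — no binning or
smoothing — at a configurable pixel size (default 1 μm²/pixel), so the
image retains the platform's native resolution. Each channel quantifies an
arbitrary gene set, optionally from its own layer (e.g. red = spliced,
green = unspliced of the same genes, for nuclear/cytoplasmic contrast).
Channels are scaled by the 0.99 quantile of their nonzero raw intensities
and clipped to 1: quantile scaling is robust to single hot pixels, which a
max rule would let dim the entire image. `render_cluster_map()` paints each
bin as a square of edge `step` centred on the bin center — so
sliding-window maps render at step granularity, which is where the finer
label boundaries become visible — resolving overlaps by nearest bin center.
UMAP layouts (`plot_umap()`) delegate to uwot, single-threaded under a
fixed seed so layouts are bit-reproducible.

## The synthetic generator: what it does and does not emulate

The generator is first-class, tested code, and its defaults are the
package's standard study conditions: 10,000 barcodes with 20-base
spatial barcodes on a 2 × 2-tile flow cell (300 × 300 μm at 0.1 μm/pixel),
200 genes, three vertical expression domains emulating zonated tissue
layers, Poisson counts with per-gene spliced fractions drawn from a
Beta(8, 2) (most UMIs spliced). Domain structure is disjoint marker blocks
(20 genes per domain at 0.4 UMI/barcode) over a uniform 0.02 background,
plus five `mt-` genes everywhere — roughly a dozen UMIs per barcode, the
sparse regime that makes per-barcode clustering hopeless and aggregation
necessary. These sizes keep a full pipeline run in seconds on one CPU while
preserving the regime of interest; they are desk-scale stand-ins for flow
cells carrying millions of barcodes.

Two generator choices deserve justification:

* **Boundaries in general position.** Stripe boundaries default to 97% of
  the equal-split positions (x = 97 and 194 μm), not to 100 and 200. Equal
  splits would place the true boundaries exactly on 10 μm bin edges, where
  the coarse grid recovers them with zero error by alignment luck — a
  measure-zero geometry no real tissue exhibits, and one under which
  comparing boundary sharpness between tracks is meaningless.
* **Pure-bin scoring.** A grid bin straddling a boundary contains a genuine
  mixture of two domains; it has no single true label, and its cluster
  assignment tracks its actual composition rather than the domain of its
  center point. `stripe_bin_truth()` therefore flags bins wholly inside one
  stripe as `pure`; exact-recovery scoring (ARI) is computed over pure
  bins, while the mixed bins are precisely what the boundary-displacement
  metric (`boundary_displacement()`: mean distance from label transitions
  to the nearest true boundary, scanned per row of bin centers) is about.

Features of real data the generator does **not** emulate, and which passing
tests therefore say nothing about: overdispersion beyond Poisson (no
gamma-mixing by default), ambient RNA and barcode swapping, optical or PCR
duplicates, heterogeneous barcode density and capture efficiency across the
flow cell, soft gradients rather than hard domain boundaries, indel
sequencing errors (correction is substitution-only by design), and
alignment artefacts — alignment itself is an external-tool boundary
(`external_align_handoff()`), never executed in-process.

## Numerical conventions

All membership tests are half-open floor rules with a shared orientation,
so QC rasters, both binning tracks, and pixel rasterization agree about
which side of an edge a coordinate belongs to. All randomness flows through
single `seed` arguments and is applied via an internal scoped-seed helper
that restores the caller's RNG state — no function leaves global state
behind. Whitelists are written in lexicographic order; MatrixMarket entries
are written row-major; bins are ordered by (row, column) of their anchor —
every artifact is byte-stable under re-runs.

## Known limitations

Aggregation windows must stay large enough (~10 μm) to collect a workable
UMI total, so genuinely subcellular inference is out of reach of the
sliding window itself; the raw-resolution RGB renderer is the subcellular
view. Label transfer is kNN-majority in PCA space and inherits PCA's
linearity; domains separable only nonlinearly may blur at transfer time.
Tissue detection is a thresholding rule, not a segmentation model, and will
include dense non-tissue artefacts if they rival tissue density. Hexagonal
or image-guided segmentation, RNA-velocity estimation, and histology
overlay are out of scope.
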