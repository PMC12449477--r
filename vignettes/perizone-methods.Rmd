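---
title: "Tumour-surface zonation of in situ single-cell data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour-surface zonation of in situ single-cell data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

perizone analyses imaging-based single-cell spatial transcriptomics of
tumour tissue — per-cell centroids, areas and targeted-panel transcript
counts of the kind Xenium-class instruments export. This vignette is the
package's account of its methods: the models and rules, the parameters that
matter, the numerical choices, what the bundled synthetic generator does and
does not emulate, and the limitations we know about.

## Positivity and cell typing

Targeted in situ counts are small integers, so cell-level marker calls use a
count threshold rather than a continuous cutoff: a cell is **positive** for
a gene when its count is at least `tau` (default 2) and **negative** only
when the count is exactly 0. A count of 1 is deliberately indeterminate —
it satisfies neither rule. This asymmetry keeps both stated rules literal;
positive-marker tests use `>= tau`, negative-marker tests (for instance the
SFTPD exclusion in the tumour grid rule) demand strict zero. `tau` trades
sensitivity against specificity: at `tau = 1` single ambient transcripts
create spurious positives, which is why 2 is the default.

Cell types come from an ordered rule list (`marker_config()`): the first
rule a cell satisfies wins, and cells matching none are `"U.C."`. Rules may
require *any* (default) or *all* of their positive markers. An explicit
priority order replaces case-by-case expert review, which an automated
pipeline cannot reproduce; since the bundled marker sets are disjoint,
order only matters for genuinely ambiguous cells. Marker summaries report
group means, percent positive, and a z score of each group mean across the
set of group means using the **population** standard deviation — the
descriptive convention of marker bubble charts (the z scores of a marker
across a fixed small set of groups always average zero; they are not
inferential statistics).

## Densities and two-group contrasts

Expression is compared as **gene density**: counts per square micrometre,
per cell (count/area) or per region (pooled counts over pooled area), which
removes cell-size and region-size effects. Contrasts use Welch's
unequal-variance t with Welch–Satterthwaite degrees of freedom, two-sided
p-values, Benjamini–Hochberg step-up q-values over the genes tested in one
call (one contrast = one family; no cross-contrast pooling), and Cohen's d
with the pooled Bessel-corrected standard deviation. The classic pooled-sd
d is used even though the test allows unequal variances: "Cohen's d"
without qualification conventionally means the pooled form. Degenerate
genes are handled explicitly: both groups constant and equal is a vacuous
contrast (t = 0, p = 1, d = 0); constant but unequal leaves the statistics
undefined and flagged rather than infinite. A pooled-variance Student t is
available behind `var_equal = TRUE` for comparability, but Welch is the
default throughout.

Tumour cells are **hot** when the basis gene (CD274 by default) has count
at least 2 and **cold** at 1 or 0. Note the hot/cold rule bisects the
counts — unlike positivity there is no indeterminate class — because the
contrast needs a partition. With a hot-cell rate of about 3 transcripts,
roughly a fifth of truly hot cells still fall below 2 by Poisson chance;
classification noise of that size is inherent to any small-count threshold
rule and attenuates, but does not bias, the hot/cold effect sizes.

## The distance field

The geometric core converts cells to a 10 µm grid (counts pooled by
centroid membership, half-open bins), extracts a tumour mask by the grid
marker rule (every positive marker's pooled count `>= 1`, negative markers
exactly 0 — the per-cell `tau` does not carry over to grids, which pool
several cells, so 1 is the minimal literal threshold and is exposed as an
argument), then smooths the binary mask with a 3×3 median filter followed
by a 3×3 uniform blur re-binarized at 0.5, with replicate padding at the
borders. On binary input both filters reduce to "at least 5 of 9", but
they are implemented as stated so each step keeps its own meaning; the
re-threshold at 0.5 is required because blurring a binary image yields
fractions.

The tumour **surface** is the first outer contour of the smoothed mask:
connected components are found in raster-scan order and the first one is
traced by Moore boundary following (every contour cell is mask-true with a
mask-false 8-neighbour). With several nests this keeps only the raster-first
component — an artefact of the origin — so `which = "largest"` selects the
maximal-area component instead; neither behaviour is asserted as the only
correct one.

Distances are multi-source shortest paths on the grid graph: nodes are grid
cells, edges join 8-neighbours with Euclidean weights (s orthogonal,
s·√2 diagonal; 4-connectivity is an option), sources are the contour cells.
The implementation iterates synchronous min-plus relaxation to a fixpoint,
which is exact for positive weights and vectorises well; tests verify it to
1e-9 µm against an independent Dijkstra on an explicit edge list. The sign
is negative inside the mask (off the contour), matching a −60…150 µm
banded view of the microenvironment. Bands are half-open `[lo, hi)` — so
20 µm falls in mid, matching the "< 20 µm" peritumour convention — with
defaults peri [0, 20), mid [20, 70), distal [70, 120) and a uniform 30 µm
partition available for contour-interval views.

**Known limitation.** The 8-connected grid metric overestimates true
Euclidean distance by up to 8.24% (worst at directions 22.5° off the
lattice axes). Within the ~150 µm zone the band analysis cares about this
is at most a few micrometres, below the grid spacing; but for grid cells
several hundred micrometres from a small nest the excess can exceed
s·√2. The geometry checks therefore use nest radii (280–310 µm on an
800 µm field) for which the whole field lies in the accurate regime. No
correction is applied, because the grid-graph distance itself is the
method being reproduced.

Band profiles divide a band's pooled counts by its grid area (cell count ×
s²), and band class proportions (for instance CXCL13+CD8+ against
CXCL13−CD8+ T cells) are computed over the classified cells of each band.
Band profiles are clustered by UPGMC — centroid linkage on Euclidean
distances — implemented via `hclust` on squared distances with merge
heights reported back on the Euclidean scale; centroid-linkage inversions,
possible by construction, are clamped to zero and flagged rather than
hidden. Dendrograms export as Newick with branch lengths from the merge
heights.

## Spot-level enrichment

The enrichment path filters genes with fewer than 10 total counts and cells
with fewer than 10 remaining counts, then total-count normalizes each cell
to the median per-cell total of the unfiltered input (the normalization
target is otherwise under-specified; the pre-filter median is stable
against the filter itself). The field is gridded into k × k spots (125 ×
125 = 15,625 by default) and a gene is a **DEG in a spot** when its
expression there reaches the top 5% of its own expression across spots —
the per-gene-across-spots reading, which is the only one that yields
spot-specific DEG sets; the per-spot-across-genes alternative sits behind
`per = "spot"`. The quantile is nearest-rank (ceiling), unambiguous on
integers; an all-zero gene is a DEG nowhere (strict positivity guard),
while a constant positive gene saturates the `>=`-cutoff rule everywhere
and is flagged as degenerate rather than silently resolved.

Per spot and gene set, over-representation is the one-sided hypergeometric
upper tail of the DEG/term overlap against the fixed panel background (302
genes in the reference configuration), BH-adjusted across terms within each
spot (each spot's DEG set is one query). Maps are −log10 of the p- or
q-values, floored at 1e-300; both raw and adjusted maps are emitted because
published "log-adjusted P" heatmaps are ambiguous between them. Gene sets
arrive as GMT files; no ontology ships with the package. Map agreement is
the plain Pearson correlation over spots, undefined (flagged `NA`) for
zero-variance maps.

Because the hypergeometric test is discrete, its attainable significance
levels are a finite set: under random DEG draws the probability of p < 0.05
is not 0.05 but the largest attainable tail mass below it. The calibration
test computes that exact level by combinatorial enumeration and checks the
empirical rate against *it* (and against the conservativity bound ≤ 0.05);
checking against 0.05 itself would mislabel any correct implementation as
miscalibrated.

## The synthetic generator

`generate_tissue()` builds the study conditions every end-to-end test runs
on: an 800 × 800 µm field with 20,000 cells; one circular tumour nest
(r = 300 µm) of epithelial cells, all other types placed by complete
spatial randomness (the simplest null compatible with the analyses under
test); lognormal cell areas (meanlog ln 80 µm², sdlog 0.4, clipped at
10 µm²), a plausible scale for epithelial/stromal cells; per-type Poisson
marker rates of 4–6 (so marker recall per cell exceeds 98% and typing is
recoverable), a mosaic of 100 µm hot/cold patches over tumour cells
(CD274 rates 3 vs 0.1, proliferation-marker rates 0.5 vs 2.5), ambient
background of 0.01 counts per gene per cell (the realistic order for
targeted in situ chemistry — at 0.05 the ambient counts would rival the
markers and the negative-marker rule would fail in a fifth of grid cells),
and chemokine rates in immune cells multiplied by f = 3 within 20 µm of
the nest surface (both sides of it). The interferon group (IFNG, CXCL9,
CXCL10, CXCL13) shares a 25 µm-lattice latent Gaussian log-intensity field
constructed so the correlation of log-rates between coupled genes is
exactly ρ (default 0.74); multipliers are mean-one
(`exp(σZ − σ²/2)`, σ = 0.5). The enrichment fold f and width d_peri are
free parameters mirroring a qualitative claim, not estimates of any real
tissue.

Ground truth (type, analytic signed distance to the nest circle,
enrichment flag, band, patch, hot/cold label) is recorded per cell, with
boundary distances computed **analytically from the circles** so generator
truth never depends on the grid pipeline it is used to test. Identical
specs (including the seed) reproduce byte-identical output.

What the generator does *not* emulate — optical noise, segmentation error,
transcript-level spot positions, clustered stromal architecture, irregular
tumour boundaries, multiple interacting nests — bounds what passing tests
show: they demonstrate that the pipeline recovers planted structure through
its own geometry and statistics under idealized placement, not that it is
robust to real-tissue artefacts.

## Problem sizes and determinism

The test suite and the analysis scripts run the full study conditions
(20,000 cells, 80 × 80 distance grid, 15,625 spots) directly; only
plumbing tests use a scaled-down tissue (4,000 cells on a 400 µm field).
Oracle suites use 100 random blob masks up to 30 × 30 for shortest paths
and 1,000 random instances per statistic. Every random draw is seeded;
`scripts/acceptance.R` derives all of its seeds from `--seed`. The
peri/distal recovery ratio is measured as the mean chemokine count of
immune-typed cells in the peri band over the distal band — immune cells
rather than whole bands, because the contour ring itself is tumour-dense
and would dilute a band-level density ratio with cells that cannot express
chemokines; measured values sit a few percent below the planted 3-fold
because band edges are quantized at the 10 µm grid.
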