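# perizone

Zonation analysis of tumour tissue for imaging-based single-cell spatial
transcriptomics (Xenium-class exports: per-cell centroids, areas, and
targeted-panel transcript counts). The package is aimed at analysts asking
*where* immune programs sit relative to a tumour: how chemokine-expressing
immune cells distribute with distance from the tumour surface, which gene
programs co-localise spatially, and how immunologically hot and cold tumour
subclones differ.

## What it computes

- **Positivity & cell typing** — a cell is positive for gene *g* when its
  count n(g) ≥ τ (default 2) and negative only when n(g) = 0; types are
  assigned by an ordered marker-rule list (first match wins, unmatched →
  U.C.), with z-score / percent-positive marker summaries per cell group.
- **Signed distance field** — cells are pooled onto a 10 µm grid; tumour
  grid cells are extracted by a marker rule (e.g. CDH1⁺ SFTPB⁺ SFTPC⁺
  SFTPD⁻), smoothed (3×3 median, then 3×3 blur re-binarized at 0.5), the
  first outer contour is traced, and each grid cell receives the
  multi-source shortest-path distance to the contour on the
  Euclidean-weighted 8-neighbour grid graph (s orthogonal, s√2 diagonal),
  negative inside the tumour.
- **Band stratification** — half-open distance bands (peri [0, 20), mid
  [20, 70), distal [70, 120) µm, or uniform 30 µm bands) with per-band gene
  densities (counts/µm²), cell-class proportions, and UPGMC (Euclidean
  centroid-linkage) clustering of band profiles.
- **Two-group contrasts** — gene density (counts/area) compared with
  Welch's t (Welch–Satterthwaite df, two-sided), Benjamini–Hochberg q, and
  Cohen's d (pooled SD); hot/cold tumour cells defined by CD274 count ≥ 2
  vs ≤ 1.
- **Spot enrichment** — count filters (≥ 10 per gene and cell),
  total-count normalization, a 125×125 = 15,625-spot grid, per-gene top-5%
  DEG calling across spots, one-sided hypergeometric over-representation
  per spot against the panel background (BH across terms within a spot),
  −log10 q maps, and Pearson correlation between maps.
- **Synthetic tissue generator** — seeded, truth-tracked tissues (tumour
  nests, peri-tumoural chemokine enrichment, a latent-field-coupled
  interferon program, hot/cold mosaics) emitting exactly the file dialects
  the readers consume, so the full pipeline is testable end to end.

## Worked example

```r
library(perizone)

spec <- tissue_spec(seed = 1)        # 20,000 cells, one r = 300 um nest
sim  <- generate_tissue(spec)
cfg  <- default_tissue_marker_config(sim$table$panel)

# typing
calls <- assign_cell_types(sim$table, cfg, tau = 2)
table(calls$label)
#>    CAF epithelial  LYM myeloid plasma   U.C.
#>   2388      10042 3295    2559    799    917

# zonation: grid -> mask -> contour -> shortest paths -> bands
grid    <- build_grid(sim$table, s = 10)
mask    <- smooth_mask(tumour_mask(grid, cfg))
dfield  <- distance_field(mask, extract_contour(mask), s = 10)
dfield
#> <distance_field> 80 x 80 at 10 um, signed range [-290.0, 264.6] um, 168 contour cells

bands <- assign_bands(sim$table, grid, dfield, band_partition())
imm   <- calls$label %in% c("myeloid", "LYM")
chem  <- gene_counts(sim$table, "CXCL9") + gene_counts(sim$table, "CXCL13")
mean(chem[imm & bands$labels$band == "peri"]) /
  mean(chem[imm & bands$labels$band == "distal"])
#> [1] 2.8092
```

The generator planted a 3-fold chemokine enrichment within 20 µm of the
nest surface; the full geometric path recovers 2.81 (band edges are
quantized at the 10 µm grid, costing a few percent). The numbered scripts
under `analysis/` run the same stages as a narrated workflow —
`01_simulate.R` … `06_hotcold.R` — writing their tables to `results/`
(e.g. the hot/cold contrast finds CD274 at Cohen's d = +2.30 in hot cells
and the proliferation marker MKI67 at d = −1.03, and the interferon-program
enrichment map correlates with the CXCL9/CXCL13/CXCL10 expression maps at
r = 0.42–0.49 against −0.002 for the stromal control COL1A1).

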