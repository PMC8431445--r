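# melcpipe

Single-cell analysis of cyclic immunofluorescence (MELC) imaging in R.

Multi-Epitope-Ligand Cartography (MELC) images one marker per cycle on the
same tissue section: each cycle stains an antibody, acquires a fluorescence
*tag* image, photobleaches, and acquires a *post-bleach* image; a
phase-contrast image is taken before every cycle and brightfield/darkframe
calibration images once per field of view (2018 × 2018 px at 0.45 µm/px,
i.e. a 908.1 × 908.1 µm field). Stacking the cycles gives a 20-plex
single-cell protein readout — for example of disseminated tumor cells and
the hematopoietic microenvironment in bone marrow — but only after a chain
of corrections: the raw images carry vignetting, residual signal from
incompletely bleached prior cycles, unspecific antibody binding and batch
variation between samples.

`melcpipe` implements that chain end to end, for image analysts and
cytometrists working with cyclic-IF data:

1. **Image correction** — rigid registration of all cycles to a reference
   (phase correlation on phase-contrast images), flat-field correction
   `(I − dark) / (bright − dark) · mean(bright − dark)`, post-bleach
   background subtraction `max(tag_c − postbleach_{c−1}, 0)`, and
   retrospective vignetting correction (per-pixel robust statistic across
   the tag stack + polynomial-surface smoothing, or a precomputed gain map).
2. **Segmentation** — classical nucleus/cell baselines (threshold +
   distance-transform watershed; texture map for phase contrast) with a
   pluggable interface for externally produced label masks, and
   reconciliation: a cell object counts as a cell only if it reproduces a
   nucleus (holds > 50 % of some nucleus's pixels).
3. **Features** — per cell: 6 morphological features (cell size/perimeter;
   nucleus size/perimeter/roundness `4πA/P²`/solidity) and 9 intensity
   features per marker: mean (ME), total (TO) and top-20 % mean (M20) in the
   nucleus, whole-cell and cytoplasm/membrane (cell − nucleus) compartments.
4. **Normalization** — negative-control ratio normalization (marker features
   divided by the same cell's NC-channel features), and per-image background
   levels estimated from mutually exclusive counterpart markers: cells
   positive for the counterpart should not express the marker, so a high
   quantile of the marker among them is its background threshold `b`;
   dividing by `b` per image doubles as batch correction.
5. **Feature validation** — consensus clustering (repeated feature
   subsampling → z-score → t-SNE → Gaussian-mixture clustering) scored by
   PAC (proportion of ambiguous consensus entries), CON (concordance of
   repeats with the consensus partition), MSS (mean silhouette) and their
   mean

   MCS = ((1 − PAC) + CON + MSS) / 3,

   plus per-feature one-way ANOVA F-tests with Benjamini–Hochberg
   correction and PCA contribution analysis.
6. **Atlas** — t-SNE embedding (perplexity 30), Gaussian mean-shift
   clustering of the embedding, scaled median cluster profiles (heatmap
   matrix), complete-linkage sub-clustering, and per-sample composition.

A first-class **synthetic acquisition simulator** (`make_scene()`,
`render_run()`) plants cell types with known masks and expression and
renders full acquisitions with all of the artifacts above, so every stage is
testable against ground truth at desk scale.

## Worked example

Simulate the default reference scene (400 cells of four bone-marrow-like
phenotypes over a 9-marker panel plus negative control and nuclear stain,
with vignetting, bleach residuals, unspecific binding and noise), run the
full pipeline, and score it against the planted ground truth:

```r
library(melcpipe)

scene <- easy_scene(seed = 0)          # 400 cells, 768 px field
run   <- render_run(scene)
print(run)
#> MELC run sim/fov1: 11 cycles, 768x768 px, 0.45 um/px
#>   markers: NC-FITC (NC), CD45, CD3, CD20, CD14, VIM, GD2, CD56, CD24, FAIM2, PI

res <- run_pipeline(run, config = list(
  normalization = list(exclusive_pairs = c(GD2 = "CD45", CD45 = "GD2"))))
print(res)
#> Pipeline result
#>   cells kept: 400 (dropped by reconciliation: 0, excluded: 0)
#>   atlas clusters: 4

rec <- evaluate_recovery(scene,
                         nucleus_mask   = res$nucleus_mask,
                         cell_mask      = res$cell_mask,
                         cell_table     = res$cell_table,
                         cluster_labels = res$atlas$labels,
                         features       = res$normalized,
                         scene_id       = attr(run, "scene_id"))
print(rec)
#> Recovery report
#>   nucleus F1@0.5: 1.000 (400/400 matched)
#>   cell F1@0.5:    1.000 (400/400 matched)
#>   clustering ARI: 1.000
#>   median marker expression r: 0.999
```

All 400 planted cells are segmented correctly at IoU 0.5, the four
mean-shift clusters of the t-SNE embedding coincide exactly with the four
planted phenotypes (adjusted Rand index 1.0), and the normalized top-20 %
cell intensities track the planted per-cell expression with median Pearson
r = 0.999.

The same flow is available from a shell via the thin CLI:

```sh
Rscript exec/melcpipe simulate --out demo --seed 0
Rscript exec/melcpipe run --in demo/acquisition --out demo/results --seed 0
```

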