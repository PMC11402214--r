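# isletquant

Per-cell quantification of immunofluorescence staining in pancreatic islet
images.

## The problem

In type 2 diabetes (T2D), insulin-like growth factor binding protein 7
(IGFBP7) is upregulated in pancreatic islets, and its per-cell staining
intensity differs between islet cell types: glucagon-positive α-cells show a
~20% increase in T2D donors while insulin-positive β-cells show a marginal
one. Measuring this requires segmenting individual cells in multi-channel
confocal images of pancreatic tissue (nuclear stain, insulin, glucagon,
IGFBP7), classifying each cell as α or β from its hormone staining, and
comparing per-cell median IGFBP7 intensity between donor groups.

`isletquant` implements that analysis as a reproducible pipeline for R, for
image-analysis scientists who want the full chain from raw planes to group
statistics under test coverage:

1. **Islet segmentation** — an 8-bit islet-probability map (from a pixel
   classifier) has 40 gray levels subtracted, is blurred at σ = 20 px, and
   thresholded with the Huang minimum-fuzziness criterion
   `E(t) = Σ_g h(g)·S(μ_t(g))`, `μ_t(g) = 1/(1 + |g − m_side|/C)`.
2. **Nucleus detection** — the islet-masked nuclear channel is blurred at
   σ = 9 px; local maxima are scored by a matched-filter correlation (a
   probability-like score in [0, 1], threshold 0.7) and filtered by greedy
   non-maximum suppression at disk-IoU 0.8, then painted as non-overlapping
   seed disks.
3. **Cell-boundary propagation** — the three hormone channels are rescaled
   to full range and max-projected into a guide; seeds expand over the
   region above the guide's global minimum cross-entropy (Li) threshold,
   each pixel joining the seed of cheapest path cost
   `√((I(p)−I(q))² + λ·‖p−q‖²)` with regularisation λ = 0.25.
4. **Classification** — a cell is β if median insulin ≥ 1.5 × median
   glucagon, α in the symmetric case, otherwise unclassified ("at least
   50% more intense", boundary inclusive).
5. **Quantification** — per-cell median IGFBP7 intensity; Manders overlap
   coefficient `Σab/√(Σa²·Σb²)` of IGFBP7 with the class hormone over each
   cell; Mann-Whitney ND-vs-T2D comparison per class.

Because the confocal images behind the published analysis are not public, the
package ships a first-class synthetic generator (`generate_truth()`,
`render_image()`, `render_probability_map()`, `generate_cohort()`) that
emulates islet geometry, hormone-specific channel intensities, the T2D IGFBP7
effect (α: 0.102/0.0863 ≈ 1.18×, β: 0.1059/0.102 ≈ 1.04×), pixel noise and
imperfect annotations — with full ground truth, so every stage can be
validated quantitatively. An annotation-guided grid search
(`run_gridsearch()`) reproduces the parameter-selection procedure.

## Worked example

```r
library(isletquant)

cfg <- pipeline_config(seed = 7)   # synthetic cohort: 6 ND + 3 T2D donor fields
run <- run_pipeline(cfg)
run
#> <islet_run> 9 fields, 1080 cells
#> <islet_summary> 1080 cells (0 unclassified)
#> # A tibble: 4 × 4
#>   group cell_class n_cells median_igfbp7
#>   <chr> <chr>        <int>         <dbl>
#> 1 ND    alpha          262        0.0879
#> 2 T2D   alpha          122        0.0983
#> 3 ND    beta           458        0.104
#> 4 T2D   beta           238        0.106
#> ND vs T2D (Mann-Whitney):
#> # A tibble: 2 × 4
#>   cell_class statistic    p_value method
#>   <chr>          <dbl>      <dbl> <chr>
#> 1 alpha          11253 0.00000302 normal_approx
#> 2 beta           51355 0.211      normal_approx
```

Each row gives the cell count and the group median of per-cell median IGFBP7
intensity (arbitrary units on [0, 1]). At this cohort size the α-cell
increase in T2D (0.0983 vs 0.0879, a 1.12× ratio against the simulated
1.18× effect) is already strongly significant, while the smaller β-cell
effect is not — α-cells carry the group difference, as in the tissue data
the simulation emulates. `tidy(run)` returns the pooled per-cell table,
`glance(run)` one row of ratios and p-values, `autoplot(run)` boxplots by
group and class, and `plot_cell_map(run$fields[[1]])` the segmented field.

A thin CLI over the same functions lives at `inst/cli/isletquant.R`
(`run`, `simulate`, `gridsearch` subcommands, YAML-configured).

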