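# epifocus

Quantitative spatial analysis of curved epithelial whole mounts imaged by 3D
confocal microscopy.

Whole-mount preparations of curved epithelia — the motivating application is
the human anterior lens capsule with its attached epithelial monolayer,
recovered at cataract surgery — never lie flat, so each slice of a confocal
z-stack shows only a band of the tissue in focus. `epifocus` turns such
stacks into per-cell, per-compartment protein measurements:

1. **Focal correction** — a Sobel gradient of every DAPI slice locates, per
   pixel, the sharpest slice; after thresholding the gradient weights at
   0.1 · prc99, a weighted least-squares fit of a total-degree-5 bivariate
   polynomial gives the in-focus manifold *z<sub>f</sub>(x, y)*, and every
   channel is linearly interpolated onto it.
2. **Compartmental segmentation** — two marker-controlled watershed
   transforms: nuclear seeds from an automatically tuned h-maxima transform
   (*h* = 0.1 · prc99.9 of the locally contrast-adjusted DAPI) flood the
   DAPI gradient; the resulting nuclei then seed a second flood of the
   summed protein gradients, yielding one nucleus + cytoplasm pair per cell.
3. **Wound-edge profiles** — vertically averaged intensity vs distance from
   the capsulotomy border in 5-µm bins, summarized by the interval fraction
   IF = ⟨P⟩₍₅₋₃₀₎ / (⟨P⟩₍₅₋₃₀₎ + ⟨P⟩₍₅₀₋₈₀₎); 0.5 means equidistribution,
   more means proximal accumulation.
4. **Colocalization** — Pearson/Spearman coefficients with 8×8-px
   tile-shuffle randomization p-values, Costes thresholds found along a
   percentile-pairing curve (stop where the outside-region PCC reaches 0),
   Manders M1/M2, per-cell nuclear fractions and compartment correlations
   with orthogonal regressions.
5. **Statistics** — Shapiro–Wilk-gated t/Welch or Wilcoxon comparisons with
   Cohen's d/d′ or the probability of superiority, two-sided throughout.

Because clinical stacks of this kind are not publicly deposited, the package
includes a **synthetic phantom generator** (`phantom_truth()`,
`render_stack()`, `make_correlated_pair()`, `make_edge_phantom()`) that
produces defocused, noisy multichannel stacks with exact ground truth —
every stage of the pipeline is tested against it.

## Worked example

```r
library(epifocus)

truth  <- phantom_truth(n_cells = 30, channel_corr = 0.5, seed = 42)
sample <- render_stack(truth, noise = c(15, 0))        # SNR ~ 10

fc <- focal_correct(sample$stack)
fc$manifold
#> <focus_manifold> degree 5, z_f range [4.03, 18.19], weighted RMSE 1.322 slices

seg <- segment_cells(fc$image)
seg$labels
#> <compartment_labels> 128x128 px, 30 cells
head(nuclear_fractions(seg$table)[, c("cell_id", "A_nuc", "A_cyt", "nucfr_B")], 3)
#>   cell_id    A_nuc    A_cyt   nucfr_B
#> 1       1  92.3261 116.7787 0.4622093
#> 2       2  90.8686 115.0425 0.5004842
#> 3       3 112.3687 158.7989 0.4773877

pixel_coloc(fc$image$channels$proteinA, fc$image$channels$proteinB,
            labels = seg$labels, seed = 1)
#> <pixel_coloc> PCC 0.553 (p = 0.004975), SRCC 0.490 (p = 0.004975)
#>   Costes: Th_A 137, Th_B 115 (converged); M1 0.447, M2 0.456
```

The weighted RMSE is the residual of the manifold fit in slice units (the
fit averages over the quantized per-pixel focus map, so its *accuracy*
against the phantom's true surface is much better — about 0.15 slices
here). The 30 segmented cells match the 30 generated nuclei; the per-cell
table holds the compartment means the colocalization and statistics layers
consume. The pixelwise PCC of 0.55 recovers the generator's target
correlation of 0.5, with the smallest p the 200-permutation tile test can
report (1/201 per tail convention).

Edge profiling against a phantom with a 2× proximal enrichment:

```r
edge <- make_edge_phantom(2, border_x = 25, shape = c(128, 160))
prof <- vertical_profile(edge, border_x = 25, pixel_size_um = 1)
interval_fraction(prof)$IF
#> [1] 0.6666667        # = 2/(2+1), the analytic value for a 2x enrichment

compare_samples(c(0.61, 0.55, 0.68, 0.52, 0.63, 0.57, 0.66, 0.59),
                mu0 = 0.5, design = "one_sample")
#> <comparison_result> one_sample, t test: p = 0.001196 (two-sided)
#>   Cohen's d = 1.854
#>   probability of superiority = 1.000
```

A thin command-line front end is installed with the package
(`exec/epifocus`): `phantom`, `focal`, `segment`, `profiles`, `coloc`,
`run-all`, and `stats` subcommands over the same functions, e.g.

```sh
epifocus phantom --cells 30 --corr 0.5 --seed 1 --out phantoms/
epifocus run-all phantoms/phantom.tif --border-x 2 --seed 1 --out results/
```

`run_pipeline()` / `run-all` write one bundle per sample (in-focus TIFF,
manifold JSON, label TIFF, compartment CSV, colocalization JSON, profile
CSV) plus aggregate statistics and a run log with the config hash; reruns
with the same inputs, config and seed are byte-identical.

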