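---
title: "Quantifying protein distribution in curved epithelial whole mounts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein distribution in curved epithelial whole mounts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifocus)
```

## The problem

Whole-mount preparations of curved epithelia — the motivating case is the
anterior lens capsule with its attached epithelial monolayer, recovered at
cataract surgery — do not lie flat on the slide. A confocal z-stack of such a
sample contains a different in-focus band in every slice, and no single slice
shows the whole tissue sharply. Downstream quantification (per-cell protein
levels, wound-edge gradients, colocalization) needs a single sharp 2D image
and a per-cell segmentation into nucleoplasm and cytoplasm.

`epifocus` implements that pipeline: focal-manifold correction, two-stage
marker-controlled watershed segmentation, wound-edge intensity profiling,
pixelwise and compartmental colocalization, and a normality-gated statistics
layer. Because clinical image stacks of this kind are rarely public, the
package ships a synthetic phantom generator with exact ground truth, and the
whole test suite runs against phantoms.

Conventions used throughout: matrices are `[row = y, col = x]`, indices are
1-based, slices run 1..n, and all structuring-element sizes are in pixels.
Percentiles are computed with the linear-interpolation convention between
order statistics (R's type 7); both the gradient-weight threshold and the
h-maxima height depend on the percentile convention, so it is fixed once and
used everywhere.

## Focal correction

The DAPI (nuclear) channel is the sharpness reference. For every slice a
3x3 Sobel gradient magnitude is computed with replicate border padding (so
the frame edge creates no spurious gradients). Per pixel, the maximum over z
and the slice attaining it give the raw focus map `z_m(x, y)`; ties resolve
to the lowest slice for determinism. Values of the maximal gradient below
0.1 times its 99th percentile are zeroed — they reflect noise, not nuclear
borders — and the surviving magnitudes weight a least-squares fit of a
bivariate polynomial of total degree 5 (21 coefficients) on coordinates
normalized to [-1, 1]. "Degree 5" is read as *total* degree: it keeps the
basis small and the normal equations well conditioned; per-axis degree is a
one-line change via the `degree` argument. The fitted surface `z_f(x, y)` is
evaluated everywhere, left unclamped by the fit, clamped to the slice range
only at interpolation, and each channel is linearly interpolated along z
between the two bracketing slices.

Two numerical choices matter here:

* **Pre-smoothing** (`presmooth_sigma`, default 2 px). The Sobel operator
  amplifies pixel-independent noise roughly 3.5-fold, and taking the maximum
  over 20-50 slices then selects the *extremes* of that amplified noise, so
  at realistic noise levels structureless pixels pass the weight threshold
  with garbage `z_m` and drag the fit toward the stack center. Smoothing each
  DAPI slice at about the optical-blur scale before the gradient restores the
  edge-to-background contrast the threshold assumes. On the standard phantom
  this is the difference between a useless fit (about 2 slices RMSE) and an
  accurate one (0.1-0.4 slices). Set `presmooth_sigma = 0` for the raw
  gradient.
* **Integer snapping.** At interpolation, `z_f` values within 1e-9 of an
  integer are snapped to it. A fit to an exactly flat focus map returns the
  constant plus floating-point dust; snapping makes "flat stack in, sharp
  slice out" an exact identity rather than a 1e-12 blend.

A phantom-specific caveat: the phantom's defocus blur is mirror-symmetric in
z, so on a *flat integer* surface every off-border pixel attains its maximal
gradient at exactly tied slice pairs, and the lowest-z tie rule biases those
pixels low. Real optics are never exactly symmetric and non-integer surfaces
do not tie, so this is an artifact of the idealized phantom, not of the
method; the identity contracts are therefore tested on already-flat stacks
and via interpolation on the true manifold, while manifold *recovery* is
tested on curved random surfaces.

## Segmentation

Segmentation applies two marker-controlled watershed transforms to gradient
images, with markers derived automatically.

**Stage 1 — nuclei.** The in-focus DAPI image is Gaussian-smoothed
(`sigma_n = 3` px), and a soft background is estimated by erosion with a
disc of radius `r_n = 9` px, dilation with `2 r_n`, and Gaussian smoothing
with sd `r_n` — removing every object smaller than `r_n` — then subtracted
(clipped at zero). The radii follow the tuning that suits nuclei of roughly
10-20 px; both are exposed as parameters. The whether-the-kernel-size-is-a-
radius-or-an-sd question for the final smoothing is resolved as sd = `r_n`.
Uneven staining is corrected by a *local contrast adjustment*: a degree-2
polynomial surface is fitted to the background-subtracted image using the
image itself as the weight (so only nuclear pixels shape the surface) and
the image is divided by the fitted surface, floored at `1e-6 * max` to keep
the ratio finite where no nuclei exist — the ratio is only meaningful where
nuclear signal is present, and the floor deliberately leaves the empty
background at essentially zero.

Nuclear seed markers come from an automatically tuned h-maxima transform of
the upper half of the adjusted image (median subtracted, clipped at zero)
with height `h = 0.1 * prc99.9`. The h-maxima transform itself is a
grayscale image; the binary markers the watershed needs are its regional
maxima (excluding the zero plateau), the standard marker-extraction step.
The extranuclear seed is the below-median mask eroded by a disc of radius 2.
The DAPI Sobel gradient is then flooded from both seed sets.

**Stage 2 — cells.** Nuclear regions become per-cell seeds (each keeps its
stage-1 label, so cell count equals nucleus count by construction). Acellular
space is seeded by the *void marker*: pixels farther than `2 d_avg` from any
nucleus, opened with a disc of radius `d_avg`, where the average internuclear
distance `d_avg` is the mode of the histogram of the distance transform of
the nuclear space (bin width 1 px, Gaussian-regularized with sd 2 bins —
the regularization method is unspecified in the original description, so a
small fixed kernel is used and both knobs are arguments). The flooding relief
is the sum of the two protein-channel Sobel gradients with a 2 px guard band
around the nuclear space zeroed, so nuclear borders do not compete with cell
borders.

The watershed itself is a deterministic priority flood: lowest relief value
first, 4-connected, FIFO on ties. Every pixel ends up labelled — ridge
pixels are claimed by the first-arriving region in flood order rather than
by a separate ridge-assignment rule — which is what makes the
nucleus/cytoplasm/acellular partition exhaustive. Reconstruction, regional
maxima and marker component labelling are 8-connected (standard
morphological practice; 4-connected labelling would split diagonal marker
plateaus into spurious double seeds).

Nucleus i is the stage-1 region with label i clipped to cell i; the rest of
the cell is cytoplasm; cells that end up without nucleus pixels are dropped
with a warning and their pixels returned to the acellular label. Mean
intensities of both protein channels are measured per compartment, and
per-cell nuclear fractions `nuc / (nuc + cyt)` are appended.

## Wound-edge profiles

A region containing the capsulotomy (wound) edge is rotated so the cut is
vertical — by a given angle, or by the principal direction of a manually
drawn border polyline (bilinear interpolation; a zero angle is an exact
identity). Each column is averaged over rows, column position is converted
to micrometres from the border, and the profile is resampled into half-open
5-um bins by averaging member columns (membership is `[5k, 5(k+1))`, so no
column is counted twice; columns are unweighted, as the underlying
description is silent on weighting).

The *interval fraction* compares a proximal band (5-30 um) with a distal
band (50-80 um): `IF = prox / (prox + dist)`, each term the mean of that
band's bin averages. The 0-5 um ramp (the tissue border comes into view
gradually) and the 30-50 um transitional band are excluded. A flat profile
gives exactly 0.5; values above 0.5 mean proximal accumulation. The
fractional form — rather than a prox/dist ratio — avoids the unstable
small-denominator regime, and makes IF invariant to global intensity
scaling. One sentence in the source material inverts the reading of IF
relative to its own formula and figure legend; the formula's orientation
(IF > 0.5 = proximal) is used.

Profiles can be normalized by their mean over the 0-80 um domain (the
normalized profile has domain mean exactly 1), aggregated across samples per
bin with sample SD (n-1) and SEM = SD/sqrt(n), and the area between a cut
polyline and a border polyline (the cell-destruction area) is computed by
the shoelace formula on the closed polygon, with self-intersecting closures
rejected.

## Colocalization

**Pixelwise.** Pearson and Spearman coefficients (Spearman = Pearson on
mean-ranked data) with a randomization significance test: the first image is
cut into 8x8 px tiles and the tiles are shuffled `n_perm` times (default
200) while the second image stays fixed; the two-sided p-value uses the
add-one convention `(1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)` and can
never be exactly zero. Cooccurrence is thresholded by a Costes-style search
along a *percentile-pairing* curve: candidate thresholds are the two
channels' values at the same quantile (0.1-percentile steps from 99.9
downward, configurable), and the search stops at the first candidate where
the Pearson correlation of the *outside* region (`A <= Th_A | B <= Th_B`)
reaches zero from above. This replaces the classic orthogonal-regression
pairing and tolerates nonlinear channel relations. If the outside
correlation never reaches zero there is no colocalized population to
separate; the thresholds degrade to the curve minimum with a warning.
Manders coefficients M1 and M2 are the fraction of each channel's total
intensity inside the cooccurrence mask. The same correlations are also
computed restricted to the pooled nucleoplasm and pooled cytoplasm masks
from the segmentation (all cells together).

**Compartmental.** Per-cell compartment means are paired six ways (same
compartment across channels, crossed compartments, same channel across
compartments) plus cytoplasmic-A against the channel-B nuclear fraction;
each pairing reports PCC and SRCC with two-sided analytic p-values and a
scale-invariant orthogonal regression (first principal axis of the
standardized pair mapped back to original units: slope
`sign(cov) * sd(y)/sd(x)` through the centroid — exact on exact lines).
Randomization p-values are available for images; for the short per-cell
vectors the analytic tests are the default. Cells are split into high and
low channel-B nuclear fraction (HNF/LNF) at a configurable cutoff — 0.5,
i.e. nuclear-dominant, since no canonical cutoff exists — and cytoplasmic
channel A is compared between groups (unpaired, normality-gated) when at
least 5 HNF cells exist; otherwise the comparison is skipped with the reason
recorded.

## Statistics

Samples are described by n, mean, SD and the 95% t-interval of the mean;
normality is formally tested (Shapiro-Wilk at 0.05), and non-normal samples
additionally get the median, the interquartile interval and a binomial
order-statistic 95% CI of the median (no resampling). Comparisons are
normality-gated on the relevant quantity — the sample for one-sample tests,
the differences for paired tests, each group for unpaired tests (both must
pass): the parametric branch uses Student's t (one-sample, paired) or
Welch's unequal-variances t (unpaired) with Cohen's d, the non-parametric
branch the Wilcoxon signed-rank or rank-sum test with the probability of
superiority (`U/(n1 n2)` with tie halving). All p-values are two-sided.

Two effect sizes are reported on the parametric branch because paired
analyses are conventionally summarized both ways: d standardizes by the SD
of the paired differences, and d' by the root-mean-square of the two sample
SDs (for unpaired designs, d uses the pooled n-1-weighted SD and d' the RMS
of the two SDs). Both definitions are emitted explicitly since reports that
quote "d and d'" rarely say which is which. A comparison with no variation
at all (all paired differences zero, all values tied) returns p = 1 with
zero effect sizes and a `degenerate` flag rather than failing.

No multiple-testing correction is applied anywhere; the analysis reports
per-comparison p-values.

## The phantom generator

The phantom defines the ground truth first and renders images from it, so
every pipeline stage has an oracle:

* **Geometry.** Disk nuclei (radius 6 px by default) on a jittered hexagonal
  lattice whose pitch tiles the frame with the requested cell count —
  emulating the near-uniform spacing of a contact-inhibited monolayer.
  Random sequential packing is available (`placement = "random"`), but it
  leaves unbiological cell-free gaps that the void marker then (correctly)
  labels acellular. Cytoplasm is the Voronoi region of each nucleus clipped
  to the sheet mask; there is no membrane model.
* **Intensities.** Per-cell cytoplasm means are bivariate normal with
  constant coefficient of variation (A: 150 +- 30, B: 120 +- 24, floored at
  5) and a target inter-channel Pearson correlation; at correlation 1 the
  B means are exactly proportional to the A means. Nucleoplasm means are
  the cytoplasm means scaled by per-cell factors in [0.4, 1]. DAPI is 200
  inside nuclei and 0 outside. An optional proximal enrichment multiplies
  channel A near a vertical border (flat factor to 30 um, linear ramp to 1
  between 30 and 40 um).
* **Optics and noise.** The in-focus surface is a random degree-5 polynomial
  rescaled to stay 2 slices clear of the stack ends. Each slice is the sharp
  scene blurred with a per-pixel Gaussian sd of 1.2 px per slice of defocus
  distance, approximated by blending a bank of uniformly blurred scenes at
  integer sd levels — cheap, and monotone sharpness in defocus distance is
  all the focal stage needs. Poisson scaling and additive Gaussian noise
  follow (defaults: Gaussian sd 15, i.e. SNR about 10 against the cytoplasm
  signal; Poisson off). There is no optical PSF physics, no z-attenuation,
  no spherical aberration, and no brightfield channel.

What passing phantom tests does **not** show about real data: the phantom's
compartments are piecewise constant (no chromatin texture, no organelles),
its noise is pixel-independent, its defocus is symmetric in z, and its cells
never overlap or divide. Accuracy numbers on phantoms are therefore upper
bounds on real-data performance, and the segmentation contains no provision
for mitotic or overlapping nuclei beyond the h-maxima split.

A known measurement limitation follows from optical sectioning itself: on a
curved surface the in-focus image is interpolated between two slices that
are each slightly defocused, so compartment borders mix. For nucleoplasm
regions of ~100 px this biases per-cell nucleoplasm means by up to ~10-15%
toward the surrounding cytoplasm; cytoplasm regions of >= 200 px stay within
5% of truth per cell. The per-cell 5% accuracy contract is therefore stated
for compartments of at least 200 px, and nucleoplasm accuracy is tracked as
a bounded regression (mean under 5%).

## Problem sizes and determinism

The test suite and the acceptance script use 128x128x21 stacks with 30
nuclei for the full-pipeline checks, 96x96x9 stacks with 12 nuclei for the
per-module checks, 100 seeded cases on images up to 64x64 for the
morphology-oracle equivalence, 100 seeded 256x256 pairs per correlation
level for the Fisher-z recovery check, 500 runs for the tile-shuffle
calibration, and 1000 replicates per branch at n = 25 for the type-I
calibration of the statistics layer — sizes at which every check completes
in seconds while keeping binomial confidence bands tight enough to be
meaningful. Every random step takes an explicit seed; the pipeline driver
writes a run log with the config hash, and reruns with the same inputs,
config and seed are byte-identical (image files are stored as deterministic
32-bit-quantized TIFF with the intensity scale in a JSON sidecar; label
TIFFs are 16-bit and exact).
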