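---
title: "Quantifying calcium-phosphate sheet-aggregates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium-phosphate sheet-aggregates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsheet)
```

## The scientific problem

Vitrified neuronal cultures contain electron-dense calcium-phosphate (CaP)
sheet-aggregates whose mineral phase, size distribution and subcellular
context carry biological meaning: an octacalcium-phosphate-like (OCP-like)
phase is a hydroxyapatite precursor, aggregate area responds to culture
conditions, and association with mitochondrial markers speaks to the
aggregates' origin. `capsheet` implements the three quantitative analyses
this kind of study rests on, plus seeded synthetic-data generators so that
every stage can be validated against known ground truth on a desk machine:

1. **Aggregate area** from 2D cryo-EM micrographs and per-aggregate label
   masks, via an adaptive per-region threshold.
2. **Low-dose selected-area electron diffraction (LDSAED) radial
   profiling**, including beam-centre estimation, band normalisation,
   background-ratio correction, and detection of the broad OCP-like
   diffraction band spanning roughly 2.5–3.2 Å d-spacing.
3. **Marker colocalization** of intracellular versus extracellular
   aggregates, as a two-sided Fisher's exact test on a 2×2 table.

## Aggregate-area measurement

Masks are drawn (by hand or by a segmentation tool) *around* each
aggregate; the region therefore contains both aggregate and nearby
background pixels. For the pixel values of one region the threshold is

$$T = (\max - \min) - \kappa\,\sigma, \qquad \kappa = 1.5,$$

with $\sigma$ the population standard deviation of the region. $T$ is a
*range-based level*: a pixel counts as aggregate when
$(\text{value} - \min) \ge T$. Reading the formula this way makes the rule
invariant to constant intensity offsets, which a raw-value comparison would
not be; the offset-invariance is asserted for thousands of random regions
in the test suite. The measured area is
$\text{count} \times (\text{pixel size}/10)^2$ nm² (pixel size in Å/px,
default 3.21). Each label in a mask gets its own threshold from its own
pixel distribution.

Choices the formula itself does not fix, each exposed as an argument:

* **Population vs sample standard deviation** — population, because the
  formula reads as a descriptive statistic of the region, not an estimate.
* **Ties at exactly $T$** — counted as passing (`>=`), which keeps the rule
  deterministic and monotone in $\kappa$.
* **Connected components** — all above-threshold pixels in the region are
  counted, not only the largest component; one area is reported per
  aggregate and sheet-aggregates are naturally multi-lobed.
* **Dark-aggregate data** — `invert = TRUE` negates values before every
  step; generators and measurer share the density-positive convention.
* **Degenerate uniform region** — $T = 0$, every pixel counts, and a
  warning is emitted.

Note that *raising* $\kappa$ *lowers* the level $T$ and therefore never
shrinks the passing set; the monotonicity test asserts exactly this
direction.

Group comparison uses the two-sided Wilcoxon rank-sum test on all pairs of
conditions, Benjamini–Hochberg adjustment across the set of pairs, and
star labels at the strict 0.05/0.01/0.001 cutoffs, with each condition
summarised by median and interquartile range.

### Why the recovery tests dilate the masks

The synthetic generator's label masks are *exact footprints* (that is what
makes them a usable ground truth, and it keeps the pixel-count conservation
invariant simple). But the adaptive threshold can only separate aggregate
from background if the region contains both: applied to a pure footprint of
a noisy plateau it would cut into the noise of the plateau itself. Real
masks are loose boundaries. The noisy recovery studies therefore measure
inside `dilate_labels(mask, 8)` — an 8 px Euclidean dilation standing in
for a loose hand-drawn boundary — while the noise-free exact-recovery check
uses the footprint directly (a uniform region counts fully, so the
footprint is recovered exactly). With Gaussian noise at 10 % of the
aggregate contrast, the median relative area error over 100 seeded
replicates is far below the 5 % documented tolerance.

## LDSAED radial-profile analysis

A diffraction image is calibrated by its Nyquist spatial frequency at the
detector edge (1.75 Å⁻¹ at the 670 mm camera distance carried in the
metadata), so `q_per_pixel = nyquist_q / (N/2)`; the camera distance itself
is never used for calibration. The stages:

1. **Beam centre.** Centroid of the brightest 0.1 % of pixels (the
   unscattered beam), refined by maximising the correlation between the
   image and its 180°-rotated copy (computed over all circular shifts by
   FFT, searched within ±10 px), finished with 3-point parabolic sub-pixel
   interpolation. Injected offsets up to 8 px are recovered well within
   1 px even with Poisson noise.
2. **Radial average.** Bin width is one pixel radius with
   rounded-distance assignment — the image's native sampling, and trivially
   mirrored by a brute-force per-pixel oracle in the tests. Bins with
   $q < 0.03$ Å⁻¹ (central-beam region) or $q > 0.95\,q_\mathrm{Nyq}$
   (partially sampled corners) are dropped.
3. **Normalisation.** Every profile is *divided* by its mean over
   $q \in [0.094, 0.113]$ Å⁻¹. Division (rather than subtraction) makes
   profiles dimensionless and exposure-scale-free, so the subsequent ratio
   is meaningful; the band must cover at least 3 bins.
4. **Background ratio.** The normalised target profile is divided by the
   normalised background profile from an adjacent exposure. Features shared
   by both — the diffuse scattering envelope and the vitreous-ice rings
   near 3.71 and 2.15 Å — divide out to ≈ 1; target-only signal survives.
   Bins with background below $10^{-6}$ are flagged invalid. The x-axis
   converts to d-spacing by $d = 1/q$.
5. **Band detection.** The historical call of the 2.5–3.2 Å band was
   visual; `detect_band()` is this package's quantitative replacement and
   every piece of it is exposed: a straight-line baseline is fitted to the
   ratio over two flank windows ($d \in [2.30, 2.45]$ and $[3.40, 3.60]$ Å,
   placed to avoid both ice positions), the score is the mean excess of the
   ratio over that baseline across $d \in [2.5, 3.2]$ Å, and the band is
   declared present when the score exceeds a threshold calibrated as three
   standard deviations of the score over 100 seeded band-free noisy
   generator pairs (`calibrate_band_threshold()`; the packaged default is
   0.0069). At the generator's default dose this yields a false-positive
   rate well under 5 % with essentially complete power at band amplitude
   0.10 over 200 seeded replicates.

## Colocalization statistics

`fisher_exact_2x2()` reports the two-sided Fisher's exact p-value under the
probability-mass rule — the total probability of all margin-fixed tables no
more probable than the observed one, with a $10^{-7}$ relative tolerance
for floating-point ties (delegated to `stats::fisher.test`, whose rule this
is; an independent hypergeometric enumeration oracle checks it exhaustively
for all table totals up to 40). The odds ratio is the *sample*
cross-product $ad/bc$ — for the published counts (28, 18, 33, 3) this is
$28 \cdot 3 / (18 \cdot 33) = 0.141$ — not the conditional maximum-likelihood
estimate, which would not match. The 95 % CI defaults to the Woolf
(log-odds normal) interval and is tagged with its method; the interval is a
convention choice, and no attempt is made to reverse-engineer the one used
in any particular publication.

`wilcoxon_rank_sum()` uses the exact permutation distribution when the
smaller sample has ≤ 10 observations and the pooled data are tie-free,
otherwise the tie-corrected, continuity-corrected normal approximation,
recording which path was taken. When every pooled value is identical the
two-sided p is 1 by convention (the rank-sum variance is zero).
`bh_adjust()` is the Benjamini–Hochberg step-up rule via `p.adjust`. The
null-calibration study uses groups of 8 + 8 so the exact path is exercised;
at that size the exact test's attainable size at nominal 0.05 is 0.0499
(computed analytically from the null distribution), making the simulated
type-I rate a clean check of the machinery rather than of discreteness.

## What the synthetic generators emulate — and what they do not

* `simulate_micrograph()`: non-overlapping disk, ellipse or fibrous
  (striped-ellipse) aggregates of known footprint at elevated intensity
  over background, with optional Gaussian and/or Poisson noise. Defaults:
  256 px images at 3.21 Å/px, plateau contrast 100, bounding radii
  8–16 px. Fibrous striping is additive texture *inside* the footprint and
  the ground truth is the footprint, because total thresholded aggregate
  area — not individual sheets — is the measurand.
* `simulate_diffraction_pair()`: radially symmetric patterns
  $I(q) = A e^{-rq}\,(1 + \sum_j a_j G_j(q))$ about a configurable true
  centre, with unit-height Gaussian rings in $q$: vitreous ice at 3.71 Å
  (relative amplitude 0.5) and 2.15 Å (0.3), widths 0.02 Å⁻¹, and a
  target-only mineral band at 2.85 Å, amplitude 0.10, width 0.022 Å⁻¹ —
  so its ±2σ extent spans ≈ 2.5–3.2 Å. Amplitudes multiply the local
  envelope, which makes the noiseless target/background ratio exactly
  $1 + a_\mathrm{band} G_\mathrm{band}(q)$ and ties the "amplitude 0.10"
  of the power studies directly to a ratio excess of 0.10 at the band
  centre. Envelope defaults: 1000 counts amplitude, decay 4 Å. Defaults
  512 px, Nyquist 1.75 Å⁻¹ — at that size the 0.094–0.113 Å⁻¹
  normalisation band covers exactly the minimum 3 bins.
* `simulate_colocalization()`: one binomial draw per location group
  (intracellular first, then extracellular — the documented contract the
  seeded-replay test relies on).
* `simulate_area_groups()`: log-normal areas per condition,
  `meanlog = log(median)`. Aggregate areas are positive and right-skewed;
  the log-sd of 0.8 used in the default four-condition configuration is a
  realistic biological spread chosen once (it corresponds to an IQR
  spanning roughly a factor of 3, typical of per-condition area scatter in
  this kind of data).

The generators reproduce the *statistical structure* the analyses consume
— contrast over noise, ring/band geometry, count sampling — not image
formation. There is no contrast-transfer function, defocus, dose
fractionation, detector point-spread or 3D structure; the diffraction noise
model is plain Poisson counting because the actual camera's noise
statistics are not known to this package. Passing the recovery and
operating-characteristic tests therefore validates the *implementations*
under controlled conditions; it does not certify performance on microscope
data with untracked systematics (astigmatic beams, anisotropic ice,
overlapping aggregates).

## Numerical choices and degenerate inputs

* Image convention: `values[row, col]`, origin top-left; the geometric
  centre of an N-grid is at (N+1)/2 (1-based). MRC2014 mode 2 is the
  lossless on-disk float format (pixel size in the header); TIFF is
  secondary, with float storage accepted only on [0, 1] (a limitation of
  the TIFF library used) and masks stored as 8/16-bit integers.
* Seeding: every generator runs under an isolated, restored RNG state
  (Mersenne-Twister), so identical specs are bit-identical and generators
  never disturb the caller's RNG.
* Thresholds/ties: `>=` comparisons throughout the area module; the
  parabolic sub-pixel step of the centre estimator is clamped to ±0.5 px.
* Degenerate inputs fail loudly and early: empty regions, absent labels,
  misaligned masks, all-zero contingency tables, constant diffraction
  images, non-overlapping placement demands, binning or normalisation
  mismatches between profiles, and band/flank windows that overlap or are
  mostly invalid.

## Problem sizes used in the packaged studies

The validation studies run at sizes chosen to make their Monte-Carlo error
small relative to the documented tolerances while staying desk-scale:
100 seeded micrograph replicates (3 aggregates each) for noisy area
recovery; 100 null pairs for threshold calibration plus 200 null and 200
band-carrying 512 px diffraction pairs for the operating characteristics;
exhaustive Fisher enumeration over all margin classes with table total
≤ 40 (reduced by row/column-swap and transposition symmetry, under which
the p-value is invariant — the invariance is itself tested); and 2,000
seeded null simulations for the rank-sum size check.

## Known limitations

* The area module measures 2D projected area; no 3D volume measurement.
* No automatic segmentation: masks are inputs, as in the workflow this
  package supports.
* The band-detection criterion is a calibrated construction, not a
  community standard; its threshold is tied to the generator's default
  conditions and should be recalibrated (one function call) for other
  noise regimes.
* No crystallographic indexing or powder-pattern simulation from unit
  cells; "OCP-like" is operationalised purely as the broad 2.5–3.2 Å
  band in the background-corrected ratio.
* MRC support covers single-section 2D images, modes 0/1/2/6; no movie
  stacks or extended-header metadata.
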