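# capsheet

Quantification of calcium-phosphate (CaP) sheet-aggregates in cryo-EM data.

Vitrified neuronal cultures accumulate electron-dense CaP sheet-aggregates
whose mineral phase, size and subcellular context are biologically
informative: an octacalcium-phosphate-like (OCP-like) phase is a
hydroxyapatite precursor, aggregate area responds to culture media and time
in culture, and colocalization with mitochondrial markers bears on where the
aggregates nucleate. `capsheet` implements the three quantitative analyses
such a study needs, together with ground-truthed synthetic-data generators
that make every stage testable without microscope data:

* **Aggregate area** — per-aggregate adaptive threshold
  *T = (max − min) − κ·σ* (κ = 1.5, σ the population s.d. of the masked
  region; pixels pass when `value − min ≥ T`), pixel counts converted to
  nm² via `count × (pixel_size/10)²`, and pairwise Wilcoxon rank-sum
  comparisons across conditions with Benjamini–Hochberg correction.
* **LDSAED radial profiling** — beam-centre estimation (bright-pixel
  centroid + FFT rotational-correlation refinement), radial averaging,
  normalisation on the q band 0.094–0.113 Å⁻¹, division of the target
  profile by a matched background profile to dampen the vitreous-ice rings
  at ~3.71 and ~2.15 Å, conversion to d-spacing (d = 1/q), and a
  calibrated score for the broad OCP-like band spanning ~2.5–3.2 Å.
* **Marker colocalization** — two-sided Fisher's exact test on the 2×2
  intracellular/extracellular × marker-status table, with the sample
  cross-product odds ratio ad/bc and a Woolf 95% interval.

Images move through MRC2014 (lossless float32, pixel size in the header) or
TIFF; tables through CSV; configurations through JSON. Results are tibbles,
fitted objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(capsheet)
run_demo("capsheet-demo", seed = 1)
```

runs all four stages on synthetic inputs (the colocalization stage analyses
the published marker table directly) and prints a report ending in
`capsheet-demo/report.txt`:

```
Aggregate areas (adaptive threshold, kappa = 1.5):
  aggregate 1: 324/1004 px above threshold 98.86 -> 33.4 nm2
  aggregate 2: 726/1654 px above threshold 89.48 -> 74.8 nm2
  aggregate 3: 292/947 px above threshold 85.21 -> 30.1 nm2

Diffraction band (target/background ratio):
  score 0.05823 over d 2.50-3.20 A, threshold 0.0069 -> DETECTED

Marker colocalization (two-sided Fisher's exact):
  counts a=28 b=18 c=33 d=3
  odds ratio 0.141, p = 0.00188322, 95% CI (0.0377, 0.53) [woolf]
  positive: extracellular 61%, intracellular 92%

Per-condition area comparison (rank-sum + BH):
  1 DIV F-12 + 10% FBS vs 1 DIV NB: p_adj = 5.96e-05 ***
  ...
```

Reading the output: each aggregate's threshold is computed from its own
region statistics, and only the pixels passing it count toward the area
(324 of the 1004 pixels inside the first loose mask region). The band score
0.058 is the mean excess of the target/background ratio over its fitted
baseline across d = 2.5–3.2 Å — far above the 0.0069 null-calibrated
cutoff, so the synthetic mineral band injected at 2.85 Å is detected. The
Fisher stage reproduces the published odds ratio 0.141 and p = 0.001883
from the printed counts, and the area comparison flags the condition pairs
whose simulated medians differ most.

The same stages are scriptable piecewise:

```r
sim <- simulate_micrograph(micrograph_spec(n_aggregates = 3, background_noise_sd = 10, seed = 1))
areas <- measure_aggregates(sim$image, dilate_labels(sim$mask, 8), condition = "1 DIV NB")
pair <- simulate_diffraction_pair(diffraction_spec(poisson_noise = TRUE, seed = 1))
ctr <- estimate_beam_center(pair$target)
rat <- background_ratio(
  normalize_profile(radial_average(pair$target, ctr)),
  normalize_profile(radial_average(pair$background, ctr))
)
detect_band(rat)
#> Band 2.50-3.20 A: score 0.0582 vs threshold 0.0069 -> DETECTED
```

A thin command-line interface over the same functions is installed at
`inst/cli/capsheet.R` (`simulate`, `area`, `compare`, `diffract`,
`colocalize`, `demo`, `run` subcommands).

## Documentation

The methods vignette (`vignettes/capsheet-methods.Rmd`) documents the
models, every tunable parameter with its default and rationale, what the
synthetic generators do and do not emulate, numerical conventions, and
known limitations.
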