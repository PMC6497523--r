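# nucmorph

High-throughput, unbiased morphometry of asymmetric cell nuclei — built for
the falciform ("hook-shaped") sperm heads of mice, applicable to any
closed nuclear outline. Intended for labs quantifying sperm shape in
studies of spermatogenesis, hybrid sterility, infertility and reproductive
toxicology, where manual scoring is slow, subjective and hard to compare
across samples.

## What it does

Given folders of single-channel grayscale TIFF images of DAPI-stained
nuclei, `nucmorph`:

1. **Detects** nuclei by edge-based segmentation (exposure-invariant
   hysteresis thresholding of the gradient, with half-intensity boundary
   refinement) and traces each outline.
2. **Encodes** every outline as an *angle profile*: the interior angle
   measured at every perimeter point across a window of 5% of the
   perimeter. This is a dense variant of the Zahn–Roskies transform — a 5%
   window corresponds to the classical 20-semilandmark ZR polygon, but
   measuring at every point superimposes all polygon placements, so sharp
   features such as the hook tip are never missed. On a circle the profile
   is the constant 180(1 − w)° = 171° at w = 0.05.
3. **Aligns** profiles (exhaustive circular search, iterative re-alignment
   to the running median), builds the population **median profile** with
   interquartile envelope, and discovers **landmarks** as its sub-/super-180°
   extrema (convex/concave corners).
4. **Measures** each nucleus: area, perimeter, max Feret diameter, minimum
   diameter through the centre of mass, circularity 4πA/P², bounding
   width/height and ellipticity H/W in a vertically oriented frame (flat
   region below the hook vertical), hook length, body width, the
   tip–centre-of-mass–caudal angle, per-segment perimeter lengths, and the
   per-nucleus **variability score** √(Σd²/L) — the RMS deviation of its
   profile from the population median.
5. **Aggregates**: consensus nuclei (mean of semilandmarks every 1% of
   perimeter), per-parameter summary statistics with coefficients of
   variability, pairwise Wilcoxon rank-sum tests with Bonferroni
   correction, and hierarchical (Ward) clustering of shape profiles with
   recursive sub-clustering to discover morphological classes within a
   sample.

A synthetic-shape module generates parametric falciform and control nuclei
with analytic ground truth and renders them to TIFF, so the entire pipeline
is testable without microscope data.

## Worked example

```r
library(nucmorph)

# a synthetic population standing in for one imaged sample
pop <- make_population(25, shape_spec("falciform"), noise = 0.03, seed = 11)
fit <- fit_profiles(lapply(pop, `[[`, "outline"), L = 500)
fit
#> Shape-profile fit: 25 nuclei, L = 500, window = 0.05
#> Landmarks: 8 (5 convex, 3 concave)
#> Variability (deg RMS): median 4.20, range [1.92, 7.17]

records <- measure_nuclei(fit)
round(colMeans(records[, c("area", "perimeter", "circularity",
                           "ellipticity", "hook_length")]), 3)
#>        area   perimeter circularity ellipticity hook_length
#>      19.637      21.069       0.556       1.193       1.446
```

The fit found 8 landmarks on the median profile (hook tip, under-hook
concavity, ventral and caudal corners among them). The measured mean area
(~19.6 um²) matches the generator's analytic ground truth (~19.5 um²); the
low circularity (0.56) reflects the elongated, hooked outline, and the
median variability of ~4° RMS is this population's intra-sample shape
spread. `plot(fit)` draws the median profile with IQR and landmarks;
`build_consensus(attr(records, "oriented"))` gives the population's mean
outline.

For image folders, the same analysis end-to-end:

```r
run_pipeline("path/to/tiffs", out_dir = "analysis", k = 2)
# writes nuclei.csv, summary.csv, median_profile.csv, landmarks.csv,
# consensus.svg (+ per-cluster consensus shapes)
```

A thin command-line front end with `simulate`, `detect`, `run` and
`compare` subcommands is installed at `inst/cli/nucmorph`.

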