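---
title: "Nuclear morphometry from windowed angle profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry from windowed angle profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Asymmetric nuclei — most prominently the falciform ("hook-shaped") sperm
heads of mice and other rodents — carry shape information that simple size
descriptors (area, length, width) miss, that elliptic Fourier descriptors
smear at sharp features such as the hook tip, and that Procrustes landmark
methods only capture after laborious manual landmark placement. `nucmorph`
implements an automated alternative: every nucleus outline is encoded as a
dense *angle profile*, profiles are aligned and aggregated into a population
median, landmarks fall out of the median's geometry, and all downstream
measurement, consensus-shape construction and clustering operate on this
common representation.

## The angle profile

For a closed outline of perimeter $P$ traversed counterclockwise, the
profile value at a boundary point $v$ is the interior angle $\angle(a, v,
b)$, where $a$ and $b$ lie half a window before and after $v$ along the
perimeter and the window is a fixed fraction $w$ of $P$ (default $w = 0.05$).
Straight stretches give $180^\circ$, convex features less, concave features
more. Measured at a *fixed* polygon of $1/w = 20$ vertices this would be the
classical Zahn–Roskies polygon encoding; measuring at *every* boundary point
instead superimposes all $20$-vertex polygon placements, so no feature falls
between vertices. Two closed forms anchor the implementation and its tests:
a circle yields the constant $180(1 - w)$ degrees ($171^\circ$ at $w = 0.05$,
by the inscribed-angle theorem), and a square corner with the window on the
adjacent sides yields $90^\circ$.

Window endpoints at fractional arc length are linearly interpolated between
vertices. Interior-versus-reflex disambiguation uses the signed cross
product under the counterclockwise convention, which `nucleus_outline()`
enforces at construction; the test suite cross-checks this against an
independent point-in-polygon probe along the angle bisector.

## Alignment, median and landmarks

Profiles are interpolated to a common length $L$ (default 1000) by circular
linear interpolation in arc length, then aligned by exhaustive search over
all $L$ circular offsets for the minimum root-mean-square difference — exact
by construction, with ties broken to the smallest nonnegative offset. The
population median is built by iterative re-alignment (align to the running
pointwise median, recompute, repeat until offsets stabilize, at most 10
rounds). The *initial* reference is the pointwise median of canonically
rotated profiles (each rotated so its own global minimum comes first); an
initial reference taken from any single profile would make the result depend
on input order, which the iterative scheme cannot always repair. All
profiles are finally rotated so the median's global minimum — the hook tip
in sperm — sits at position 1, giving every dataset the same start
convention.

Landmarks are the local extrema of the (3-point moving-average smoothed)
median: minima below $180^\circ$ are convex landmarks, maxima above are
concave. Alternating extremum pairs with amplitude below a 5° prominence
threshold are pruned, suppressing pixel-noise wiggles; both the smoothing
window and the threshold are exposed as arguments. Each landmark is then
located on each individual nucleus by minimizing the local RMS difference to
the median within ±5% of $L$ of the median position.

The per-nucleus **variability score** is
$\sqrt{\sum_i d_i^2 / L}$, the RMS deviation of the aligned profile from the
median, in degrees. It is computed after global alignment and before
per-landmark refinement, so refinement failures cannot leak into the
population-variability statistic.

## Vertical orientation and measurements

Bounding-box parameters require a reproducible frame. The implemented rule
places the *flat region below the hook* vertical: starting from the
under-hook concave landmark (the first concavity after the tip), the first
sustained stretch of near-$180^\circ$ profile positions is collected, capped
at a fixed 5%-of-perimeter arc window. The cap matters: a variable-length
"longest flat run" rule lets the reference direction jump between shape
families, making hook-length measurements incomparable across, say, a sweep
of hook sizes. A principal-axis fallback (with a warning) covers outlines
with no detectable flat region. The hook side is recorded (`left`/`right`)
rather than forced, since a rigid rotation cannot mirror chirality.

All Table-style parameters follow from the oriented outline: area (shoelace),
perimeter, maximum Feret diameter (convex-hull pairwise distances), minimum
diameter through the centre of mass (chords sampled at 0.5° steps; if the
centroid falls outside an extreme crescent, the nearest chord on the line is
used and logged), circularity $4\pi A / P^2$, bounding width/height and
ellipticity $H/W$, hook length and body width (horizontal distances from the
flat-region line to the two bounding-box edges, summing exactly to the
width), the tip–centre-of-mass–caudal angle (caudal reference = the most
deviant convex landmark in the posterior half of the perimeter), and the
landmark-to-landmark perimeter segment lengths.

## Consensus shapes and clustering

The consensus nucleus averages the x and y coordinates of corresponding
semilandmarks spaced every 1% of the perimeter from the hook-tip anchor,
over vertically oriented nuclei centred at the origin; the mean (not the
median) of coordinates is used. Clustering is agglomerative on the aligned
profiles (Euclidean distance, Ward linkage by default; average and complete
are available), cut at a user-chosen $k$, with a silhouette-based
suggestion available via `suggest_k()` — the right $k$ for a real sample is
a biological judgement, not an algorithmic rule. No per-position
standardization is applied: all positions share units and comparable scale.
Sub-clustering re-clusters one cluster's members in place, leaving other
labels untouched.

## The synthetic-shape generator

Because validation needs ground truth, the package renders parametric
nuclei. The falciform family is built from a thickened spine — a straight
body of length 6 um continued by a circular hook arc (length 3 um, turning
2.2 rad), with a half-width profile peaking at 1.5 um mid-body and tapering
to sharp points at both ends — sampled into 12 control points joined by a
periodic cubic spline. The defaults give an area near 19.5 um², matching the
scale of the mouse sperm nucleus; area and perimeter ground truth for
splined shapes come from a $10^4$-vertex polygonization, and the true arc
positions of the tip, under-hook concavity, ventral flat region and caudal
base are recorded for landmark scoring. Circles, ellipses and squares carry
closed-form truth (the ellipse perimeter via the complete elliptic
integral). Population noise perturbs control-point radii (relative sd =
noise scale); draws whose spline self-intersects are deterministically
re-drawn from follow-up sub-seeds, so a (spec, seed) pair always reproduces
the same population. Rendering rasterizes filled shapes at high intensity,
applies Gaussian blur and additive noise, and writes 16-bit single-channel
TIFF, approximating a cooled-CCD DAPI capture at 0.065 um/pixel.

What the generator does **not** emulate: intensity texture inside the
nucleus, acrosome/tail remnants, touching or overlapping nuclei, debris, and
uneven illumination. Passing the synthetic recovery suite therefore
demonstrates the geometry pipeline, not robustness to every real-world
artefact; detection on real slides will need per-dataset tuning of the size
gate and edge thresholds.

## Detection

The paper-style detector is edge-based: Gaussian smoothing, Sobel gradient,
hysteresis thresholding with thresholds expressed as *fractions of the
maximum gradient magnitude* (so a global exposure change alters nothing),
morphological closing, hole filling and connected-component labelling. Two
refinements give metrological accuracy: each object's boundary is re-drawn
at the half-intensity level between its local foreground and background
medians (the 50% crossing of a symmetrically blurred step edge sits at the
true boundary), and the traced pixel chain is smoothed with a 5-pixel
circular moving average and pushed half a pixel outward along the local
normal (pixel centres sit systematically half a pixel inside the contour).
On blurred synthetic shapes this brings areas within ~0.4% and perimeters
within ~0.3% of analytic truth; square corners lose ~2% of perimeter because
blur physically rounds them.

## Numerical choices and problem sizes

Exhaustive circular alignment is $O(L^2)$ per profile; at the default
$L = 1000$ and a few hundred nuclei this is seconds-to-minutes work, traded
deliberately for exactness. The validation suites run at $L = 400$–$500$
with populations of 25–50 nuclei per condition — sizes at which every
acceptance property is stable across seeds while the whole suite stays
interactive. Floating-point tie handling in the alignment treats scores
within $10^{-9}$ of the scale of the summed squares as equal (catastrophic
cancellation makes exact-zero comparisons meaningless there), resolving to
the smallest nonnegative offset.

## Known limitations

- Touching or overlapping nuclei are not separated (no watershed); the
  renderer refuses overlapping placements for the same reason.
- Hysteresis edge linking assumes the blur scale roughly matches the
  detection pre-smoothing; extremely sharp and extremely blurred objects in
  one image can shadow each other through the shared gradient normalization.
- The angle profile is measured on the traced pixel chain (lightly
  smoothed), not on a fitted continuous contour; sub-pixel features below
  the smoothing window are invisible.
- Only rigid orientation is used; chirality is recorded, never corrected.
```{r example, eval = FALSE}
pop <- make_population(25, shape_spec("falciform"), noise = 0.03, seed = 11)
fit <- fit_profiles(lapply(pop, `[[`, "outline"), L = 500)
summary(fit)
plot(fit)
records <- measure_nuclei(fit)
consensus <- build_consensus(attr(records, "oriented"))
plot(consensus)
```
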