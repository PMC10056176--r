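---
title: "Methods: how orientfilm quantifies biofilm morphology and orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how orientfilm quantifies biofilm morphology and orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orientfilm)
```

## The measurement problem

Mature biofilms imaged by stereomicroscopy after crystal-violet staining
appear as dark biomass on a lighter substrate. Two things make such images
hard to quantify. First, at 50–80% coverage the intensity histogram loses a
clean global valley, so global thresholds either flood or fragment the
segmentation; a *local* threshold is required. Second, much of the
biologically interesting structure is not captured by a binary mask at all:
the film organizes into mosaic subdomains with locally preferred texture
orientations, which calls for a per-pixel *orientation* analysis of the raw
grayscale image. `orientfilm` implements both, plus the statistics needed
to compare orientation regimes across samples.

## Pathway (a): local thresholding and shape statistics

**Niblack threshold.** At each pixel, `thr = m + k·S` where `m` and `S` are
the mean and *population* standard deviation over the centered
`(2·radius+1)²` window. Choices worth stating:

* *Boundary handling* is half-sample symmetric (reflective) padding, which
  avoids the spurious edge darkening of zero padding. The integral-image
  implementation reproduces a brute-force window oracle to machine
  precision (tested at 1e-9).
* *`k`* defaults to −0.2 with dark foreground: with `k < 0` the threshold
  dips below the local mean, so in windows mixing both phases it lands in
  the sparse valley between the dark-biofilm and light-substrate modes.
  Pixels exactly at the threshold are background under either polarity,
  so a constant image yields an empty mask.
* *`radius` is a required, image-dependent parameter* (window half-width).
  The meaningful regime is windows large enough to mix both phases almost
  everywhere — in practice a substantial fraction of the image side
  (`niblack_radius_sweep()` reports coverage across a radius grid so the
  plateau can be picked deliberately; nothing is chosen silently). On the
  384-px synthetic images used throughout the tests, radius 128 sits on
  that plateau and recovers ground-truth coverage within 0.02 at targets
  0.4–0.8.

**Shape statistics.** Connected components are extracted with a run-based
union-find labeler (8-connectivity by default, 4 available; border-touching
objects are kept but flagged). Circularity is the standard dimensionless
form `4πA/P²`, clamped at 1. The perimeter estimator matters here: naive
counting of boundary "crack" edges overestimates smooth perimeters by up to
`4/π`, which would depress circularity systematically. We count crack
edges `E` and boundary turns `T` (a lattice vertex whose 2×2 pixel
neighborhood holds 1 or 3 foreground pixels is one turn; a diagonal pair is
two) and use `P = E − 0.38·T`. The chamfer constant was calibrated once so
digitized disks of radius 10–80 px are measured within about 1% of `2πr`;
with it, a 30-px square scores Circ ≈ 0.81 (continuous limit `π/4`) and a
radius-20 disk ≈ 0.99. Hole boundaries count toward the perimeter. The
aspect ratio is `sqrt(λ₁/λ₂)` of the pixel-set covariance (the
moment-equivalent ellipse); a single pixel reports 1 and perfectly
collinear pixels report an `Inf` sentinel rather than an error. Histograms
use Sturges' rule with base-10 logs and a ceiling, `k = ⌈1 + 3.322 log₁₀
n⌉`, and the "circularity ≈ 1" / "AR ≈ 1" fractions take a tolerance
parameter (default 0.1) since "approximately one" is convention, not
mathematics.

## Pathway (b): Voronoi regularity

Object centroids seed a Euclidean Voronoi tessellation, computed by
clipping each seed's cell (starting from the window rectangle) against the
perpendicular bisectors of its neighbors, nearest first, with a distance
cutoff that stops once no remaining seed can cut the current polygon. The
tessellation is verified in the tests against a brute-force nearest-seed
classification of 10⁴ random points.

The regularity index is `VRI = mean(D)/sd(D)`. Two readings of `D` exist:
we pool the centroid-to-vertex distances across cells (default) and also
expose a per-cell-mean variant; likewise the "centroid" is the clipped
cell's polygon centroid by default, with the seed point as an option.
Cells touching the window boundary are excluded by default because clipping
distorts their distances — when fewer than two interior cells remain, the
pipeline falls back to including border cells with an explicit warning. A
perfect lattice drives `sd(D)` to zero and returns an `Inf` sentinel with a
`regular_pattern` flag rather than overflowing. VRI is scale invariant;
its absolute magnitude depends on the seed-rule and clipping conventions,
so analyses should rely on comparisons (the jitter ordering below), not on
absolute values.

## Pathway (c): structure-tensor orientation

The gradient pair feeds the windowed structure tensor
`J = G_σ * (∇f ∇fᵀ)`; orientation and coherency follow from its
eigenstructure:

* `θ = ½·atan2(2·Jxy, Jyy − Jxx)`, reported in degrees on [0, 180).
  Convention: image coordinates with y increasing downward; θ is the
  orientation of image *structures* (intensity isolines), 0° = horizontal,
  increasing counter-clockwise on screen. The synthetic generator shares
  this convention, so ground-truth angles compare directly.
* `C = sqrt((Jyy−Jxx)² + 4Jxy²)/(Jxx+Jyy) = (λ₁−λ₂)/(λ₁+λ₂)`, clamped to
  [0, 1]. Where the tensor energy `Jxx+Jyy` falls below 1e-12 of the image
  maximum, θ is undefined (NA) and C is set to 0, flagged rather than
  thrown.

Three gradient operators are provided. The default is the first-order
Riesz transform, applied in the frequency domain with multipliers
`−i·ωj/‖ω‖` and a zero DC term: it is rotation- and scale-invariant and
does not amplify high frequencies, which suits low-contrast biofilm
texture. Derivative-of-Gaussian (separable, reflective boundaries, scale
`sigma_d`) and central finite differences are the alternatives. The window
`sigma` defaults to 8 px — roughly half the dominant texture wavelength of
the synthetic images — and is the main resolution/stability trade-off: the
tensor is averaged over a neighborhood of that scale, so structures well
below it are smoothed into the local average. The tests pin down the
numerical behavior: orientation recovered within 1° on gratings at six
angles for both Riesz and Gaussian operators, rotation equivariance within
2° (bilinear-interpolation limited), coherency ≥ 0.95 on gratings versus
≤ 0.3 on isotropic noise, invariance of θ under affine intensity maps, and
stability of the Riesz result under wavelength doubling at fixed
`sigma/wavelength`.

**ROI summaries and angle series.** ROIs tile the frame on a deterministic
grid (counts that do not divide the image evenly produce minimal overlap;
a single ROI is centered). Within a ROI the per-pixel tensors are averaged
directly — summing tensor entries weights pixels by gradient energy, so
textureless pixels do not dilute the estimate — and the aggregated tensor
yields the dominant angle, an eigen-ellipse (axes ∝ √eigenvalues) and its
elongation. A ROI straddling two differently oriented subdomains looks
nearly isotropic in the aggregate, which is why the modal angles of the
coherency·energy-weighted angle histogram are reported too: 2° bins,
3-bin circular smoothing, peaks = local maxima above 1.5× the uniform
level, ties broken by larger mass then smaller angle, sub-bin position by
parabolic interpolation. Elongation below 1.5 flags a ROI near-isotropic.

The angle series records the top 3 modal angles of each of 20 ROIs,
N = 60 per sample. The 3-per-ROI reading is a design decision: it is the
configuration consistent with both customary numbers (20 ROIs, N = 60) and
it captures multimodal ROIs; `peaks_per_roi` is configurable, and ROIs
with fewer detected peaks are padded with their dominant angle.

## Cross-sample statistics

Angles are treated as linear values on [0, 180), mirroring common practice
in this workflow; this is statistically questionable near the wrap-around
(0° ≡ 180°), so a circular treatment (angle doubling) is the better choice
when samples straddle the boundary — the linear default is kept for
fidelity and the caveat documented. Box/violin summaries use type-7
quantiles, the 1.5-IQR outlier rule, and a Gaussian KDE with Silverman's
bandwidth; outliers are dropped only from the drawn violins, never from
the statistics unless requested. Pearson/Spearman come from `cor.test`.
The chi-square comparison is defined as a paired test on sorted
(quantile-matched) series with the second series as expectation and
N − 1 degrees of freedom, two-sided; this is one reasonable reading of a
"goodness-of-fit between two angle series", and a binned alternative
(shared Sturges bins) is provided. Zero expected values are floored at a
small epsilon and flagged. PCA standardizes every variable to mean 0 / sd 1
so no sample's variance dominates, and fixes signs so each component's
largest-magnitude loading is positive; series enter as sorted order
statistics so the j-th variable is comparable across samples. The
separation report works in the first two component scores: per-sample
centroids, their pairwise distances, the mean within-sample replicate
distance, their ratio, and a mean silhouette — descriptive quantities, not
hypothesis tests. No multiple-testing correction is applied to the
pairwise matrix; that is deliberate and should be kept in mind when many
samples are compared.

## The synthetic generator: what it does and does not emulate

`gen_oriented_texture` builds band-pass-filtered white noise with an
orientation-selective Fourier mask: a radial Gaussian band around
`1/wavelength` (width `ρ₀/3`) and an angular von-Mises weight whose
concentration `κ = (4a/(1−a))²` maps anisotropy `a ∈ [0,1)` from isotropic
(`a = 0`) to nearly 1-D; `a = 1` switches to an exact random-phase grating
so "pure 1-D" is exact, not asymptotic. Mean coherency is monotone in `a`,
and the dominant tensor angle equals the requested angle by construction.

`gen_biofilm_image` composites subdomain textures, dark colony discs with
logistic-smoothed edges, and a low-frequency modulation, then maps the
composite through a steep logistic onto the two intensity levels so that
exactly the target fraction of pixels falls below the
foreground/background midpoint — coverage is enforced by thresholding the
noiseless composite at its coverage quantile, which decouples coverage
from texture parameters. Within-phase texture is restored by a term
clamped to never cross the midpoint, so the ground-truth mask remains
exactly the sub-midpoint set. Defaults (384² px, levels 70/180, noise sd
3, wavelength 16 px, 25 colonies of radius 8–24 px) emulate a sharply
stained, strongly bimodal image — the regime in which Niblack thresholding
is the method of choice.

What the generator does *not* emulate: uneven illumination, out-of-focus
blur, RGB color (synthesis is grayscale; channel selection is exercised on
constructed arrays), cell-scale growth processes, and realistic texture
spectra of any particular instrument. Passing tests therefore demonstrate
correctness of the measurement chain under controlled, favorable
conditions, not performance on any particular microscope's output; on real
images the Niblack radius and window sigma must be chosen per image.

`gen_point_pattern` supplies the Voronoi fixtures: a square lattice
(equal nearest-neighbor distances), a jittered lattice (i.i.d. Gaussian
displacements, reflected back into the window so points stay inside), and
binomial ("Poisson") uniform points. Median VRI over 20 replicates is
strictly decreasing across jitter levels 1%, 5%, 10%, 20% of the spacing.

## Determinism and problem sizes

Every generator is a pure function of its arguments and seed: the global
RNG stream is saved and restored, so repeated calls are bit-identical and
do not perturb the caller's randomness. Pipeline runs with equal
configuration produce byte-identical CSV/JSON outputs (checked by md5 in
the tests), and every run writes its resolved configuration and file
digests into a manifest.

The test and acceptance workloads use 192–600 px images, 100–500-point
patterns, and a four-strain study of twelve 384² images (three replicate
seeds per strain at subdomain regimes centered on 20°, 60°, 100°, 140°,
anisotropy 0.9); these sizes were chosen so the full suite exercises every
claim in minutes on a single CPU while keeping all the statistical margins
comfortable. A single 384² image runs through all three pathways in about
a second.

## Known limitations

* Absolute VRI values are convention-dependent (seed rule, centroid
  definition, border policy); only comparisons are meaningful.
* Linear treatment of angles breaks down when orientation distributions
  straddle 0°/180°; use the circular option there.
* Per-pixel numerical parity with any particular GUI implementation of the
  structure tensor is not claimed; correctness is asserted against
  analytic cases and brute-force oracles instead.
* The perimeter chamfer constant is calibrated for compact, smooth-ish
  objects; extremely filamentous objects will still carry estimator bias.
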