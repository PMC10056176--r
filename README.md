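# orientfilm

Quantitative image analysis of mature, high-coverage bacterial biofilms in
stereomicroscopy images. Crystal-violet-stained biofilm appears as dark
biomass on a lighter substrate; at high coverage, global thresholds fail and
the interesting structure is *orientational*: the film organizes into
subdomains with locally preferred texture directions. `orientfilm`
implements the full digital workflow for this setting, in base R, along
three pathways:

* **(a) Binarization and morphology.** Local Niblack thresholding,
  `thr(x, y) = m(x, y) + k · S(x, y)` with the mean `m` and standard
  deviation `S` computed over a sliding `(2r+1)²` window (reflective
  boundaries, integral-image implementation), followed by
  connected-component statistics: area and coverage, circularity
  `Circ = 4πA/P²` with a turn-chamfered, anti-biased perimeter estimator,
  moment-ellipse aspect ratio `AR = major/minor`, and Sturges-binned
  histograms (`k = ⌈1 + 3.322 log₁₀ n⌉`).
* **(b) Spatial regularity.** Voronoi tessellation of object centroids and
  the Voronoi regularity index `VRI = mean(D)/sd(D)`, where `D` pools the
  distances from each cell's centroid to its vertices. Lattice-like
  arrangements give large VRI (a perfect lattice returns an infinite
  sentinel with a regular-pattern flag); irregular arrangements give values
  near zero.
* **(c) Orientation fields.** Per-pixel structure tensor
  `J = G_σ * [fx²  fx·fy; fx·fy  fy²]` with selectable gradient operators
  (Riesz transform — the default, rotation- and scale-invariant —,
  derivative-of-Gaussian, central finite differences), orientation
  `θ = ½·atan2(2Jxy, Jyy − Jxx)` in degrees on [0, 180), and coherency
  `C = (λ₁−λ₂)/(λ₁+λ₂) ∈ [0, 1]`. Fields are rendered as HSB maps (hue =
  orientation, saturation = coherency, brightness = input) and coherency
  maps, summarized over tiled ROIs (dominant angle, tensor-ellipse
  elongation, modal angles of the weighted angle histogram), and collected
  into angle series (20 ROIs × 3 peaks = N = 60 per sample). Cross-sample
  statistics: box/violin summaries with the 1.5-IQR outlier rule,
  Pearson/Spearman correlations, a paired chi-square comparison, and
  standardized PCA with a separation report.

Because suitable public image data are rare, the package ships a
first-class synthetic generator (`gen_biofilm_image`, `gen_oriented_texture`,
`gen_point_pattern`) that produces biofilm-like images and point patterns
with exact ground truth (coverage masks, per-pixel angle maps), so every
stage is validated end-to-end.

## Worked example

Two synthetic "strains" with different coverage and orientation regimes,
run through all three pathways:

```r
library(orientfilm)

specs <- list(
  wildtype = biofilm_spec(image_size = c(384, 384), coverage_target = 0.45,
    colony_count = 60, colony_radius_range = c(5, 12), rng_seed = 1,
    subdomains = mosaic_subdomains(c(384, 384), c(20, 40, 30, 30))),
  mutant   = biofilm_spec(image_size = c(384, 384), coverage_target = 0.62,
    colony_count = 60, colony_radius_range = c(5, 12), rng_seed = 2,
    subdomains = mosaic_subdomains(c(384, 384), c(110, 130, 120, 120))))
images <- lapply(specs, function(s) gen_biofilm_image(s)$image)

cfg <- run_config(niblack_radius = 128, n_rois = 12, roi_size = 96)
report <- run_study(images, cfg)
print(report)
#> study report: 2 sample(s), reference wildtype
#>    sample count  area relative_cvg      vri  coverage
#>  wildtype    33 66179      0.00000 5.330325 0.4488051
#>    mutant     8 90541     36.81228 1.937444 0.6140205
#> PCA: first two components explain 100.0% of the variance

print(report$pairwise[[1]])
#> Pearson r = 0.4030 (p = 0.0148); Spearman rho = 0.5203 (p = 0.00114)
#> chi-square (paired) = 2377, df = 35, two-sided p = 0
```

Reading the table: the mutant covers 61% of the frame against the wild
type's 45% (a +36.8% change in segmented area relative to the reference
sample), in fewer, larger components, and with a lower Voronoi regularity
index. The two samples' angle series sit far apart (the wild type's
orientations cluster near 30°, the mutant's near 120°), which the
chi-square comparison flags even though the linear correlations are modest.

Single pathways are available directly: `run_pathway_a` (mask + shape
table), `run_pathway_b` (Voronoi + VRI), `run_pathway_c` (orientation
field + ROI summaries + angle series), or the underlying functions
(`niblack_field`, `label_objects`, `tessellate`, `vri`, `gradient`,
`structure_tensor`, `orientation_and_coherency`, `collect_angle_series`,
`pairwise_stats`, `pca_angles`, ...).

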