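# poromech

Quantitative analysis of how fatigue loading changes the organic
(collagenous) matrix of cortical bone. After demineralization, everything
that is not collagen — vascular canals, lacunae, fissures, delaminations —
appears as dark pore-like objects in stained microscopy sections, and the
mechanical competence of the remaining matrix can be probed by unconfined
compression with simultaneous acoustic-emission (AE) monitoring. `poromech`
implements the full analysis chain for such experiments:

* **Segmentation** of calibrated 8-bit micrographs: 5×5 median denoising,
  brightness equalization by division with a strongly Gaussian-blurred copy
  of the image, fixed gray-level thresholding at 50, connected-component
  labeling (8-connectivity), and exclusion of objects touching the field
  border.
* **Pore morphometry.** For each object with area *A* (pixel count ×
  μm²/pixel) and perimeter *P*:
  - circularity `C = 1 − 4πA / P²` (0 for a circle),
  - elongation `E` = axis ratio of the ellipse with the same second
    central moments as the region,
  - shape roughness `SR = ((med(d)·min(d)) / max(d)²)^{1/3}` over the
    distances *d* from boundary points to the centroid (1 for a circle,
    lower for ragged outlines),
  plus per-slice total pore fraction (Σ object area / field area) and
  descriptor histograms (bin widths 60 μm², 0.1, 0.02, 0.02).
* **Mechanics.** Three-point-bending secant moduli
  `E = (F/δ)·L³/(48 I)` for fatigue protocols (first vs last cycle,
  percent change), and compression descriptors: engineering stress/strain,
  trapezoidal work (mJ), ultimate point at the global force maximum for
  transversely loaded samples, 50%-strain evaluation for longitudinal ones.
* **Acoustic emission.** Threshold-crossing hit detection (threshold =
  factor × baseline RMS, dead-time closing), event energies Σv², 0.1 s
  binning, and cumulative counts/energies truncated at 95% of maximum load
  (transverse) or 50% strain (longitudinal).
* **Statistics.** Paired *t* test, two-way ANOVA (histology × treatment)
  with interaction and Type III sums of squares for unbalanced groups, and
  Tukey–Kramer post hoc comparisons with stars at p < 0.05 / 0.02 / 0.01.
* **Synthetic data with ground truth.** Calibrated images of rasterized
  analytic pore boundaries (so true areas and elongations are known
  exactly), nonlinear force–deformation curves, and AE waveforms with
  injected bursts — every stage of the pipeline is testable end to end
  without external data.

## Worked example

```r
library(poromech)

spec <- image_spec(width_px = 512, height_px = 512, n_objects = 30,
                   axis_length_range_px = c(10, 22), axis_ratio_range = c(1, 2),
                   roughness_amplitude = 0.15, noise_fraction = 0.02,
                   illumination_gradient_amplitude = 0.2, seed = 7)
syn  <- generate_pore_image(spec)
mask <- segment_pores(syn$image)
mask
#> labeled_mask: 512 x 512 px, 30 objects (0 border-excluded)

slice <- measure_slice(mask)
slice
#> slice_morphometry: 30 objects, pore fraction 5.780%
head(slice$objects[, c("label", "area_um2", "elongation", "circularity",
                       "shape_roughness")], 3)
#>   label area_um2 elongation circularity shape_roughness
#> 1     1    864.6      1.479     0.06316          0.8107
#> 2     2    781.4      1.476     0.05882          0.8022
#> 3     3   3220.6      1.401     0.08503          0.8212
```

All 30 generated pores are recovered; the pore fraction (5.78%) is the
summed object area over the 512² px field. Objects here are moderately
rough ellipses, hence C well above 0 and SR well below 1.

A full 2×2 batch (plexiform/Haversian × fatigued/control) with group
summaries, ANOVA and Tukey tables written as CSV plus a checksummed
manifest:

```r
res <- run_demo("demo-out", seed = 1, image_px = 256)
res$group_summary[, c("histology", "treatment", "n_objects",
                      "area_mean", "shape_roughness_mean", "pore_fraction_mean")]
#>   histology treatment n_objects area_mean shape_roughness_mean pore_fraction_mean
#> 1        AM         F        28       694                0.658             0.0499
#> 2        PL         F        34      1489                0.736             0.1300
#> 3        AM         C        20       398                0.629             0.0205
#> 4        PL         C        24      1362                0.750             0.0840

res$anova$shape_roughness
#>                  term   sum_sq  df  mean_sq statistic   p_value
#> 1           histology 0.252103   1 0.252103   40.3661 5.959e-09
#> 2           treatment 0.001529   1 0.001529    0.2448 6.218e-01
#> 3 histology:treatment 0.011612   1 0.011612    1.8592 1.757e-01
#> 4           Residuals 0.637032 102 0.006245        NA        NA
```

The demo's synthetic groups are built with larger pores in the
Haversian-like (PL) fields, which the histology main effect picks up,
while the treatment effect on SR is (correctly, for this draw) not
significant at these small sample sizes.

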