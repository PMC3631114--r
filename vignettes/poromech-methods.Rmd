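---
title: "Methods: pore morphometry, mechanics and acoustic emission in demineralized bone matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore morphometry, mechanics and acoustic emission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poromech)
```

`poromech` quantifies how fatigue loading changes the collagenous matrix of
cortical bone: pore morphometry from stained sections of demineralized
samples, compression descriptors with acoustic-emission (AE) monitoring,
and the two-factor statistics comparing histological type (plexiform A-M
vs Haversian P-L) and pre-treatment (fatigued F vs control C). This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Image protocol

The acquisition the package assumes is a confocal field of 2048 × 2048
pixels at 2.971 μm² per pixel (3.53 × 3.53 mm). Segmentation is a fixed
three-stage protocol, deterministic by construction:

1. **Median denoising**, 5 × 5 window, against salt-and-pepper noise.
   Borders are reflect-padded so the filter cannot manufacture a dark rim
   that would later be labeled as an object. The window is configurable
   but 5 × 5 is the protocol constant.
2. **Brightness equalization by division.** Each pixel of the denoised
   image is divided by the corresponding pixel of a strongly
   Gaussian-blurred copy. The blur sigma must sit far above the pore
   scale and below the field size; the default is 50 px, configurable.
   The protocol fixes only that the blur is "strong"; the output scale of
   the ratio is a design choice. We map ratio 1.0 to gray 128 and clip to
   [0, 255], so the fixed threshold 50 keeps its meaning on the 8-bit
   scale: it selects pixels darker than about 39% of their local
   background. Blurred pixels are floored at 1 before the division so
   pure-black regions cannot produce undefined ratios. On a flat field
   the operation returns the constant 128 and is idempotent.
3. **Fixed-threshold segmentation** at gray level 50 (strict `<` for dark
   objects; polarity is configurable since stains and imaging modes
   differ), 8-connected component labeling (4-connectivity available),
   and removal of every component touching the raster border — partially
   visible objects carry no usable morphometry; they are counted
   separately. No minimum object size is applied by default: single-pixel
   objects are retained (configurable).

## The four descriptors

For every retained object, with pixel area calibration `s` (μm²/px):

* **Area** `A = pixel_count × s`, exact by definition.
* **Elongation** `E = sqrt(λ₁/λ₂)` from the eigenvalues of the second
  central moment matrix of the pixel coordinates — the axis ratio of the
  equal-second-moment ellipse. Degenerate regions use fixed conventions,
  flagged in the output: one pixel gives E = 1; a perfectly collinear run
  of n pixels (singular moment matrix) gives E = n, which stays monotone
  in visual elongation.
* **Circularity** `C = 1 − 4πA/P²`, exactly 0 for a circle and growing
  toward 1 with departure from circularity. Digitized near-circles can
  push `4πA/P²` marginally above 1, so C is clamped below at 0.
* **Shape roughness** `SR = ((med(d)·min(d))/max(d)²)^{1/3}` over the
  distances `d` from boundary points to the centroid: exactly 1 when the
  three order statistics coincide (a circle), lower for ragged outlines.

**Perimeter and boundary radii.** Counting pixel-edge steps overestimates
the perimeter of smooth shapes by up to ~27%, which would destroy the
C = 0 circle anchor, so the boundary is traced as the sub-pixel 0.5
iso-level polygon between pixel centers (marching squares). The raw
midpoint polygon still overestimates smooth perimeters by about 6%; a
circular moving average of the polygon vertices (window 5, applied when
the polygon has at least 10 vertices) reduces the error below ~0.5% for
disks of radius ≥ 20 px, giving C ≤ 0.01 on digitized disks at r ≥ 30.
The same smoothed vertices are the sample set for the SR radii — the
boundary-point set the definition calls for — and the median over an even
count is the mean of the two central values. Tests verify SR against an
independent exhaustive scan of all contour radii on every test object.

**Slice summaries.** Total pore fraction is Σ object area divided by the
*full* observed field area (border-excluded objects are not subtracted
from the denominator). Histograms use right-open bins of width 60 μm²
(A), 0.1 (E), 0.02 (C) and 0.02 (SR), anchored at 0 for A, C, SR and at
1.0 for E, since E cannot fall below 1.

## Mechanics

Bending fatigue is summarized by the secant modulus of the first and last
complete cycle of a constant-deflection three-point-bending protocol
(defaults: 300 cycles to 0.9 mm on a 32 mm span, 5 × 5 mm section). The
protocol names only a "secant" modulus; we evaluate the Euler–Bernoulli
beam formula `E = (F/δ)·L³/(48 I)`, `I = w h³/12`, at the cycle's peak
deflection (peak force if the ramp is non-monotone there). Since the
fatigue criterion is the *relative* change `100·(M_first − M_last)/M_first`,
any fixed geometric prefactor cancels; a sample failing mid-protocol
keeps its last complete cycle and is flagged.

Compression records are displacement–force tables triggered at 0.1 N;
strain is engineering strain on the initial (post-demineralization)
height — reported failure strains of ~50% make a true-strain convention
implausible. Work is the trapezoidal integral of force over displacement
(N·mm = mJ), within 0.1% of closed forms for polynomial curves sampled at
≥ 500 points. Transversely loaded (T) samples always fail within the
3 mm travel: the ultimate point is the *global* force maximum (a single
dominant failure event, robust to appended post-failure samples), and a
record whose maximum sits at its end signals no-failure instead of
guessing. Longitudinal (L) samples never fail, so their descriptors are
evaluated at 50% strain by linear interpolation; shorter records signal
insufficient range.

## Acoustic emission

The hit logic is standard threshold crossing: the threshold is
`threshold_factor ×` baseline RMS, an event opens at the first `|v|`
crossing and closes once `|v|` stays below threshold for the dead time.
Defaults `threshold_factor = 5`, `dead_time_s = 0.002` are exposed, since
the exact operationalization used with any given sensor chain varies;
energies are Σv² in arbitrary units, matching how AE energy is tabulated
for these experiments. The baseline is the RMS of the quietest decile of
0.1 s bins, robust when emission starts immediately. For Gaussian noise a
5 × RMS threshold yields well under one false event per 10 s at
44 000 S/s, while injected bursts with peaks ~10× the noise RMS are
recovered at ≥ 95%. No band-pass filter is applied: the physical sensor
band (1–16 kHz) is hardware, and synthetic fixtures are band-limited by
construction.

Events are binned at 0.1 s by onset. Cumulative counts and energies are
truncated at the first time force reaches 95% of its maximum on the
rising branch (T samples — a pre-peak cutoff that excludes the final
fracture) or at 50% strain (L samples); a cutoff beyond the record
accumulates over the whole record with a warning.

## Statistics

Group comparisons follow the two-factor design: two-way ANOVA with
interaction, histology × treatment. Because group sizes are unbalanced
(e.g. 12 vs 16 slices, thousands of objects differing per group), the
sums of squares are partial (Type III), computed from sum-to-zero
contrasts by dropping each term's columns from the full interaction
model; for balanced data this reduces to the classical decomposition.
Tests verify agreement with `car::Anova(type = 3)` to 1e−8 and an
empirical type-I error of 5% ± 1.5 points over 2000 null replicates.
The post hoc is Tukey–Kramer over the four cells, using the residual
mean square of the full model and the studentized range distribution,
with the harmonic `1/n_i + 1/n_j` form for unequal n and stars at
p < 0.05 / 0.02 / 0.01. Objects are treated as independent observations
in object-level ANOVA, mirroring how object counts are reported in this
kind of analysis; this ignores within-slice clustering, so a slice-level
analysis (pore fraction) is provided alongside and both are written by
the pipeline. The paired *t* test (fatigue effectiveness) delegates to
`stats::t.test`; identical series return t = 0, p = 1, while constant
non-zero differences are rejected as degenerate.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage has known ground truth.

* **Images.** Objects are star-shaped analytic boundaries: an oriented
  ellipse radius `r₀(θ)` times `1 + a·Σₖ cₖ cos(kθ + φₖ)`, k = 3..8,
  with Σ|cₖ| = 1 so the relative perturbation never exceeds the roughness
  amplitude `a < 0.5` and the boundary cannot self-intersect. Rasterization
  is by pixel-center inclusion, so the true enclosed area `½∮r²dθ` is
  computable by quadrature and digitization error is quantifiable. The
  illumination field is a quadratic surface normalized to mean 1 (the
  smooth unevenness the equalization step targets); salt-and-pepper noise
  replaces a set fraction of pixels with 0 or 255. Defaults emulate the
  assumed acquisition: 2048² px at 2.971 μm²/px, background 200 / object
  40 gray levels, pore semi-axes 10–25 px (osteonal-canal to lacunar
  scale), illumination amplitude 0.2, noise fraction 0.02. Tests run at
  512² or smaller with the same per-pixel statistics — the protocol is
  local, so field size only multiplies the object count.
* **Compression curves.** Power-law stress `σ = σ₀ εᵖ` (default p = 2)
  on a ~5 mm cube; T curves drop ≥ 50% within 2% strain past the failure
  strain, L curves stay monotone through the travel. This reproduces the
  *shape* and truncation behavior of matrix compression, not any
  constitutive model of collagen.
* **AE waveforms.** Gaussian baseline plus exponentially decaying
  sinusoidal bursts (2–8 kHz, τ = 2 ms) at Poisson times; a fraction
  (default 0.1) of bursts carries 5–15× energy, the high-energy
  population superimposed on near-continuous low-energy emission typical
  of demineralized matrix. Defaults (baseline 0.01 V, burst peaks ~12×
  RMS, ~20 events/s over a test lasting tens of seconds) give hit counts
  of the order such experiments tabulate.

What passing tests on these fixtures does *not* show: real histology has
textured tissue background, touching pores, stain variability and
out-of-focus light, none of which are modeled; real AE has sensor
coupling and frequency-dependent attenuation. The generators validate
the *computational* chain — correctness of the descriptors, the
truncation rules, the statistics — not biological fidelity.

## Numerical choices and edge cases

* Median/Gaussian filter borders: reflect padding, handled in this
  package so the filtering backend's boundary convention never reaches
  the field of view.
* Division-by-zero guard in equalization: blurred pixels floored at 1.
* Contour fallback: a region whose bounding box yields no traceable
  contour (not reachable through the public API) is assigned its
  equivalent-disk perimeter and flagged.
* Ties in the strain/force interpolations use ordered `approx`.
* Placement of synthetic objects retries up to 1000 draws and then
  reports an overcrowded specification rather than degrading to
  overlapping objects.
* All generators consume a single integer seed and are bitwise
  reproducible; the segmentation protocol has no random state at all.

## Problem sizes used by the test and acceptance suites

Parameter-recovery checks run 20 seeded 512² fields with ≥ 30 objects
each (noise 0.02, illumination 0.2): ≥ 95% of objects recovered, mean
area error per field < 2%, mean elongation error < 5%, pore fraction
within 1 percentage point of truth. Statistics oracles run 50 seeded
datasets against reference implementations and 2000 null replicates for
the type-I rate. AE checks use 5–10 s records at the native 44 kHz. The
end-to-end demo writes a full 2 × 2 batch at 256² px. These sizes were
chosen as the smallest at which the asymptotic claims (perimeter
convergence, recovery rates, test levels) are comfortably exhibited.

## Known limitations

* Touching pores are not separated (no watershed); they are measured as
  one object, consistent with pooling every non-collagenous space —
  canals, lacunae, fissures, fracture spaces — into a single object class
  regardless of origin.
* The perimeter estimator is tuned for smooth-ish boundaries; at very
  high roughness the vertex smoothing slightly underestimates the true
  arc length, which biases C down and SR up relative to the analytic
  boundary. Monotonicity in roughness is preserved and tested.
* Object-level ANOVA inherits the independence caveat above.
* Absolute AE energies are arbitrary units; only within-study contrasts
  are meaningful.
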