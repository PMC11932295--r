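---
title: "Methods: ratiometric bioluminescence colorimetry for cadmium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric bioluminescence colorimetry for cadmium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadmilume)
```

## The measurement model

A cadmium-sensitive firefly luciferase emits green light that shifts toward
orange as Cd²⁺ binds the enzyme. Photographed in a dark box, each reaction
well is a self-luminous disk whose *color*, not brightness, encodes the
cadmium concentration. The package reduces a well to normalized chromatic
coordinates `r = R/(R+G+B)`, `g`, `b` and the green/red ratio `ρ = G/R`.
Because `ρ` is a quotient of two channels of the same emission, it cancels
everything that scales all channels together: exposure time, ISO, enzyme
amount, reaction volume, and the slow decay of the luminescent signal. That
is the entire point of a ratiometric readout, and it is what the pipeline's
exposure-invariance tests exercise end to end.

Over the assay's working range (0–2 mM) the readout is modelled as linear in
concentration, `ρ = β₀ + β₁C` with `β₁ < 0`. The standards row (the 0 mM
water control plus eight cadmium standards) is fitted by ordinary least
squares; the control is included as a calibration point because it anchors
`β₀`, the pure-green ratio. Unknowns are estimated by inverting the line,
with the classical inverse-prediction standard error

$$\mathrm{SE}(\hat C) = \frac{s}{|\beta_1|}
 \sqrt{1 + \frac{1}{n} + \frac{(\rho - \bar\rho)^2}{\beta_1^2 S_{xx}}},$$

which is smallest near the middle of the calibration cloud and grows
symmetrically away from it. A fitted slope ≥ 0 is treated as an assay
failure (mislabelled wells, dead enzyme), not as a usable calibration.
Out-of-range estimates are flagged (`below_range` / `above_range`) and still
reported; clamping them would hide exactly the failures a field assay needs
to surface.

**Assumptions.** The plate is photographed face-on in a fixed dark box (≤ ~5°
rotation, no perspective distortion); the wells are the only light sources;
the camera response is linear in exposure (no gamma or tone curve applied to
the saved image); and the ratio–concentration relation is linear over the
standards' range. Nonlinear (e.g. sigmoidal) calibration is deliberately out
of scope; the fitting step is isolated behind `fitCalibration()` so an
alternative could be added without touching the rest.

## Image-analysis choices

* **Detection channel — per-pixel channel maximum.** A luminance weighting
  (0.2R + 0.7G + 0.1B) would make green wells several times brighter than
  orange ones and bias detection against high-cadmium wells; the channel max
  treats both ends of the calibration range symmetrically.
* **Thresholding — Otsu on the integer histogram** (exhaustive
  between-class-variance scan; plateau midpoint on ties), with a
  `fixed:<T>` fallback for pathological scenes. Foreground is strictly above
  threshold. A constant image has no separable classes and is an error.
* **Mask cleanup.** Morphological opening with a disk of radius 1 removes
  noise specks smaller than the structuring element. At the component stage
  interior holes are filled: detection follows outer contours, so a few
  shot-noise pixels dipping below threshold inside a dim well must not
  distort its area or perimeter.
* **Shape filters.** `min_area = 100` px² rejects dust; `min_circularity =
  0.6` (with `4πA/P²`, edge-count perimeter with the π/4 Crofton correction,
  clamped at 1) rejects glare streaks while passing digitized disks, whose
  circularity comes out ≈ 0.99. Both are user-tunable.
* **Grid assignment — y-gap splitting.** Detections sorted by y are split
  into physical rows wherever the gap exceeds half the median detection
  diameter, then ordered by x within rows. With the default geometry (60 px
  pitch, 18 px wells) this tolerates the intended ≤ 5° of plate rotation: a
  3° tilt skews within-row y by ~3 px per column, far below the 18 px split
  threshold, while the 60 px row gap stays unambiguous. A fitted homography
  would add nothing for face-on dark-box photographs.
* **Background — local annulus median** (1.2–1.5 well radii, excluding all
  detected wells). Dark-box frames still have a nonzero floor (dark current,
  stray light); no dark-frame capture exists in the protocol, so the
  background is estimated per well from its own neighbourhood.
* **Color — median over the core disk** (0.7 of the detected radius). The
  median resists residual glare and dust; the core scale keeps the cosine
  rim falloff out of the measurement. Pixels saturated in any channel are
  excluded, and a well with more than 50% saturated core pixels is refused
  outright (`invalid` in the report): a censored median is biased low in the
  brightest channel and would silently corrupt the ratio.

Per-well failures (saturation, undefined ratio, empty ROI) flag that well
without aborting the run; a calibration failure aborts, because no
concentration can be reported without a line.

## The synthetic plate generator

No reference photographs are distributed with the assay, so the generator is
the package's ground truth and is first-class, tested code. It emulates the
dark-box scene: a uniform dark floor, disk wells (flat core to 0.8 r, cosine
falloff to the rim) at grid positions with optional rotation and Gaussian
center jitter, colored by the emission model, with CCD-style per-pixel noise
— Poisson photon noise (via `photon_gain`) plus Gaussian read noise —
quantized and clipped to the bit depth. One seeded generator drives all
randomness, so identical spec + seed is bit-identical.

Ground truth is defined in ratio space: `ρ(C) = ratio0 + ratio_slope·C`
(defaults 2.0 and −0.75 per mM, keeping ρ positive up to 2 mM and roughly
halving the green/red balance across the range, i.e. a green → orange
progression). In `ratio_linear` mode the channels are set directly from the
line (`R = exposure`, `G = exposure·ρ`, `B = 0.1·exposure` as a fixed blue
floor). In `spectral` mode the well emits a two-Gaussian mixture (defaults
550/610 nm, 30 nm width — nominal green firefly emission and its red-shifted
form; the real enzyme's peaks are not pinned down here, so they are
configurable) whose mixing weight is solved by root-finding so the
camera-integrated G/R — Gaussian channel bands at 460/540/610 nm, 1 nm
Riemann sums over 400–700 nm — equals the same line exactly. Defining truth
in ratio space and fitting the spectrum to it guarantees the generator
satisfies the assumed linearity exactly, which makes calibration recovery a
sharp test: any bias the pipeline shows is the pipeline's, not the
generator's.

**Default conditions** (the study conditions for all accuracy figures): a
2×9 layout with the water control and standards at 0.1, 0.25, 0.5, 0.6, 0.8,
1.0, 1.5, 2 mM on top and three samples at 0.5, 1.0, 1.5 mM below; 18 px
wells on a 60 px pitch in a 640×240 8-bit frame; exposure 90 counts (peak
noiseless channel ≈ 180 counts, 70% of full scale — bright but safely
unsaturated, as a careful operator would expose); background 5 counts, read
noise 2 counts, photon gain 1, 1 px center jitter. At these levels the
per-well ratio noise is a fraction of a percent, so the ten-plate recovery
summary measures pipeline fidelity, not the noise dial.

**What the generator does not model:** optical blur/PSF, JPEG compression,
Bayer demosaicing, vignetting or flat-field error, perspective, well-to-well
enzyme variability, and the luminescence decay over minutes. Passing the
synthetic suites therefore demonstrates correctness of the computational
pipeline under the stated image model — not robustness to every artifact a
phone camera can produce.

## Numerical choices and problem sizes

* Pixel coordinates are 0-based, origin top-left, x rightward, y downward;
  centroids are intensity-unweighted and sub-pixel.
* Circularity values pushed slightly above 1 by discretization are clamped;
  the validity bound tolerates polygonal-perimeter error up to 1.1 before
  clamping.
* The spectral mixing weight is solved by `uniroot` to 1e−13 on the
  monotone α → ratio map; out-of-gamut targets (ratio beyond what pure green
  or pure red can produce under the camera bands) are an error, not a clamp.
* The exposure-invariance property is asserted on 16-bit noiseless renders
  at exposures 9000 and 4500, where the 1-count quantization floor is ~1e−4
  relative; at 8 bits quantization alone moves estimates by ~7e−3 mM, which
  would dominate the 1e−3 mM agreement being demonstrated.
* Monte-Carlo checks (median concentration under noise, OLS sampling
  distribution) use 1000 fixed-seed replicates; end-to-end accuracy uses ten
  plates × three samples. The full suite runs in well under a minute on one
  CPU.
* `fitCalibration` requires ≥ 3 points at ≥ 2 distinct concentrations —
  the minimum leaving a residual degree of freedom for `s` — and rejects
  layouts that cannot provide them at construction time.
* Ties in detection ordering are broken by (y, x); row splitting ties are
  resolved in favour of the stable sort order, making reports byte-identical
  across reruns.

## Limitations

* The linear OLS line is the package's calibration model; if the true
  response saturates near the range edges, the range flags are the only
  guard. No LOD/LOQ machinery beyond those flags.
* Mercury cross-sensitivity of the enzyme is a wet-lab concern the software
  cannot see; a mercury-contaminated sample will read as (wrong) cadmium.
* Grid inference assumes row-dominant layouts photographed face-on; heavily
  rotated (> ~5°) or perspective-distorted plates need rephotographing, not
  parameter tuning.

## A complete run

```{r example}
report <- runPipeline(plateSpec(seed = 1))
report
wellMeasurements(report)[, c("row", "col", "role", "ratio", "conc_mM", "flag")]
```
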