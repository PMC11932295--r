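# cadmilume

Quantification of cadmium in water samples from the **color** of firefly
luciferase bioluminescence, photographed on a well plate in a dark box.

Cadmium-sensitive firefly luciferases shift their emission from green toward
orange as Cd²⁺ binds. A plate is loaded with a water control, a row of cadmium
standards (0.1–2 mM) and the unknown samples; the only light in the frame is
the wells' own luminescence. `cadmilume` is the computational side of that
assay for people who want to run it from a script instead of a phone app:
analytical chemists and teaching labs doing field-style heavy-metal screening,
and method developers who need a fully controlled synthetic test bed.

## Method

For each detected well the package extracts background-subtracted channel
medians `(R, G, B)` and forms normalized chromatic coordinates

```
r = R / (R + G + B),   g = G / (R + G + B),   b = B / (R + G + B)
```

and the ratiometric readout `ρ = G / R` (= `g / r`), which is invariant to
exposure, enzyme amount and integration time. Over the working range the
readout is linear in cadmium concentration, so the standards row is fitted by
ordinary least squares,

```
ρ = β₀ + β₁ C,     β₁ < 0,
```

and unknowns are read off the inverted line, `Ĉ = (ρ − β₀) / β₁`, with the
classical inverse-prediction standard error

```
SE(Ĉ) = (s / |β₁|) · sqrt(1 + 1/n + (ρ − ρ̄)² / (β₁² Sxx)).
```

Estimates outside the standards' range are flagged, never clamped. Unit
helpers convert in-well mM back to the original sample (evaporative
concentration factor) and to ppm (mg/L) on a CdSO₄ or elemental-Cd basis.

The pipeline stages are: channel-max detection image → Otsu threshold +
morphological opening → connected components filtered by area and
circularity → y-gap row splitting to assign the plate grid → annulus-median
background → core-disk color extraction → calibration → inverse prediction →
CSV/JSON report. A seeded synthetic renderer (`plateSpec()`, `renderPlate()`)
draws physically motivated plates (flat-core disks, Poisson + read noise,
optional two-peak emission spectra integrated against Gaussian camera bands)
with a ground-truth table for every well.

## Worked example

```r
library(cadmilume)

# a synthetic plate: control + 8 standards on top, samples at 0.5/1.0/1.5 mM
report <- runPipeline(plateSpec(seed = 1))
report
#> AnalysisReport: 12 wells (3 sample)
#> CalibrationModel: ratio = 2.0163 -0.7575 * C (mM), n = 9, R^2 = 0.9997, residual sd = 0.008523, range [0.00, 2.00] mM
#> Sample estimates (mM):
#>   label  ratio conc_mM  se_mM     flag
#> 1    S1 1.6154  0.5292 0.0119 in_range
#> 2    S2 1.2697  0.9856 0.0119 in_range
#> 3    S3 0.8667  1.5175 0.0127 in_range
```

The fitted line recovers the generator's true color law (intercept 2.0, slope
−0.75 per mM) and the three unknowns land within a few percent of their true
0.5, 1.0 and 1.5 mM. `writeReportCSV()` / `writeReportJSON()` save the table
(`row, col, role, label, ratio, conc_mM, se_mM, flag, orig_conc_uM, ppm`);
`annotateReport()` writes an overlay image with outlined wells and estimates.

For real photographs: `readPlateImage("plate.png")` plus a layout
(`parseLayout("layout.json")` or `defaultLayout()`), then
`runPipeline(image, layout)`.

A command-line interface wrapping these functions ships in
`system.file("scripts", "cadmilume.R", package = "cadmilume")` with
`analyze`, `simulate` and `selftest` subcommands.

## Vignette

`vignettes/cadmilume-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, the synthetic
generator's noise model and its limits, and the numerical choices.
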