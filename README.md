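# uricolor

Digital readout for paper-based colorimetric detection of urinary uric
acid. Filter paper treated with potassium ferricyanide and ferric chloride
forms Prussian blue in proportion to the uric acid applied; a scanned or
photographed spot then carries the concentration in its darkness. This
package turns such images into quantitative, clinically interpretable
results, for people building or validating low-cost paper diagnostics:
assay developers, point-of-care researchers, and anyone who needs a
reproducible image-to-ppm pipeline with honest censoring and uncertainty.

## What it computes

* **CMY gray conversion** — per pixel `gray = (R+G+B)/3`, then
  `CMY = 255 − gray`, so darker (more analyte) is larger.
* **Spot ROI detection** — background-median + 3·MAD threshold on the image
  border, largest connected component, enclosing circle shrunk 15% to skip
  the coffee ring; Tukey-fence screening of aberrant pixels.
* **Saturating calibration** — `G(C) = G0 + (Gmax − G0)(1 − e^(−C/τ))`,
  fitted by nonlinear least squares and inverted in closed form, with
  estimates censored at the saturation concentration `C_sat95 = τ ln 20`
  (the colour stops discriminating near 500 ppm).
* **Temperature correction** — linear gray-vs-°C drift model, additive
  correction back to the 25 °C calibration reference.
* **Clinical remark** — against the published acceptable range
  300–700 ppm (inclusive), after multiplying by the sample dilution factor
  (default 2X).
* **Reaction kinetics** — order selection among the linearized rate laws
  (`x = Kt`; `ln10·log10(a−x) = −Kt + c`; `1/(a−x) = Kt + c`) with
  per-order asymptote estimation; colour formation conforms to first-order
  kinetics with `K ≈ 0.64 s⁻¹`.
* **Synthetic generator** — deterministic spot images, calibration
  standards, kinetics and temperature series from known ground truth, so
  the whole pipeline is testable without any instrument.

## Worked example

```r
library(uricolor)

truth <- truth_bundle()   # generator ground truth (saturation at 500 ppm)

# calibrate from synthetic standards (0-1000 ppm, 4 replicates each)
std   <- gen_standards(seq(0, 1000, by = 50), truth = truth, seed = 42)
curve <- fit_calibration(std)
curve
#> <calibration_curve [expsat]>
#>   G0 = 20.054, Gmax = 170.008, tau = 167.001 ppm
#>   C_sat95 = 500.3 ppm, r^2 = 1.0000, residual SD = 0.066 gray
#>   fitted on 21 standards at 25 degC

# quantify a spot image at 250 ppm (applied, i.e. 2X-diluted, scale)
img <- tempfile(fileext = ".png")
write_spot_png(gen_spot_image(250, truth, seed = 7), img)
quantify_image(img, curve)
#> uric acid 500 +/- 1 ppm (within acceptable limit; mean CMY gray 136.48
#> over 8176 px, 175 outliers removed, 2X dilution, 25 degC)
```

The spot was prepared at 250 ppm on the applied-sample scale; with the
default 2X dilution the undiluted urine estimate is 500 ppm, inside the
300–700 ppm acceptable band, read from 8176 disc pixels of which 175
(~2%) were screened out as outliers.

```r
# reaction-order analysis of a colour-formation video series
res <- analyze_kinetics(gen_kinetics(truth, seed = 1))
glance(res)
#> # A tibble: 1 x 4
#>   best_order K_best a_best r_squared
#>        <int>  <dbl>  <dbl>     <dbl>
#> 1          1  0.630   150.     0.997
```

First-order kinetics win (r² = 0.997 on the log-linear plot) with a rate
constant of 0.63 s⁻¹ recovered from data generated at 0.64 s⁻¹.

Fitted objects have `tidy()`, `glance()` and `autoplot()` methods; a
command-line interface (`inst/cli/uricolor`) exposes `quantify`,
`calibrate`, `kinetics` and `simulate` subcommands with JSON output.

## Further reading

The methods vignette (`vignettes/uricolor-methods.Rmd`) documents the
model assumptions, the numerical choices (asymptote estimation,
formation-phase restriction, parsimony tie-break, censoring and clamping
rules), what the synthetic generator does and does not emulate, and the
package's known limitations.
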