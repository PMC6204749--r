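---
title: "Methods: quantifying urinary uric acid from paper-assay images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying urinary uric acid from paper-assay images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uricolor)
```

## The assay and the readout problem

Uric acid applied to paper treated with potassium ferricyanide and ferric
chloride reduces Fe(III) and forms Prussian blue, an insoluble pigment whose
darkness increases with the amount of uric acid. A scanner or camera turns
that colour into an 8-bit RGB image; the readout problem is to turn the image
back into a concentration with an uncertainty, a saturation flag and a
clinical interpretation.

The pipeline is:

1. **Gray conversion.** Per pixel, `gray = (R + G + B) / 3`, kept as an exact
   fraction. We then invert the scale, `CMY = 255 - gray`, so that darker
   colour (more product, more analyte) means a *higher* number. All
   quantification happens on the CMY scale.
2. **ROI detection.** The spot is found by thresholding at the background
   median plus three background MADs (scaled MAD, consistent with a normal
   background), where the background is the outer 10% image border. The
   largest connected component above threshold is taken, its enclosing circle
   (centroid plus maximal member distance) fitted, and the radius shrunk by
   15% to exclude the coffee-ring accumulation at the drying edge. Pixel
   membership uses pixel-centre distance with 1-based row/column indices, the
   native R convention.
3. **Pixel screening.** Dust, fibre shadows and reflections produce isolated
   aberrant pixels. A single-pass Tukey rule removes values outside
   `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quantiles). The rule is
   parameter-free; on spot-like pixel distributions it is idempotent, so a
   single pass is well defined.
4. **Calibration inversion** and classification, described next.

## The saturating calibration model

The measured colour saturates with concentration: beyond roughly 500 ppm the
paper cannot get visibly darker. We model the standards with a
three-parameter exponential-saturation curve

$$G(C) = G_0 + (G_{max} - G_0)\,\bigl(1 - e^{-C/\tau}\bigr),$$

with baseline gray $G_0$ (blank), asymptote $G_{max}$ and scale constant
$\tau$ (ppm). The form is monotone, analytically invertible, and has a
natural operational saturation point: we define $C_{sat95} = \tau \ln 20$,
the concentration at 95% of the span. A linear-range-only calibration was the
main alternative; the saturating form was chosen because it uses all
standards and makes the censoring point a fitted quantity rather than a
user-supplied cut-off.

Fitting is Levenberg–Marquardt nonlinear least squares on all replicate
points (parameter tolerance 1e-8), initialised from the data ($G_0$: mean
gray of the lowest standard; $G_{max}$: largest per-concentration mean;
$\tau$: half the largest concentration). At least four distinct
concentrations are required, with anchors at or below 50 ppm and at or above
400 ppm, so both the baseline and the bend are constrained.

Inversion is closed-form,
$C = -\tau \log\!\bigl(1 - (G - G_0)/(G_{max} - G_0)\bigr)$, with three
guards:

* gray at or above 95% of the span: the estimate is **censored** at
  $C_{sat95}$ and reported as a lower bound;
* gray between $G_0 - 2\,\hat\sigma$ and $G_0$ (blank noise): clamped to
  0 ppm;
* gray below $G_0 - 2\,\hat\sigma$: rejected as signal below blank.

The reported concentration refers to undiluted urine: the estimate on the
applied-sample scale is multiplied by the dilution factor (default 2,
matching a two-fold dilution; 2–5X are typical). The uncertainty half-width
is a delta-method interval, $z_{0.975}\,\hat\sigma / |dG/dC|$ at the
estimate, scaled by the dilution factor; $\hat\sigma$ is the calibration
residual SD. This is a pragmatic recipe — it propagates calibration scatter
only, not spot-to-spot manufacturing variation.

Classification uses the published acceptable range for urinary uric acid,
300–700 ppm, inclusive at both ends: `below_range`,
`within_acceptable_limit`, `above_acceptable_limit`. A point of caution we
deliberately did not resolve: clinical sources often quote daily excretion
(mg/day), which equals ppm (mg/L) only for a 1 L daily urine volume. The
remark logic follows the published ppm usage literally and should not be
read as a diagnosis.

## Temperature correction

Developed colour intensity drifts upward with temperature (paper yellowing
contributes); over 25–50 °C the drift is adequately linear, anchored in the
generator at gray 82 (25 °C) and 96 (50 °C), i.e. 0.56 gray/°C. We fit
`gray = intercept + slope * T` by OLS (at least three distinct temperatures)
and correct measurements additively back to the calibration reference
temperature (default 25 °C), clamping to [0, 255]. Temperature-specific
calibration curves would be the more faithful alternative when the drift
interacts with concentration; the additive offset is the simplest model
consistent with the observed monotone trend. Published plots quote the drift
in RGB units while reporting results in CMY; the package fits whatever
scheme the input series declares and leaves that inconsistency to the user's
metadata.

## Reaction-order kinetics

Colour formation $x(t)$ (CMY gray, a product proxy) is recorded from video
(default 30 frames/s). Candidate rate laws are compared through their
classical linearizations:

| order | linear plot | rate constant |
|-------|-------------|----------------|
| 0 | $x$ vs $t$ | $K = $ slope (gray/s) |
| 1 | $\log_{10}(a - x)$ vs $t$ | $K = -\ln(10)\cdot$ slope (1/s) |
| 2 | $1/(a - x)$ vs $t$ | $K = $ slope (1/(gray·s)) |

Three numerical choices matter and are worth stating plainly:

* **Asymptote estimation.** The asymptote $a$ (limiting gray, proxy for the
  initial reactant amount) is a free parameter of orders 1 and 2. Each order
  estimates its own $a$ by nonlinear least squares of its integrated rate
  law ($x = a(1 - e^{-Kt})$ for first order, $x = a - 1/(Kt + 1/a)$ for
  second order), falling back to a coarse grid search over
  $(\max x,\ 1.5 \max x]$ maximizing the linearized $r^2$ when the nonlinear
  fit fails (e.g. on a pure ramp, where the first-order model degenerates).
  A fixed grid alone is too coarse: its resolution bounds the achievable
  precision of $K$, and forcing $a > \max x$ biases $K$ badly when noise
  pushes plateau samples above the true asymptote.
* **Formation-phase restriction.** Once the reaction plateaus, $a - x$ is
  noise-dominated and its log or reciprocal is uninformative (and explosively
  leveraged). All three linearized fits therefore use only samples with
  $x \le 0.95 \max x$ — the same subset for every order, so $r^2$ values are
  comparable. This is the linearized-kinetics analogue of fitting the
  initial-rate region.
* **Order selection with parsimony.** Orders 1 and 2 can imitate a straight
  line arbitrarily well by letting $a \to \infty$, so raw argmax-$r^2$
  selection degenerates to a coin flip on true zero-order data, with ties at
  the $10^{-4}$ level. The selected order is therefore the *lowest* order
  whose $r^2$ is within $10^{-3}$ of the maximum. On noiseless data of each
  true order the selection is exact; at noise SD 1 gray it is correct in
  60/60 simulated trials.

The conversion constant for the base-10 linearization is the exact
$\ln 10 = 2.302585\ldots$, not the conventional rounded 2.303 — with the
rounded constant, noiseless data could never recover $K$ to better than
about $2\times10^{-4}$ relative.

## The synthetic generator

No public image set exists for this assay, so the package ships a
deterministic generator whose defaults anchor every printed behaviour of the
system: the truth calibration curve is $(G_0, G_{max}, \tau) = (20, 170,
500/\ln 20)$ so that saturation lands exactly at 500 ppm; kinetics are first
order with $K = 0.64\,\mathrm{s}^{-1}$ toward $a = 150$ gray, sampled at
30 fps for 10 s; temperature drift passes through (25 °C, 82) and
(50 °C, 96). $G_0$, $G_{max}$ and $a$ magnitudes themselves are generator
choices — published axes do not pin them — and are stated in every fixture
manifest. Noise defaults: pixel SD 2 gray; replicate-level standard noise
$2/\sqrt{1000}$ gray (the standard error of a mean over roughly a thousand
spot pixels); series SD 1 gray; 2% of disc pixels shifted +60 gray as
dust-like outliers.

Spot images are gray-on-white discs with equal R = G = B channels; values
are rounded to 8-bit only when written, which adds at most half a gray of
quantization to any pixel. Every generator output is a pure function of its
arguments and an explicit seed (the global RNG stream is untouched).

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real photographs: chromatic structure of the
Prussian-blue hue, illumination gradients and shadows, perspective, white
balance, coffee-ring radial profiles, paper texture, and humidity effects.
The pipeline's accuracy on real images is bounded below by these, not by the
statistics validated here.

## Problem sizes and runtime posture

The shipped tests and the acceptance script run simulations at the sizes the
study design uses: 200×200 px spot images with radius-60 discs; calibration
sets of 21 concentrations (0–1000 ppm, step 50) × 4 replicates over 20
seeds; kinetics series of 300 frames over 5–20 seeds; 6-point temperature
series. These sizes put every recovery claim (10% median concentration
error, 10% rate-constant error, ±10% saturation-point bias) well inside its
Monte-Carlo resolution while keeping a full run in tens of seconds.

## Known limitations

* Single spot per image; no multi-spot plates, no perspective or
  illumination correction, no colour-card white balancing.
* Calibration is unweighted; heteroscedastic weighting and formal LOD/LOQ
  are out of scope.
* The delta-method interval ignores between-spot variation.
* The temperature correction is additive and global; it does not model a
  temperature–concentration interaction.
* Kinetics assume a single dominant rate process; multi-step mechanisms and
  Arrhenius temperature dependence of $K$ are not modelled.
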