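---
title: "Methods: tomography-free bubble quantification in wet-embedded tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tomography-free bubble quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblometry)
```

## Scope and model

This package quantifies X-ray-induced gas bubble formation in soft tissue
embedded in liquid (70% ethanol in water, immobilized with crushed agar)
from time-resolved 2D radiographs, plus micro-gas-chromatograph (µGC)
traces recorded concurrently. The imaging model is a parallel beam through a
container of thickness $L$ along the beam; monochromatic-equivalent
attenuation at the mean beam energy (82 keV); and gas that displaces liquid.
The transmitted intensity of a frame is

$$ I = \mathrm{flat}(x,y,t)\, e^{-\tau(x,y)} + \mathrm{dark}, \qquad
   \tau = \tau_{\mathrm{bg}} - \mu_{\mathrm{liq}}\, t_{\mathrm{gas}}, $$

where $t_{\mathrm{gas}}$ is the beam-path length through gas. The analysis
chain inverts this: flat-field correction gives transmission $T$, optical
depth $\tau = -\ln T$, subtraction of a pre-onset context map
$\tau_{\mathrm{ref}}$ (per-pixel median over bubble-free frames) isolates
the bubble signal $\Delta\tau$, and Beer–Lambert inversion
$t_{\mathrm{gas}} = \Delta\tau / \mu_{\mathrm{liq}}$ summed over pixels
yields the in-field gas volume per frame. No phase retrieval is attempted:
propagation fringes are treated purely as a robustness hazard, and the
phantom can inject a Laplacian-shaped fringe surrogate to probe it.

Two assumptions deserve emphasis. First, depth: bubbles are placed at
mid-container depth with orthographic projection — absorption paths do not
depend on depth in a parallel beam, so this only matters for fringes, which
we do not invert. Second, $\mu_{\mathrm{liq}}$: the inversion constant is
the linear attenuation of the *displaced liquid*. The default,
$0.0158\ \mathrm{mm^{-1}}$, is derived by the elemental mixture rule from
NIST mass-attenuation coefficients of H, C, O log–log interpolated to
82 keV, for 70 vol% ethanol/water at density $0.868\ \mathrm{g\,cm^{-3}}$.
It is a named, overridable model input (`attenuation_model()`), not a fitted
quantity.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| pixel size | 25 | µm | detector geometry of the emulated setup |
| frame rate | 3 | s⁻¹ | acquisition rate of the emulated cineradiographs |
| container thickness | 70 | mm | slice diameter; beam path through liquid (assumption, configurable) |
| $\mu_{\mathrm{liq}}$ | 0.0158 | mm⁻¹ | mixture-rule derivation above |
| onset threshold | $5.24\times10^{-4}$ | mm³ | volume of a 100 µm sphere — a bubble at the resolution limit |
| onset persistence | 3 | frames | 1 s at 3 fps; rejects single-frame noise |
| noise floor | $3\hat\sigma$ | — | robust (MAD) sigma of smoothed pre-onset residuals |
| detection smoothing | 1.5 | px | suppresses pixel noise before thresholding |
| min component size | 25 | px | rejects smoothed-noise clusters in pipeline runs |
| fit window | 600 | s | the power law describes only early growth |
| top-edge exit margin | 10 | px | bubbles rise; only the top edge is an exit |
| circularity slope threshold $\varepsilon$ | $5\times10^{-3}$ | s⁻¹ | see below |
| dose rate | 36.8 | Gy s⁻¹ | measured beamline value for the emulated setup |
| specific heats | 4184 / 2440 | J kg⁻¹ K⁻¹ | standard room-temperature values (water / ethanol) |

## Volumetry: detection map versus integration aperture

Flooring the excess-depth map at $3\sigma$ and summing would lose the faint
silhouette rim (a sphere's chord goes to zero at its edge) and, conversely,
summing the unfloored map accumulates noise over the entire field of view.
The implementation therefore separates detection from integration: bubbles
are segmented on a smoothed, floored *detection* map, and the volume
integrates the *raw, signed* excess depth over the detected components
dilated by 3 px. Zero-mean noise cancels inside the aperture; the dilation
recovers the sub-floor rim. On rendered noiseless spheres this chain is
exact to machine precision; with noise, accuracy is limited by
threshold–noise correlation at the aperture boundary for marginally
resolved bubbles, which is why the ledger-comparison tests evaluate
cumulative volumes above ~1 mm³.

Negative excursions of $\Delta\tau$ (denser than reference) are clipped to
zero in the excess map — in this model gas can only reduce optical depth —
but kept (signed) in the integration aperture so that noise remains
zero-mean there.

## Onset, and why the growth fit uses the generator's onset

Onset detection automates the manual first-visible-bubble selection: the
earliest time the in-field volume exceeds the 100 µm-sphere threshold for
3 consecutive frames. On the degassed preset this trails the true
nucleation time by a few seconds (the test suite enforces ≤ 5 s), mirroring
the expected discrepancy between visible onset and true onset at finite
resolution.

For *exponent recovery on synthetic series*, however, the fit is anchored at
the generator's true onset rather than the detected one. An idealized pure
power law extends all the way to $V = 0$, so on log–log axes the earliest
samples carry large leverage; anchoring the fit a few seconds late biases
the recovered exponent downward by several tenths — an artifact of the
idealization, since a measured series has no usable samples below the
detection threshold anyway. Onset-detection accuracy is validated
separately; a `cofit_onset` flag in `fit_power_law()` frees $t_{bo}$ for
sensitivity analysis. Fitting defaults to log–log least squares (the
phantom's error model is multiplicative); a Levenberg–Marquardt fit on the
linear scale is available and agrees to 6 significant digits on exact data.

## Shape classification

Tracks are linked by maximal pixel overlap between consecutive frames (ties
break toward the lower track id), which is robust to deformation at 3 fps.
Classification proceeds in fixed order: stepped growth first (a
piecewise-constant fit from binary segmentation with ≥ 2 change-points must
beat a straight line's residual sum of squares by a factor of 2), then
vessel confinement (Theil–Sen circularity slope below $-\varepsilon$), then
unconstrained growth (median circularity above 0.85 with $|$slope$| <
\varepsilon$); anything else is reported `unclassified` rather than forced.

The slope threshold $\varepsilon$ must sit above a measurement artifact: the
perimeter estimator (8-connected chain length with the Kulpa correction
$\pi(1+\sqrt2)/8 \approx 0.948$) has a residual positive bias for small
rasterized disks that decays with size, so a *growing* circular bubble shows
a spurious downward circularity drift of order $10^{-3}\,\mathrm{s^{-1}}$ at
these growth rates. Genuine vessel confinement in the presets runs an order
of magnitude faster (~$2\times10^{-2}\,\mathrm{s^{-1}}$); the default
$\varepsilon = 5\times10^{-3}\,\mathrm{s^{-1}}$ separates the two. Shape
metrics are only trustworthy above a few hundred pixels of area; the disk
calibration tests pin the estimator to circularity $1.00 \pm 0.02$ at
radius 100 px and $0.841 \pm 0.02$ on a 2:1 ellipse against a numerical
elliptic-integral oracle.

## Flat-field correction

Two methods are provided. *Static* divides by the mean flat after mean-dark
subtraction. *Dynamic* tracks slow illumination drift: on bubble-free
lateral border strips, the static sample attenuation is removed as the
per-pixel time-median of the frame-to-mean-flat ratio, and the residual
per-frame variation is fitted as a non-negative combination of the recorded
flats' illumination patterns (non-negative least squares — equivalently,
non-negative loadings on the flats' principal components). The fit must not
be done on raw intensities: with the sample in the beam, that would absorb
the attenuation scale into the illumination estimate. The border region is
assumed sample-static and bubble-free; default static, since drift-free
sequences gain nothing from the extra fit.

## Chromatogram analysis

Baselines are estimated by morphological opening (rolling minimum then
rolling maximum, which removes peaks narrower than the window while
reproducing linear drifts exactly away from peak shoulders) followed by
rolling-mean smoothing. Peaks are local maxima above $5\sigma$ (noise from
the MAD of first differences) that also reach 5% of the tallest peak — the
relative-height filter rejects residual-baseline bumps that would otherwise
steal watershed boundaries or reference assignments. Each peak integrates
trapezoidally over its contiguous above-floor support, bounded at the
midpoint toward any adjacent apex (watershed), *above the chord* joining
its endpoints — the local linear baseline that absorbs whatever drift the
global correction missed. Areas are normalized within module and cycle;
the 2.4 min elution cycle is the native time resolution, so onset-aligned
summaries use nearest-cycle lookup within half a cycle, never
interpolation.

The window classification rule (increasing / decreasing / unchanged when
the post–pre mean difference exceeds the cycle-to-cycle sigma) is applied
per sample exactly as defined. Note a structural property: for a truly
unchanged species the difference of window means is itself of order sigma,
so the rule misclassifies a null species in roughly one sample in seven
regardless of the noise scale. The validation therefore asserts the *modal*
classification over a panel of nine simulated samples — the same logic as
reading the consistent behavior off a panel of experimental samples —
rather than demanding a single noisy sample classify perfectly.

## The phantom: what it emulates, and what it does not

The generator reproduces the statistical and geometric structure the
analysis assumes: Beer–Lambert absorption through a 70 mm liquid path with a
smooth agar/tissue context texture; flats with optional drift and darks
consistent with the correction model; multiplicative intensity noise
(default 2%); bubbles nucleating sequentially and growing by three laws
(square-root radial growth of free spheres; fixed-radius bidirectional
capsule elongation in a 100 µm vessel; sequential filling of tangent
125 µm-radius alveolar compartments with dwell times); scripted exits and
upward migration; and µGC cycles with Gaussian peaks, incoherent baseline
wander, and a solvent-fraction step at onset (EtOH up by 0.15 of the
solvent share, H₂O down). The macroscopic degassed preset generates
cumulative volumes $V_C = k\,t^3$ with $k = 6\times10^{-6}\ \mathrm{mm^3\,
s^{-3}}$ — about 1.3 cm³ of gas over the first 10 min, a plausible load for
a 50 × 4 mm field of view through a 70 mm container, and small enough that
the default onset rule trails the true onset by only a few seconds. The
non-degassed preset draws its exponent uniformly from [2.4, 3.0] per
sample, giving the sample-dependent spread the comparison statistic
(max − min per group) is designed to expose.

Deliberately *not* emulated: coherent propagation physics (fringes are a
Laplacian surrogate, default off), polychromatic beam hardening, detector
ring artifacts and distortion, bubble coalescence dynamics beyond
overlap-merge events, tissue deformation, and radiolysis chemistry beyond
the solvent-fraction bookkeeping. Passing tests on the phantom therefore
demonstrate correctness of the measurement chain under its stated model,
not robustness to every artifact of real beamline data.

## Numerical choices and degenerate inputs

Degenerate inputs have defined behavior rather than exceptions where the
spec of the analysis demands it: an all-zero volume series yields a
"no onset detected" result object; an empty excess-depth frame yields an
empty measurement table; a track shorter than 10 frames refuses
classification with an explicit error; a cycle with zero assigned peak area
is flagged and excluded from fractions; a non-converging nonlinear fit
falls back to log–log with a warning. Reproducibility is by explicit
seeding: every stochastic generator takes a seed and restores the caller's
RNG state, and the pipeline's report hash is a pure function of config plus
seed.

Validation problem sizes were chosen to keep the full suite fast while
staying in the regimes the estimators need: rendered stacks of 160–320 px
per side and 50–85 frames, 20 seeded runs per growth scenario, 50–200
replicates for exponent-recovery statistics, nine-sample GC panels. The
README shows a complete worked example with its actual output.

## Known limitations

* Absorption contrast of mm-scale gas paths is ~2%, comparable to typical
  intensity noise; bubbles much below ~0.3 mm path are invisible to this
  chain (the real experiments see them through phase contrast, which is out
  of scope). Volume accuracy for marginally resolved bubbles is biased by
  threshold–noise correlation, as quantified in the tests.
* $\mu_{\mathrm{liq}}$ assumes a fixed solvent composition; local tissue
  attenuation differences enter the context map but composition drift over
  a long scan does not.
* The dose model is a constant surface dose rate; depth-dependent
  deposition is not modeled, and the adiabatic $\Delta T$ is an upper
  bound, not a temperature estimate.
* Replication against the public experiment deposit requires a manual
  download and a user-written mapping file; only the mapping and error
  contracts are testable offline.
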