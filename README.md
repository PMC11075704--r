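# bubblometry

Quantification of X-ray-induced gas bubble formation in wet-embedded soft
tissue, from in-line phase-contrast cineradiographs and real-time micro-gas
chromatography — without tomography.

## The problem

Long synchrotron scans of tissue embedded in liquid (70% ethanol, immobilized
with crushed agar) eventually nucleate gas bubbles that ruin the images.
Quantifying when bubbles appear, how fast they grow, what shapes their
surroundings force on them, and what gas they contain tells you how much dose
a sample tolerates and how preparation (vacuum degassing) buys imaging time.
This package implements that analysis for radiograph sequences plus µGC
chromatograms, and ships a synthetic phantom with exported ground truth so
every stage is testable without beamtime.

## What it computes

* **Gas volumetry without tomography.** After flat-field correction, the
  optical depth of a frame is `τ = −ln T`. Subtracting the pre-onset
  agar/tissue context `τ_ref` leaves the bubble signal `Δτ = τ_ref − τ`,
  and direct inversion of the Beer–Lambert law turns it into gas path
  length, `t_gas = Δτ / μ_liq`, hence an in-field volume per frame:
  `V = Σ t_gas · p²` over pixels of size `p`. The default
  `μ_liq = 0.0158 mm⁻¹` is derived from NIST elemental mass-attenuation
  tables for 70 vol% ethanol/water at 82 keV and is overridable.
* **Onset and bookkeeping.** Bubble onset `t_bo` is the first time `V`
  exceeds the volume of a 100 µm sphere for 3 consecutive frames. The
  cumulative volume adds frozen volumes of bubbles that left the field of
  view: `V_C(t) = V(t) + Σ_{exits ≤ t} V_frozen`.
* **Growth kinetics.** The early cumulative growth is fit by a rect-windowed
  power law `V_C(t) = k (t − t_bo)^α` over the first 10 min after onset;
  the exponent α separates highly degassed (consistent α ≈ 3) from
  non-degassed samples (sample-dependent α).
* **Constrained growth.** Per-bubble tracks (overlap linking) are classified
  from circularity `4πA/C²` and area time series into unconstrained growth,
  vessel-confined elongation, or stepped alveolar filling.
* **Gas composition.** µGC chromatograms per 2.4 min elution cycle are
  baseline-corrected, peak-integrated, normalized per module/cycle, and
  summarized in windows around onset (EtOH rises, H₂O falls, N₂/O₂
  unchanged).
* **Dosimetry.** Cumulative surface dose `D = dose_rate · t_rad` (36.8 Gy/s
  default) and the adiabatic heating bound `ΔT = D / c_p` per solvent.

## Worked example

```r
library(bubblometry)

attenuation_model()
#> <attenuation_model> mu_liq = 0.01577 mm^-1 at 82 keV

# a synthetic highly-degassed cumulative volume series (2% noise, 3 fps)
vs <- simulate_volume_series("degassed", seed = 42)
detect_onset(vs)
#> <onset_estimate> t_bo = 64.33 s (t_bbo = 64.33 s)

fit_power_law(vs, attr(vs, "true_onset_s"))
#> <growth_fit> alpha = 2.984 +/- 0.003, k = 6.56e-06 mm^3 s^-alpha (loglog, n = 1797)

# dose and adiabatic heating after 21 min of irradiation
d <- cumulative_dose(21 * 60)   # 46368 Gy = 46.4 kGy
temperature_bound(d, "water")   # 11.1 C
temperature_bound(d, "ethanol") # 19.0 C
```

The detected onset trails the true onset (60 s here) by ~4 s — the time a
growing bubble needs to exceed the resolution-limit threshold. The fitted
exponent recovers the preset α = 3 from noisy data; the heating numbers are
upper bounds assuming no heat exchange.

A full end-to-end run (simulate → correct → segment → track → volumetry →
kinetics → report) from the bundled demo configuration:

```sh
Rscript inst/cli/bubblometry.R analyze \
  --config inst/extdata/demo_config.json --out /tmp/run --seed 5
```

which writes `onset.csv`, `growth_fit.csv`, `classifications.csv`,
`volumes.csv` and a `manifest.json` whose report hash is reproducible for a
given config and seed. `simulate` writes phantom stacks (16-bit TIFF, flats,
darks, timestamps, ground truth CSVs); `replicate` maps a user-downloaded
experiment deposit into the same pipeline via a mapping JSON (nothing is
downloaded automatically).

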