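# ctmaxslope

Maximum-slope CT perfusion, from the full dynamic curve or from just two
scan phases.

## The problem

Dynamic contrast-enhanced CT perfusion imaging quantifies organ blood flow
by scanning the same volume repeatedly during the transit of a contrast
bolus — typically dozens of frames, with the radiation dose and noise that
implies. The classical *maximum slope* method defines perfusion as

```
Perfusion = (maximum slope of the tissue time-enhancement curve)
            / (peak enhancement of the feeding vessel)
```

in mL/s per mL of tissue, with the abdominal aorta as the feeding vessel.
Measuring the maximal upslope normally requires the whole sampled curve.

This package implements an alternative that needs only **two CT scan
phases** — a pre-contrast baseline and a peak-enhancement scan — plus the
feeding-vessel peak and bolus shape. Both vessel and tissue enhancement
follow the Madsen form of the gamma-variate function,

```
y(t) = y_max * tau^alpha * exp(alpha * (1 - tau)),   tau = t / t_max,
```

where `y_max` is the peak enhancement above baseline (ΔHU), `t_max` the
time of the peak and `alpha` the bolus-shape parameter, conserved from the
arterial input into the tissue. The maximal upslope of such a curve is
available in closed form, `y_max * k(alpha) / t_max`, where the
dimensionless factor `k` is the first derivative evaluated at the ascending
inflection root `tau = (alpha - sqrt(alpha)) / alpha` and is nearly linear
in `alpha` over the clinical range 3–15: `k ≈ 1.502 + 0.092016 * alpha`.
So the two-phase perfusion estimate is

```
Perfusion = (peak_hu - baseline_hu) * k(alpha) / t_max
            / (peak feeding vessel enhancement)
```

with `alpha` taken from the aortic curve (or a bolus test) and `t_max` from
the scan timing. The same algebra yields two useful corollaries implemented
here: the predicted arterial-phase enhancement is a linear, origin-crossing
function of perfusion, and the perfusion ratio of two ROIs sharing a
feeding vessel equals their enhancement ratio, with no arterial input
needed at all.

The package is aimed at researchers in quantitative perfusion imaging: it
provides the closed-form model (`gv_enhancement()`, `gv_slope()`,
`k_exact()`, `k_linear()`), curve fitting from noisy sampled ROI curves
(`fit_gamma_variate()`, `fit_spline_max_slope()`, `fit_aortic_input()`),
both perfusion estimators (`perfusion_full_curve()`,
`perfusion_two_phase()`), method-comparison statistics
(`compare_methods()`: regression + Bland–Altman), a seeded synthetic-study
generator for validation (`study_config()`, `generate_study()`,
`recovery_experiment()`), and a command-line interface
(`inst/cli/ctmaxslope`).

## Worked example

A tissue ROI reads 40 HU on the baseline scan and 140 HU at its peak 35 s
after injection; the aortic peak is 350 ΔHU with bolus shape `alpha = 9`:

```r
library(ctmaxslope)
ao  <- aortic_input(peak_enhancement = 350, alpha = 9)
est <- perfusion_two_phase(baseline_hu = 40, peak_hu = 140, t_peak = 35, aorta = ao)
est
#> Perfusion: 1.141 mL/min/mL (0.01902 1/s) [gamma_two_phase]
#>   max slope 6.658 HU/s, aortic peak 350 dHU
```

The 100 ΔHU enhancement translates into 1.14 mL/min per mL of tissue — a
typical pancreatic perfusion. Inverting the same equation predicts the
enhancement a renal cortex at 2.5 mL/min/mL would show under this bolus:

```r
enhancement_from_perfusion(2.5 / 60, aortic_peak = 350, t_max = 35, alpha = 9)
#> [1] 219.0494
```

Validation against the classical full-curve method runs on synthetic
dynamic studies (40 frames every 1.5 s, aortic SNR ≈ 2.2, three organs
with known true perfusions):

```r
tab <- recovery_experiment(study_config(seed = 1), n_replicates = 11)
compare_methods(tab$spline_perfusion, tab$two_phase_perfusion)
#> Method comparison (n = 33):
#>   regression: y = 0.02678 + 0.9828 x,  r2 = 0.992, p = 4.75e-34
#>   Bland-Altman (y - x): bias 0.002463, LoA [-0.1431, 0.1481]
```

The two estimators agree to a slope near 1, negligible bias relative to
the 0.6–2.5 mL/min/mL range of true perfusions, and tight limits of
agreement.

The same operations are available from a shell:

```sh
Rscript inst/cli/ctmaxslope two-phase 40 140 35 --aortic-peak 350 --alpha 9
Rscript inst/cli/ctmaxslope simulate --out-dir study1 --seed 7
Rscript inst/cli/ctmaxslope fit-aorta study1/aorta.csv
```

See `vignettes/two-phase-ct-perfusion.Rmd` for the full account of the
model, the estimators and the synthetic validation design.

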