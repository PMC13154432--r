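# phloempet

Quantifying phloem transport in thin plant shoots from dynamic
carbon-11 PET.

Phloem — the pressurized sugar-transport tissue of vascular plants —
is nearly inaccessible to direct measurement, especially in
small-diameter model plants such as *Arabidopsis thaliana*. Dynamic
PET after pulse labelling with ¹¹CO₂ yields time-activity curves
(TACs): the decay-corrected mean ¹¹C concentration (MBq/mL) per 5-min
frame in consecutive cylindrical regions of interest (ROIs) along a
shoot. This package turns such TACs into estimates of the phloem front
speed and the radial partitioning of recently fixed carbon, for plant
physiologists working with (or planning) plant-PET acquisitions and
for methodologists who want a fully testable reference implementation
of the analysis.

## The model

Each ROI *i* of length *l* holds three compartments; a set of four
consecutive ROIs (input + 3) is fitted jointly:

    dT¹ᵢ/dt = (s_Ph/l)·T¹ᵢ₋₁ − (s_Ph/l)·T¹ᵢ − a₁₂·T¹ᵢ + h·a₁₂·T²ᵢ
    dT²ᵢ/dt = a₁₂·T¹ᵢ − (h·a₁₂ + b + c)·T²ᵢ
    dT³ᵢ/dt = b·T²ᵢ

with T¹ the sieve tubes (plug-flow advection at front speed `s_Ph`,
µm/s), T² the phloem parenchyma (unloading `a12`, retrieval
`a21 = h·a12` with coupling constant `h = 0.68759`), T³ irreversible
storage (`b`), and respiratory efflux to the atmosphere (`c`).
Exchange fraction rates are per minute. The input ROI is closed
against its measured total, `T¹ = T_tot − T² − T³` (floored at zero),
and the observable per ROI is the total `T¹+T²+T³` averaged over each
frame. Parameters are estimated by minimizing the RMSE between
simulated and measured TACs of ROIs 1–3 with a from-scratch shuffled
complex evolution (SCE-UA) global optimizer; identifiability is
certified with the collinearity index
`γ = 1/√λ_min` of the unit-normalized sensitivity matrix (threshold
15). A Monte-Carlo module computes the probability that positrons born
in the near-surface phloem of a sub-2-mm stem annihilate inside it —
the physical premise of the measurement.

## Worked example

```r
library(phloempet)

truth   <- model_parameters(s_ph = 128, a12 = 0.27, b = 0.08, c = 0.38)
roi_set <- generate_roi_set(synthetic_config(params = truth, noise_cv = 0))
fit     <- calibrate(roi_set$noiseless, roi_geometry(),
                     calibration_config(seed = 1))
fit
#> Calibration by shuffled complex evolution (converged after 3116 evaluations, 104 shuffles)
#>   RMSE: 7.39053e-06 MBq/mL   free: s_ph, a12, b, c   seed: 1
#> Four-compartment phloem transport parameters
#>   s_ph :  127.266 um/s  (phloem front speed)
#>   a12  :   0.2655 1/min (unloading)
#>   a21  :   0.1826 1/min (retrieval = h * a12)
#>   b    :   0.0816 1/min (storage)
#>   c    :   0.3885 1/min (efflux)
#>   h    :  0.68759       (coupling constant)

report <- assess_identifiability(fit$params, roi_geometry(), roi_set$noiseless)
report[report$size == 4, ]
#>        subset size    gamma identifiable
#>  s_ph,a12,b,c    4 11.17384         TRUE

annihilation_probability(stem_cylinder(1.5), n_samples = 1e6, seed = 7)
#> In-stem annihilation, d = 1.5 mm (n = 1000000):
#>   P_annihilation: 71.3%  (mean capped travel 0.876 mm)
#>   direct per-positron fraction: 61.9% (SE 0.05)
```

The fit recovers the generating parameters to well under 1 % here
(noiseless data): a 128 µm/s front speed, strong unloading partly
retrieved (`a21/a12 = h`), little storage, substantial efflux. The
collinearity index of the full four-parameter set (11.2, below the
threshold of 15) certifies the set as locally identifiable on the
state surface; under realistic 5 % measurement noise the
data-visible surface supports `s_Ph` to ~10 % but the exchange rates
only to within factors of ~2 — see the vignette for the error
analysis. The annihilation estimate says that ~71 % of positrons born
in the phloem of a 1.5-mm stem annihilate inside it, so the PET
signal is dominated by in-stem events.

## Analysis workflow

The `analysis/` directory holds the end-to-end study as numbered
drivers, writing everything under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_cohort.R` | 16 synthetic ROI sets (4 plants × primary/secondary) at 5 % noise, with ground-truth sidecars |
| `02_fit_roi_sets.R`    | one SCE-UA calibration per set + recovery table against the truths |
| `03_identifiability.R` | collinearity-index summary across fits |
| `04_positron_physics.R`| annihilation probability over a stem-diameter grid |
| `05_summaries.R`       | parameter means ± SE by shoot class, correlations with shoot position |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cohort.R`.

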