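# petkin

Tracer kinetic quantification for dynamic brain PET with a reversibly
binding radioligand.

First-in-human PET evaluations of a new radioligand must establish
whether its binding can be quantified reliably: from dynamic scans with
arterial blood sampling they estimate the **total distribution volume**

> V<sub>T</sub> = V<sub>ND</sub> + V<sub>S</sub> = (K₁/k₂)(1 + k₃/k₄)

per brain region with compartment models and graphical analyses, and the
**non-displaceable binding potential**

> BP<sub>ND</sub> = V<sub>T</sub>(target) / V<sub>T</sub>(reference) − 1

with blood-free reference-tissue and SUVR methods, then ask whether the
simpler methods agree with the gold standard. `petkin` implements that
whole chain for kinetic modellers and methods researchers:

* **Input functions** — blood/HPLC table IO, Hill / power / interpolated
  parent-fraction fits, metabolite correction, a continuous
  piecewise-linear C<sub>p</sub>(t) with exact integrals and optional
  mono-exponential tail extrapolation.
* **Compartment models** — analytic 1TCM/2TCM forward model (exponential
  convolution, no ODE quadrature error), weighted multi-start NLS with a
  fixed 5% blood volume, percent-SE identifiability from the fit
  covariance (delta method for V<sub>T</sub>).
* **Graphical analyses** — Logan plot and MA1 beyond t\* = 20 min, with
  vascular correction and t\*-sensitivity tables.
* **Reference/SUVR methods** — MRTM<sub>O</sub> at ROI and voxel level
  (parametric BP<sub>ND</sub> maps, NIfTI in/out), indirect
  BP<sub>ND</sub> from V<sub>T</sub> ratios, SUVR−1 over 40–60 … 70–90
  min windows, regression + Bland–Altman method comparison.
* **Model selection & stability** — least-squares AIC, weighted MSC,
  nested F test, scan truncation 90 → 40 min, CV summaries.
* **Synthetic subjects** — a seeded generator with 15 regions of known
  ground truth (V<sub>T</sub> 2.7–4.2, BP<sub>ND</sub> 0.07–0.56,
  cerebellar cortex as the k₃ = 0 reference), realistic plasma/metabolite
  curves, frame-duration-dependent noise, optional 4D labelled volumes
  and cohorts — so every estimator is validated by parameter recovery.

See `vignettes/tracer-kinetics.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

Simulate a subject (noisy TACs, blood and HPLC tables), rebuild the
input function from its blood data, and quantify the pallidum:

```r
library(petkin)

subj <- simulate_subject(noise_scale = 0.1, seed = 42)
pf   <- fit_parent_fraction(subj$hplc, "hill")
inf  <- build_input_function(metabolite_correct(subj$blood, pf))

fit_parent_fraction(subj$hplc, "hill")
#> Parent-fraction curve (hill); f(90 min) = 0.550
inf
#> Input function: 30 samples to 90.0 min, peak Cp 162 kBq/mL (linear)

fit_compartment(subj$tacs$pallidum, inf, "2tcm")
#> 2TCM fit: VT = 4.169 mL/cm^3 (SE 0.21%), SSR = 0.5234, converged
#>    K1 = 0.3162, k2 = 0.1203, k3 = 0.0318, k4 = 0.0542

logan_vt(subj$tacs$pallidum, inf)
#> LOGAN fit: VT = 4.177 mL/cm^3 (t* = 20 min, 14 points, R2 = 0.9999)

mrtmo_fit(subj$tacs$pallidum, subj$tacs$cerebellar_cortex)
#> MRTMo fit: BPND = 0.5518 (t* = 20 min, 14 points, R2 = 0.99997)
```

The generating truth for this region is V<sub>T</sub> = 4.2 and
BP<sub>ND</sub> = 4.2/2.7 − 1 ≈ 0.556: the 2TCM recovers V<sub>T</sub>
to 0.7% under noise with sub-percent identifiability, the Logan slope
agrees with it, and the blood-free MRTM<sub>O</sub> lands within 1% of
the true binding potential. `run_full_pipeline(run_config(seed = 1))`
chains every stage (simulation → input function → all estimators →
comparison, stability and selection tables) into one deterministic
report; `write_study_report()` serialises it as CSV + JSON.

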