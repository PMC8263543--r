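---
title: "Quantifying reversible radioligand binding with petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reversible radioligand binding with petkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The quantification problem

Dynamic brain PET with a reversibly binding radioligand measures, frame by
frame, the total radioactivity concentration in tissue. That signal mixes
free, non-specifically bound and specifically bound ligand, plus a
vascular contribution. The quantities of scientific interest are

* **V~T~**, the total distribution volume — the equilibrium tissue-to-plasma
  concentration ratio, the sum of a non-displaceable part
  (V~ND~ = K~1~/k~2~) and a specific part (V~S~ = K~1~k~3~/(k~2~k~4~)); and
* **BP~ND~**, the non-displaceable binding potential,
  BP~ND~ = V~T~(target)/V~T~(reference) − 1, with a reference region
  devoid of specific binding (here the cerebellar cortex).

`petkin` implements the full estimation chain used in first-in-human
evaluations of such ligands: arterial input-function construction with
metabolite correction, one- and two-tissue compartment modelling (1TCM /
2TCM), Logan and MA1 graphical analyses, the original multilinear
reference tissue model (MRTM~O~), SUVR windows, model-selection statistics
(AIC, MSC, F test), scan-truncation stability analysis, and voxelwise
parametric BP~ND~ mapping — together with a fully seeded synthetic-subject
generator so that every estimator can be validated by parameter recovery
without any patient data.

## Models

### Compartment models

The tissue kinetics follow the standard catenary system driven by the
metabolite-corrected plasma concentration C~p~(t):

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1 + k_4 C_2, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

with C~2~ ≡ 0 for the 1TCM. The measured concentration adds a fixed
fractional blood volume V~b~ applied to whole blood:
C~model~ = (1 − V~b~)(C~1~ + C~2~) + V~b~C~b~. V~b~ is held at 0.05
throughout and is not fitted. The solver is analytic: the impulse
response of C~1~ + C~2~ is a sum of two exponentials whose convolution
with the piecewise-linear C~p~ has a closed form per segment, accumulated
by an exact recursion. Repeated eigenvalues (discriminant ≈ 0) are
handled by a tiny perturbation; the solver never returns NaN. A
fine-grid Runge–Kutta integration of the same ODEs (via deSolve) serves
as the independent oracle in the test suite and agrees with the analytic
path to ~10^−13^ relative — far below the 0.1% the tests assert.

Because frames are up to 5 minutes long, model predictions are **frame
averages** (trapezoid over ≥ 10 sub-samples per frame), not midpoint
samples. Fits are weighted nonlinear least squares (minpack.lm) on
(K~1~, k~2~) or (K~1~, k~2~, k~3~, k~4~), bounds (10^−6^, 10) on all
rates, default inits (0.2, 0.1, 0.05, 0.05), and 5 seeded multi-starts
(the extra starts are log-normal jitters of the init; the lowest weighted
SSR wins). Multi-starts matter in one identifiable corner: fitting a
2TCM to a region whose true k~3~ is 0 has an SSR-flat ridge in k~3~/k~4~
on which a single start can strand with a misleading V~T~.

Parameter precision is reported as percent standard errors from the
covariance SSR~w~/(n − p) · (JᵀWJ)^−1^ at the optimum; the V~T~ SE uses
the delta method. The weighting default is `duration` (w~i~ ∝ Δt~i~,
normalised to mean 1); `uniform` and `duration_decay` (which additionally
undoes the decay-correction amplification of late-frame variance,
λ = ln2 / 20.4 min for carbon-11) are available.

### Graphical analyses

The Logan plot regresses ∫₀^t^C~T~/C~T~(t) on ∫₀^t^C~p~/C~T~(t) for
frames with mid-time beyond the equilibrium time t\*; the slope is V~T~.
MA1 is the multilinear rearrangement with the noisy term moved to the
response, C~T~(t) = −(V~T~/b)∫C~p~ + (1/b)∫C~T~, which reduces the
noise-induced underestimation Logan is known for. Both use t\* = 1200 s
(20 min) as a global default, selected frames by mid-time strictly
greater than t\*, the exact piecewise-linear plasma integral, and the
frame trapezoid for the tissue integral. Because V~b~ is fixed and known
in this protocol, both estimators first remove the vascular signal,
(C~measured~ − V~b~C~b~)/(1 − V~b~), so their estimand is the tissue
V~T~ rather than a blood-contaminated mixture (with a 5% blood volume the
contamination would otherwise bias V~T~ by about −3%).
`tstar_sensitivity()` re-estimates V~T~ over a t\* grid (default 20–60
min) and reports the maximal relative spread.

### Reference-tissue and SUVR methods

MRTM~O~ estimates BP~ND~ without blood data by OLS on

$$\int_0^t C_T = \gamma_1 \int_0^t C_{ref} + \gamma_2\,C_{ref}(t)
  + \gamma_3\,C_T(t), \qquad t > t^*,$$

where γ~1~ is the distribution-volume ratio, so BP~ND~ = γ~1~ − 1. The
voxelwise variant reuses the reference-side design columns across all
voxels. A degenerate design (a voxel identical to the reference) is
solved by the pivoted least-squares solution with aliased coefficients
zeroed, accepted only when it reproduces the data — this returns the
admissible BP~ND~ = 0 instead of failing. Known behaviour reproduced by
the tests: MRTM~O~ has a negative noise-induced bias, small when BP~ND~
is small (< 1).

SUVR − 1 is computed from duration-weighted window means (frames
partially overlapping a window count in proportion to the overlap; on the
default schedule the four windows 40–60, 50–70, 60–80, 70–90 min align
exactly with frame boundaries, so the policies coincide), normalised to
the cerebellar cortex. Negative BP~ND~ estimates are reported, never
clipped.

### Model selection and stability

AIC uses the least-squares form n·ln(SSR/n) + 2k (an AICc term is
available behind a flag); only differences are meaningful, so absolute
values are not comparable across weighting conventions. MSC uses the
weighted form ln(SST~w~/SSR~w~) − 2k/n, invariant to weight rescaling.
The F test compares the nested weighted fits with α = 0.05. Scan
truncation keeps frames whose **end** time fits within each duration
(default 90 down to 40 min in 10-min steps) and reports V~T~, its SE%,
and the ratio to the full-length estimate.

## The synthetic study

No public data accompany the study this package emulates, so the
generator is a first-class, tested module. It emulates:

* a **33-frame, 90-min acquisition** (10 s × 6, 20 s × 3, 1 min × 6,
  3 min × 4, 5 min × 14);
* an arterial plasma curve of the Feng bolus form
  (A~1~(t−τ) − A~2~ − A~3~)e^λ1(t−τ)^ + A~2~e^λ2(t−τ)^ + A~3~e^λ3(t−τ)^,
  sampled on the study's schedule (10-s intervals to 2 min, 30-s to
  3 min, 1-min to 10 min, sparse to 90 min);
* a Hill-type parent fraction with plateau 0.5, reaching 0.55 at 90 min
  (slow metabolism: more than half the plasma activity is still parent at
  scan end), with the metabolite signal split between two hydrophilic
  radiometabolites (carried in the HPLC table only);
* **15 brain regions** whose ground-truth V~T~ spans 2.7 (cerebellar
  cortex, generated with k~3~ = 0 as a pure non-displaceable reference)
  to 4.2 (pallidum). All regions share K~1~ = 0.30 mL·cm^−3^·min^−1^,
  k~2~ = K~1~/2.7 and k~4~ = 0.05 min^−1^; k~3~ is set per region to hit
  the V~T~ target. Only the macro-parameters are constrained by the
  emulated study; the shared micro-parameters are a modelling choice that
  makes BP~ND~ differences purely k~3~-driven;
* frame-duration-dependent Gaussian noise,
  SD = scale·√(C(t~mid~)·e^λt~mid~^/Δt) with λ = ln2/20.4 min — the
  decay-correction factor restores counted-activity statistics, so late
  short-count frames are noisiest. The default scale 0.1 gives ~0.5%
  relative noise at the peak and ~2% in late frames, typical of regional
  TACs from a modern scanner. True Poisson sinogram noise, scanner
  resolution, partial-volume effects and motion are out of scope;
* optionally, a small labelled 4D volume (one voxel block per region,
  each voxel an independent noise realisation) for the parametric-mapping
  path, and a cohort mode with a lognormal between-subject V~T~ spread
  (default CV 10%).

The plasma-shape defaults deserve a note, since the emulated study
publishes only figures, not curves. Amplitudes are set so tissue peaks
land at SUV ≈ 6–7 (the study reports 4–8) for 350 MBq into 70 kg. The
washout is two-phase over the scan: an intermediate clearance phase
(half-time ≈ 4 min) essentially finished by 20 min, then an hours-scale
tail. This calibration reproduces two behaviours the study reports as
findings, which the generator must emulate to be a faithful test bed:
graphical plots become linear beyond t\* = 20 min (with the default
kinetics the slowest equilibration eigenvalue is 0.036 min^−1^, so a
plasma curve still falling quickly at 20–40 min would leave the pallidum
visibly un-equilibrated and bias Logan/MA1 by ~−2%), and late-window
uptake ratios approach the distribution-volume ratio **from above**, so
the across-region SUVR−1 slope declines monotonically from the 40–60 to
the 70–90 min window (≈1.32 → 1.23 here). What passing these synthetic
tests does **not** show: robustness to dispersion/delay errors in real
arterial data, to reference-region specific binding, or to
reconstruction artefacts — none of which the generator simulates.

Determinism is a contract: a subject regenerated from the same seed and
configuration is bit-identical, per-stage seeds are derived stably from
the master seed, and the full pipeline writes byte-identical reports on
reruns (no timestamps in any output).

## Numerical choices and edge cases

* Time is seconds internally; rate constants are reported in min^−1^ and
  V~T~ in mL·cm^−3^ at every interface.
* All activities are assumed decay-corrected to injection time; the
  package never applies decay correction except inside the synthetic
  noise model.
* The input function is anchored at (0, 0) even when the first sample is
  late; evaluation beyond the last sample is constant (with a warning)
  unless the `loglinear_tail` mono-exponential extrapolation is chosen.
  Negative corrected activities are clipped to zero with a warning. A
  constant appearance-delay parameter exists for sensitivity studies but
  defaults to 0; dispersion correction is deliberately not applied.
* Parent-fraction fits fall back to monotone-safe clipped interpolation
  whenever a parametric fit leaves [0, 1], keeping the pipeline total.
* ROI means are unweighted voxel averages (uniform voxel size).
* Exact fits produce AIC −∞ / MSC +∞ sentinels flagged `exact_fit`; an
  F test whose "complex" SSR exceeds the simple one (optimizer noise) is
  clipped to F = 0, p = 1 with a warning.
* Non-convergent compartment fits return `converged = FALSE` with
  infinite SE% rather than raising.

## Problem sizes used in the validation suite

The test suite and the acceptance script regenerate everything from
seeds: 15-region noise-free recovery for every estimator; 20 random
parameter draws for the analytic-vs-RK4 oracle; 50 noisy replicates for
the model-selection rates; 100 replicates for the Logan/MA1 and MRTM~O~
noise-bias directions; 12 replicates for the truncation variability
comparison; and an 8×8×4 volume for the parametric/ROI concordance.
These sizes were chosen so the entire suite validates every claim in a
few minutes on one CPU while keeping Monte-Carlo margins comfortable.

## Known limitations

* MRTM~O~ is the only reference-tissue model shipped (no MRTM/MRTM2/SRTM,
  no k~2~′ estimation); irreversible (k~4~ = 0) plasma-input models and
  basis-function/spectral methods are out of scope.
* The graphical estimators fix t\* globally rather than searching per
  region, mirroring the emulated protocol.
* The %SE of V~T~ uses the delta method, not profile likelihood.
* Image-derived input functions, dispersion deconvolution and
  dual-metabolite kinetics are not implemented.
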