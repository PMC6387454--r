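---
title: "Quantitative relaxometry for USPIO uptake: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative relaxometry for USPIO uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrelax)
```

## The measurement problem

Iron-oxide nanoparticle (USPIO) contrast agents shorten T1, T2 and T2\*.
After infusion, the relaxation-rate changes in brain tissue are small
(ΔR1 of order 0.03–0.08 s⁻¹, ΔR2\* of a few s⁻¹) while venous blood R1
rises roughly eight-fold. Quantifying uptake therefore requires R1 and
R2\* maps that are accurate and stable *between examinations*, and a
normalisation that removes between-subject and between-visit variation in
blood-pool concentration. `qrelax` implements that chain: forward signal
models, voxelwise fitters, ROI aggregation, blood-normalised metrics, and
cohort statistics, together with a synthetic-data layer that makes every
stage testable.

## Signal models

All sequences are parameterised by a `seq_params` record (times in
seconds, flip angles in degrees). The bundled `study_3t` preset encodes a
3-T protocol: two IR-sGRE scans (TR/TI = 1190/1000 and 632/450 ms, flip
5°, echo spacing τ = 4.5 ms, N = 80 readout pulses), three sGRE scans
(TR 5.7 ms, flips 12/5/3°), an 8-echo ME-sGRE scan (TE 4.6–41.5 ms) and a
five-point IR-SE gold-standard series (TR 1550 ms, TI 30–1530 ms).

**sGRE** uses the spoiled-GRE steady state
$S = s_0\,\frac{1-E}{1-E\cos k\beta}\sin k\beta$, $E = e^{-R_1 TR}$,
neglecting T2\* decay at the 2.5 ms echo time.

**IR-sGRE** is modelled three ways:

* `irsgre_signal_simplified()` assumes the low-angle readout train does
  not perturb the recovery and that inversion is complete.
* `irsgre_signal_brix()` computes the exact periodic steady state of the
  pulse train. Because the between-pulse map
  $m \mapsto (1-E_\tau) + \cos(k\beta)E_\tau\,m$ is affine, its N-fold
  composition and the cycle-closure condition have a closed-form
  geometric-series solution; a brute-force fixed-point iteration of the
  same cycle is kept in the test suite as an independent oracle and agrees
  to 10⁻¹⁰ relative.
* `irsgre_signal_deichmann()` treats the train as continuous relaxation
  with effective rate $R_1^* = R_1 - \ln(\cos k\beta)/\tau$ toward an
  effective equilibrium $M_0^* = (1-E_\tau)/(1-\cos(k\beta)E_\tau)$, with
  free recovery before and after the train. At the preset parameters it
  agrees with the pulse-by-pulse model to better than 0.004% of $s_0$
  over R1 ∈ [0.1, 6] s⁻¹, and it reduces exactly to the simplified model
  as β → 0.

### Timing conventions

TI is interpreted as the *effective* inversion time — inversion pulse to
the excitation acquiring the central k-space line, taken at the train
midpoint (`readout_index = ceiling(N/2)`) because slice-direction k-space
is sampled linearly in one train. This is not merely a convention choice:
with TR 1190 ms, TI 1000 ms and an 80-pulse train at 4.5 ms spacing, a
"TI to first pulse" reading would place the train end at 1355 ms, outside
the TR cycle, so the midpoint reading is the only geometrically consistent
one; `seq_params()` rejects inconsistent combinations and exposes
`readout_index` for other dialects. The train length N = 80 derives from
72 slices × 1.111 slice oversampling, and is overridable. Residual dead
time within the cycle is placed after the train.

### Where the simplified model fails

The simplified and pulse-by-pulse predictions differ by < 0.25% of $s_0$
at tissue-like R1 (≈ 1.1 s⁻¹) but by ≈ 0.8% at post-contrast blood R1
(≈ 4.7 s⁻¹); the induced error in fitted R1 grows monotonically from
−0.14 to −0.44 s⁻¹ as true R1 goes from 2 to 6 s⁻¹. Note that the raw
*signal* difference is not monotone over that range — both models
saturate toward $s_0 \sin\beta$ as recovery completes within TI, so the
signal gap peaks near R1 ≈ 3.9 s⁻¹ and then shrinks — while the
*parameter* error keeps growing; assessments of model adequacy here are
therefore made on fitted R1, not on raw signals. This is why the
effective-relaxation (Deichmann) model is the default for fitting.

## Fitting

`fit_despot1_hifi()` minimises the sum of squared differences between the
measured sGRE + IR-sGRE signals and the forward model over (s₀, R₁, k),
all constrained positive, using Levenberg–Marquardt with box constraints
(`minpack.lm`). Initialisation is deterministic: s₀ from the largest
signal divided by sin β at k = 1, R₁ = 1 s⁻¹, k = 1; if the first start
does not converge, a fixed fallback grid R₁ ∈ {0.3, 1, 3} s⁻¹ is tried
and the best SSE kept. Convergence is declared at relative SSE change
< 10⁻¹⁰ or 500 iterations. There is no randomness anywhere in fitting.

`fit_vfa()` is the standard linearised DESPOT1 regression of S/sin β on
S/tan β with k ≡ 1, polished by a nonlinear refinement; it exists to
quantify the bias the joint fit removes.

`fit_r2star()` fits the mono-exponential decay unconstrained (negative
estimates are legal and diagnostic). Points below
`noise_floor_factor × noise_sigma` (default 3σ, with σ supplied or
estimated from a background region) are excluded; voxels with fewer than
`min_echoes` (default 3) surviving points are flagged not-fit and carry
the `NA` sentinel in maps rather than raising. The default estimator is
nonlinear least squares on magnitudes; a weighted log-linear fast mode is
available. Noise-floor exclusion matters only where the decay actually
reaches the floor within the echo train: at SNR 30 the crossover is
around R2\* ≈ 130 s⁻¹ with these echo times, so the package's
demonstrations use an iron-rich 150 s⁻¹ decay, where exclusion reduces
the mean bias by about a third.

`fit_irse()` restores the polarity of magnitude IR-SE data exhaustively:
every sign assignment consistent with a single zero-crossing along
increasing TI is fitted and the best SSE kept, so no polarity heuristic
can fail silently.

`fit_volume()` applies per-stack intensity-scale correction (each
`image_stack` records the scanner scale factor), runs the chosen fitter
inside a mask, and writes `NA` sentinels elsewhere. Registration and
brain extraction are out of scope; volumes must already be congruent, and
`check_congruent()` enforces matching grids/affines rather than
resampling.

## Synthetic data

`build_phantom()` rasterises geometric compartments onto a voxel grid.
The `nine_syringe` preset arranges nine cylinders (R1 0.3–4.5 s⁻¹,
linearly spaced — white matter through post-USPIO venous blood) in a
short-T1 loading background. The physical phantom it emulates specifies
MnCl₂ concentrations, but without a relaxivity those do not convert to
rates, so the preset prescribes R1 directly; the background value
(2.0 s⁻¹, a doped-water loading solution) is likewise synthetic. The
flip-angle-scale field k(x, y, z) is a second-order in-plane polynomial
(default: centre ≈ 1.1 falling parabolically) times a cosine slab-profile
taper in z — the two features visible in measured k maps from
slab-selective 3-D acquisitions; coefficients are configurable and must
keep k > 0.

`simulate_acquisition()` applies the matching forward model (Brix for
IR-sGRE, by default) and adds seeded Gaussian or Rician noise; Rician is
the default since magnitude reconstruction is what produces the noise
floor the R2\* fitter must handle. Noise can be given as an absolute σ or
as a per-acquisition SNR (`noise_snr`), in which case
σ = mean(noiseless signal)/SNR per stack — mirroring per-stack receiver
scaling, which the pipeline corrects anyway. Fixed seeds give
bit-identical volumes.

`simulate_uspio_cohort()` draws per-subject baselines, blood ΔR₁ values
and CBV fractions from between-subject distributions and propagates them
through a purely intravascular generative model,
R₁(t) = R₁,base + CBV·ΔR₁,blood(t) + u(t), with the R2\* change
proportional (ρ, default 100) to the same intravascular driver.
Defaults encode a small-vessel-disease-like cohort of 12 subjects: blood
ΔR₁ of 3.146 s⁻¹ immediately after a one-third dose and 4.139 s⁻¹ at
24 h, complete elimination at one month, CBV 0.008 (WM), 0.024 (GM),
0.015 (WMH), 0.0125 (stroke lesion), 20% between-subject CBV variation,
and measurement noise of 0.01 s⁻¹ (R1) / 0.3 s⁻¹ (R2\*) on ROI medians.
Parenchymal uptake u(t), if prescribed, applies from 24 h onward (cell
uptake and barrier leak develop over hours) and is eliminated by one
month. With u = 0 the blood-normalised R1 change equals CBV at *every*
post-infusion timepoint — the null pattern against which parenchymal
uptake is detected. Blood rows never carry R2\* (venous R2\* is
spatially heterogeneous and unusable for normalisation), and R1 is not
generated at one month, matching the measurement schedule the table
mirrors.

What the generator does *not* emulate: partial-volume mixing, flow and
in-flow enhancement in the sagittal sinus, vessel-orientation-dependent
susceptibility effects, imperfect inversion, slice-profile effects,
motion, and registration error. Passing tests therefore validate the
estimators and the inference chain under the stated noise models, not
robustness to those acquisition artefacts.

## Statistics

`cohort_stats()` reports two-sided paired t-tests against baseline and
between post-infusion timepoints, per-region regression of ΔR₂\* on ΔR₁
with Pearson correlation, coefficients of variation of the normalised
changes, and all pairwise between-tissue comparisons. No multiple-testing
correction is applied — raw p-values against a plain 0.05 threshold —
and subjects with missing rows are dropped pairwise, never imputed. The
coefficient of variation uses the population (1/n) standard deviation,
so CoV({1, 2, 3}) = 40.8%. The degenerate paired case (zero-variance
differences) returns t = 0, p = 1 rather than erroring. No automatic
outlier exclusion is performed; per-ROI distributions are reported for
manual review.

## Numerical choices and problem sizes

Validation computations are sized for a desk machine: the model-agreement
sweep uses 591 R1 points; noiseless recovery a 4 × 3 parameter grid; the
noise-floor experiment 1000 simulated voxels; the cohort null 100
replicates of 12 subjects; and the end-to-end phantom a 24 × 24 × 8 grid
(≈ 1500 in-compartment voxels), where HIFI and gold-standard IR-SE
compartment means agree within ≈ 2 pooled standard errors at SNR 50.
Because that comparison takes a maximum over nine compartments of a
noisy statistic with a small residual systematic (Rician floor near the
IR-SE null crossing, plus the 0.004%-of-s₀ Deichmann–Brix gap), values
slightly above 3 pooled SE can occur at some seeds; the distribution,
not a single draw, is the meaningful summary.

Known limitations: R1 fitting assumes perfect spoiling and complete
inversion; R2\* fitting ignores macroscopic B0 gradients; the Deichmann
transcription is validated against the Brix oracle rather than an
external reference; and blood R2\* is deliberately never used for
normalisation.
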