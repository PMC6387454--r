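# qrelax — quantitative MRI relaxometry for USPIO uptake mapping

`qrelax` measures the uptake of ultrasmall superparamagnetic iron-oxide
(USPIO) contrast agents in the brain from quantitative MRI relaxation-rate
maps. USPIO particles shorten T1, T2 and T2\*, so the longitudinal and
effective transverse rates R1 = 1/T1 and R2\* = 1/T2\* (both in s⁻¹) rise in
proportion to local contrast concentration. Measured before and after
infusion, and normalised to the R1 change in venous blood, these changes
quantify the blood pool of each tissue — and, at later timepoints, any
parenchymal uptake by inflammatory cells or blood–brain-barrier leak. The
package is aimed at quantitative-imaging researchers who need a fully
scriptable, testable pipeline from raw sequence volumes to cohort
statistics, plus a digital phantom to validate every stage without scanner
time.

## What it computes

**B1-insensitive R1 mapping (DESPOT1-HIFI).** Volumetric R1 mapping from
variable-flip-angle spoiled gradient-echo (sGRE) data is biased at 3 T by
flip-angle (B1) inhomogeneity. `fit_despot1_hifi()` therefore jointly
estimates, per voxel, the signal scale *s₀*, *R₁* and the flip-angle scale
*k* (actual/nominal) from multi-flip sGRE plus inversion-recovery-prepared
sGRE (IR-sGRE) acquisitions, by constrained least squares. Three IR-sGRE
forward models are provided:

- *simplified*: S = s₀ (1 − 2e^(−R₁·TI_eff) + e^(−R₁·TR)) / (1 + e^(−R₁·TR)) · sin(kβ),
  assuming the readout train does not perturb the recovery;
- *Brix*: the exact pulse-by-pulse periodic steady state of the N-pulse
  readout train (closed-form geometric series);
- *Deichmann*: a closed-form effective-relaxation approximation
  (R₁\* = R₁ − ln cos(kβ)/τ) that tracks the Brix model to within 0.004% of
  s₀ across R1 = 0.1–6 s⁻¹ at the bundled protocol settings.

The simplified model is adequate for tissue R1 but fails at post-contrast
blood R1 (≈ 4–5 s⁻¹); the package demonstrates and quantifies that failure.

**R2\* mapping.** `fit_r2star()` fits s_i = s_TE=0 · e^(−R2\*·TE_i) to
multi-echo sGRE magnitude data, unconstrained, excluding points below a
noise-floor threshold (default 3σ) to limit Rician bias at long TE.

**Gold standard.** `fit_irse()` fits the inversion-recovery spin-echo
signal s₀ (1 − 2e^(−R₁·TI) + e^(−R₁·TR)) across inversion times, with
exhaustive polarity restoration for magnitude data.

**Uptake metrics.** `roi_median()`, `normalized_change()` and
`cohort_stats()` implement the inference chain: ROI medians per subject ×
region × timepoint; ΔR₁,norm = ΔR₁/ΔR₁,blood and ΔR₂\*,norm =
ΔR₂\*/ΔR₁,blood (immediately post-infusion these approximate, respectively
are proportional to, the cerebral blood volume fraction); paired t-tests,
ΔR₂\*-on-ΔR₁ regression, coefficients of variation and between-tissue
comparisons.

**Synthetic data.** `nine_syringe_spec()`/`build_phantom()`/
`simulate_acquisition()` build a digital nine-compartment phantom
(R1 0.3–4.5 s⁻¹) with a smooth B1/slab-profile flip-angle field and
Gaussian or Rician noise; `simulate_uspio_cohort()` generates a
multi-region, multi-timepoint cohort in which all tissue changes derive
from a prescribed CBV fraction and blood ΔR₁.

## Worked example

Simulate the nine-syringe digital phantom at SNR 50, map R1 with the
HIFI fit, and compare ROI medians against truth:

```r
library(qrelax)
proto <- protocol_preset("study_3t")
spec  <- nine_syringe_spec(grid = c(16L, 16L, 6L), noise_snr = 50, seed = 42L)
maps  <- build_phantom(spec)
hseqs <- proto[c("irsgre_long", "irsgre_short",
                 "sgre_fa12", "sgre_fa5", "sgre_fa3")]
stacks <- simulate_protocol(maps, hseqs, spec, model = "brix")
fitted <- fit_volume(stacks, maps$label > 0,
                     fit_config(model = "deichmann"), what = "hifi")
for (i in c(1L, 5L, 9L)) {
  sel <- maps$label == i
  cat(sprintf("syringe %d: true R1 %.3f  fitted median R1 %.3f  median k %.3f\n",
              i, maps$r1[sel][1], roi_median(fitted$r1, sel),
              roi_median(fitted$k, sel)))
}
```

```
syringe 1: true R1 0.300  fitted median R1 0.299  median k 0.813
syringe 5: true R1 2.400  fitted median R1 2.403  median k 1.037
syringe 9: true R1 4.500  fitted median R1 4.513  median k 0.903
```

Fitted R1 tracks truth across the full range while the fitted `k` map
reflects the simulated B1 dip and slab-edge taper (which is why the
uncorrected variable-flip-angle fit would be biased here). A synthetic
cohort yields blood-normalised changes that read out the prescribed blood
volume fraction:

```r
sim <- simulate_uspio_cohort(cohort_spec(seed = 1L))
nc  <- normalized_change(sim$table, "GM", "post")
mean(nc$delta_r1_norm)
#> 0.0257  (deep grey matter, prescribed CBV 0.024)
```

A command-line wrapper for the main pipeline stages (simulate-phantom,
fit-r1, fit-r2star, fit-irse, roi-stats, uptake, report) is installed at
`system.file("cli", "qrelax.R", package = "qrelax")`; see `?qrelax_cli`.

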