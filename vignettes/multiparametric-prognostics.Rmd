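---
title: "Multiparametric imaging prognostics: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric imaging prognostics: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohsccmpi)
```

# Scope

`ohsccmpi` implements a multiparametric prognostic analysis for advanced
oropharyngeal/hypopharyngeal squamous cell carcinoma: FDG-PET metabolic and
heterogeneity parameters, DCE-MRI extended-Kety pharmacokinetics, DWI ADC,
and a survival layer that dichotomizes markers by maximally-selected
log-rank cutoffs and combines them into a composite 0–4 risk score. This
vignette is the package's own account of the models, the tunable
parameters, the numerical conventions, and — because the original patient
images are not public — what the synthetic validation does and does not
establish.

# PET segmentation and conventional parameters

The tumor is segmented *inside* a generous user-drawn VOI, never across
the whole field of view. Two modes are provided:

* **Fixed threshold** (`segment_fixed_threshold`): voxels with SUV
  strictly above 2.5 g/mL. The inequality is strict by declaration — a
  voxel at exactly 2.5 is excluded — so tie handling is reproducible.
* **Adaptive threshold** (`segment_adaptive`): the published description
  of the adaptive method cites external software without reproducing the
  rule, so the package declares its own standard background-referenced
  form, `T = b + f (SUVmax − b)` with background `b` measured by
  `estimate_background` (mean SUV of a 10-mm sphere in a lesion-free
  region) and fraction `f = 0.5` by default. The applied rule and
  threshold are recorded on the returned mask so outputs are
  self-describing.

After thresholding, only the largest 26-connected component is kept by
default (`keep_largest = TRUE`): a VOI drawn "generously" can clip
physiologic-uptake specks whose inclusion would corrupt MTV and texture.
The filter is toggleable because the raw threshold definition is also a
useful contract (several tests exercise it directly).

Everything geometric uses voxel-center membership: a voxel belongs to a
sphere iff its center is within the radius. This makes every volume
exactly countable, which the tests exploit (the MTV of a digital sphere
converges to $\tfrac{4}{3}\pi r^3$ within 5% at 1 mm spacing).
Conventional parameters follow their definitions: MTV is voxel count times
voxel volume (mL); TLG = SUVmean × MTV, and the identity
`tlg = suv_mean * mtv_ml` is asserted as an invariant rather than stored
independently.

# Heterogeneity (texture) parameters

Intensities inside the segmented tumor are discretized with a
**fixed bin number** (32 and 64 levels; both computed in one call to
`texture_features`), mapping the in-mask minimum to level 1 and the
maximum to level `bins`. A constant region has no definable range and is
rejected rather than silently mapped; callers with an external
discretization can wrap it via `label_volume()`.

**NGLCM.** Co-occurrences are counted over the 13 unique space directions
at Chebyshev distance 1, in both senses of each direction (so every
directional matrix is symmetric), each normalized to sum 1 and then
averaged. Directions that contain no in-mask pair are excluded from the
average — with them, the "entries sum to 1" contract would be
unsatisfiable for thin or small masks. Whether one should average the
matrices and then compute features (the default) or average per-direction
feature values is genuinely open; both are implemented
(`texture_features(..., average = "features")`) and the choice is recorded
on the output. Entropy uses log base 2, also recorded. Feature formulas
are the standard Haralick forms; for a one-hot matrix the gray-level
variance vanishes and correlation is defined as 0.

**NGTDM.** For each in-mask voxel with at least one in-mask neighbor in
its 26-neighborhood, the absolute difference between its level and the
mean level of those neighbors accrues to its level's `s` entry; `p` is
level occupancy among contributing voxels. Features follow the
Amadasun–King definitions with `eps = 1e-6` regularizing the coarseness
and strength denominators (a perfectly flat image has coarseness 1e6, not
infinity), and contrast/busyness defined as 0 when fewer than two levels
are occupied or the busyness denominator vanishes. These conventions
matter only for degenerate images but must be fixed for reproducibility.

Both matrix computations are verified *exactly* against independent
brute-force enumerations on hundreds of small random phantoms — the
implementation is vectorized array shifting, the oracle is a literal
triple loop, and they must agree to machine precision.

# DCE-MRI pharmacokinetics

The acquisition emulated throughout is a 3D spoiled gradient echo at
TR = 3.5 ms: variable-flip-angle baselines at 4°, 8°, 15°, 25°, then a
dynamic series at 15°, 80 frames at 3.3 s temporal resolution with 4
pre-bolus baseline frames. TE is ~1 ms, so T2* weighting is treated as a
constant factor and ignored.

* **T1₀ mapping** (`fit_t10_vfa`): linearized DESPOT1 regression of
  $S/\sin\alpha$ on $S/\tan\alpha$; a slope outside (0, 1) is
  non-physical and raises an error.
* **Concentration** (`signal_to_concentration`): the effective M0 is fixed
  from the mean of the pre-bolus frames together with T1₀, the SPGR
  equation is inverted per frame for T1(t), and
  $C(t) = (1/T_1(t) - 1/T_{1,0})/r_1$. Relaxivity defaults to
  r₁ = 3.6 s⁻¹mM⁻¹ (Gd-DTPA at 3 T) and is configurable; samples whose
  signal implies a non-physical T1 are flagged, not fabricated.
* **Forward model** (`kety_forward`): the extended Tofts–Kety convolution
  is evaluated *exactly* for a piecewise-linear AIF against the
  exponential kernel, by the per-interval closed form with a series
  fallback when $k_{ep}\,\Delta t$ is tiny. There is no quadrature error
  beyond the AIF sampling itself; against a step-AIF closed form the
  numeric curve agrees to ≤ 1e-8 mM on the 80-frame grid.
* **Fitting** (`fit_extended_kety`): bounded Levenberg–Marquardt over
  (K^trans, v_e, v_p) with K^trans ∈ [0, 5] min⁻¹, v_e ∈ (10⁻³, 1],
  v_p ∈ [0, 0.5], and up to 3 dispersed starts; k_ep is always derived as
  K^trans/v_e so the ratio invariant holds by construction. A voxel
  without enhancement (all-zero curve) or without convergence is returned
  flagged with diagnostics rather than raising, so map fitting degrades
  gracefully. ROI reporting uses the mean of voxel-wise fits (median
  available via `roi_summarize`'s `statistic` argument); rates are
  reported in min⁻¹ while time grids are in seconds, with the conversion
  centralized in the forward model.
* **AIF**: the blind-source-separation extraction used with the original
  data is out of scope; the package supplies a measured-curve container
  (`aif_curve`) and a population bi-exponential (`aif_population`,
  Weinmann-type amplitudes 3.99 and 4.78 kg/L, decays 0.144 and
  0.0111 min⁻¹, dose 0.1 mmol/kg) with a 5 s exponential rise and bolus
  arrival after the 4 baseline frames (13.2 s).

# DWI

`compute_adc` is the two-point closed form $\ln(S_0/S_b)/b$, reported in
10⁻³ mm²/s. Non-positive signals yield flagged `NA`s; Sb > S0 yields a
negative ADC that is flagged but preserved (it is information about noise,
not a computational failure). IVIM and multi-b fitting are out of scope.

# Survival analysis and the composite score

Kaplan–Meier estimation, log-rank tests and Cox regression are delegated
to the `survival` package (Efron tie handling — month-resolution follow-up
produces ties routinely); the package's own contributions are the layers
above, and the tests verify the delegated layer against literal
risk-table computations on exhaustive small fixtures.

**Cutoff search** (`find_cutoff`) scans every midpoint between consecutive
distinct order statistics, keeps candidates leaving both groups at least
`min_group_frac` (default 10%) of the cohort, and returns the log-rank
argmax, ties resolved toward the smaller cutoff. Two caveats are by
design: the guard is a deliberate deviation knob (0 disables it) against
the degenerate splits an unconstrained scan permits, and no multiple-testing
adjustment is applied to the selected p-value — mirroring the analysis
being reproduced — so the printed output carries an explicit
selection-bias caveat. A test demonstrates the bias: under the null the
selected p-values pile up far below the nominal level.

**Scoring** (`assign_score`): the composite score counts satisfied binary
risk factors. Boundary conventions match the printed inequalities:
"≤"-type rules include equality as risk, ">"-type rules exclude it. The
standard definitions ship as `os_risk_definition()` (smoking;
K^trans ≤ 0.5512; K_ep ≤ 0.8872; uniformity ≤ 0.00381 — the uniformity
cutoff is taken at 32 bins), `rfs_risk_definition()` (hypopharyngeal
subsite; alcohol; the same DCE cutoffs) and `prior_risk_definition()`
(K_ep ≤ 0.887; SUV > 14.22) for the two-system comparison.
`stratify_and_compare` reports per-stratum KM curves, 3-year survival, the
overall log-rank, and Cox hazard ratios versus the worst occupied stratum
as reference. Heterogeneity parameters are strongly collinear, so when
they are used as Cox covariates they should be entered one at a time; the
package keeps them as separate columns and leaves model composition to the
caller.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the pipeline is
validated:

* `generate_pet_phantom`: a spherical lesion (voxel-center membership) in
  a uniform low-uptake background with constant, two-level-checker, or
  correlated Gaussian-random-field texture, plus a generous VOI
  (lesion radius + 6 mm). The random field is white noise convolved with
  a Gaussian kernel and scaled by the kernel's ℓ² norm, so the marginal sd
  is the requested one.
* `generate_dce_series`: per-voxel Kety forward curves → relaxivity →
  SPGR signals, plus the VFA baselines — precisely the chain the
  estimators invert, so zero-noise recovery must be exact to fitting
  tolerance.
* `generate_dwi_pair`: mono-exponential decay at b = 800 s/mm².
* `generate_cohort`: a 0–4 score per patient with marker values placed on
  the corresponding side of the standard cutoffs, and exponential OS/RFS
  times with hazard `baseline_hazard · hazard_ratio_per_point^score`,
  censored administratively. Defaults emulate the published cohort:
  124 patients, stratum occupancy (0, .09, .42, .38, .11) — every patient
  carries at least one factor — censoring at 58 months, baseline hazard
  0.0012/month with ratio 2.5 per point, which reproduces approximately
  the published 3-year survival gradient under exponential hazards.

Deliberate simplifications: additive Gaussian noise on magnitude signals
(no Rician floor), no partial-volume effects, no reconstruction physics,
no motion, proportional exponential hazards with a single administrative
censoring time. Passing tests therefore establish *computational*
correctness (the estimators invert the stated forward models; the
statistics match their definitions) — they do not establish that the
published cutoffs or effect sizes generalize to real acquisitions, which
would require real multi-scanner data.

# Validation problem sizes

The test suite and acceptance checks use: texture oracle equivalence on
200 random phantoms up to 6×6×6 voxels; the DCE round trip on a
1000-voxel parameter map over 80 frames (recovery within 1% per voxel at
zero noise, and within 10% median K^trans error at SNR 20); exhaustive
8-patient event-pattern enumeration (255 patterns) for KM and log-rank;
Cox recovery of ln 2 within 3 SE at n = 10 000; and the end-to-end power
study on 50 seeds of 2000-patient cohorts with a true per-point hazard
ratio of 2. The 2000-patient size is chosen for power: the smallest
stratum holds ~9% of patients, and demanding a strictly ordered 3-year KM
gradient across all four strata in ≥ 90% of seeds needs small per-stratum
standard errors; at the 124-patient scale the same data-generating process
frequently (and unremarkably) produces locally inverted adjacent strata.

# Known limitations

* The adaptive-threshold rule is a declared stand-in for an unpublished
  method; results under it are labelled with the rule applied.
* The cutoff search inherits the optimism of maximally-selected
  statistics; reported cutoff p-values are descriptive, not confirmatory.
* `fit_kety_map` loops voxels in R; at ~1 ms per voxel fit it is
  comfortable for ROI-scale maps (10³–10⁴ voxels), not whole-volume
  parametric imaging.
* No DICOM ingestion, no coregistration, single-lesion analysis only.
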