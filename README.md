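# ohsccmpi

Multiparametric PET/MRI prognostic modelling for advanced oropharyngeal and
hypopharyngeal squamous cell carcinoma (OHSCC).

Patients with advanced OHSCC treated by chemoradiation have widely varying
outcomes that TNM staging predicts poorly. This package implements, as a
tested and reusable pipeline, a prognostic analysis that combines three
image-derived axes with clinical risk factors:

* **FDG-PET metabolism and heterogeneity** — tumor segmentation inside a
  user-drawn VOI (fixed SUV > 2.5 threshold, or a background-referenced
  adaptive threshold), conventional parameters (SUVmax, SUVmean, MTV, TLG),
  and intratumoural texture from the 13-direction 3D normalized gray-level
  co-occurrence matrix (NGLCM: uniformity, entropy, dissimilarity, contrast,
  homogeneity, inverse difference moment, correlation) and the neighborhood
  gray-tone difference matrix (NGTDM: coarseness, contrast, busyness,
  complexity, strength), each at 32 and 64 gray levels.
* **DCE-MRI pharmacokinetics** — the extended Tofts–Kety model

  $$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
    e^{-k_{ep}(t-\tau)}\,d\tau, \qquad k_{ep} = K^{trans}/v_e,$$

  fitted voxel-wise after variable-flip-angle (DESPOT1) baseline T1 mapping
  and SPGR signal-to-concentration conversion.
* **DWI diffusion** — the apparent diffusion coefficient
  $ADC = \ln(S_0/S_b)/b$ from a two-b-value acquisition (b = 0, 800 s/mm²).

The survival layer provides Kaplan–Meier estimation, log-rank tests,
maximally-selected log-rank dichotomization cutoffs, Cox regression (Efron
ties), and the composite prognostic score: each of four binary risk factors
contributes one point. For overall survival the factors are smoking,
K^trans ≤ 0.5512 min⁻¹, K_ep ≤ 0.8872 min⁻¹, and NGLCM uniformity
≤ 0.00381; for recurrence-free survival, hypopharyngeal subsite, alcohol
drinking, and the same two DCE cutoffs. Strata are compared by KM, overall
log-rank, and per-stratum hazard ratios against the worst stratum, with a
side-by-side comparison against an earlier two-factor system
(K_ep ≤ 0.887, SUV > 14.22).

A synthetic-data module generates every input the pipeline consumes — PET
lesion phantoms with controllable heterogeneity, forward-simulated DCE
acquisitions, DWI pairs from a known ADC field, and survival cohorts whose
hazard rises with the score — so the whole chain is testable against known
ground truth without any imaging download.

## Worked example

Scoring one patient from their measured values — a smoker with
K^trans = 1.056 min⁻¹, K_ep = 1.1356 min⁻¹ and PET uniformity 0.0047 only
carries the smoking risk factor:

```r
library(ohsccmpi)
pt <- list(smoking = TRUE, ktrans = 1.056, kep = 1.1356, uniformity = 0.0047)
assign_score(pt, os_risk_definition())
#> [1] 1
```

An end-to-end synthetic study (124 patients, hazard ratio 2.5 per score
point) runs the full scoring/stratification analysis and the comparison
against the two-factor system:

```r
res <- demo_study(seed = 3)
print(res)
#> Composite-score stratification (OS), reference stratum 4
#>   score 1: n =   7, events =   1, 3-yr survival = 85.7%
#>   score 2: n =  59, events =  25, 3-yr survival = 74.6%
#>   score 3: n =  41, events =  27, 3-yr survival = 56.1%
#>   score 4: n =  17, events =  17, 3-yr survival = 5.9%
#>   overall log-rank chisq = 60.819 (df 3), p = 3.928e-13
#>   stratum1: HR = 0.033 (0.004-0.254), p = 0.001033
#>   stratum2: HR = 0.118 (0.061-0.226), p = 1.316e-10
#>   stratum3: HR = 0.222 (0.118-0.417), p = 2.953e-06
#> --- comparison system ---
#> Composite-score stratification (OS), reference stratum 2
#>   score 0: n =  30, events =  14, 3-yr survival = 66.7%
#>   score 1: n =  55, events =  32, 3-yr survival = 60.0%
#>   score 2: n =  39, events =  24, 3-yr survival = 53.8%
#>   overall log-rank chisq = 1.100 (df 2), p = 0.577
#>   stratum0: HR = 0.710 (0.367-1.373), p = 0.3087
#>   stratum1: HR = 0.932 (0.549-1.584), p = 0.7955
```

The four-factor score separates the synthetic strata sharply (3-year
survival falling from 86% to 6%, HRs of 0.03–0.22 against the worst
stratum), while the two-factor system — blind to the factors that carry the
simulated hazard — does not. The methods vignette
(`vignettes/multiparametric-prognostics.Rmd`) documents the models,
parameter choices, and what the synthetic validation does and does not
establish.

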