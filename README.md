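# memfluor

Fluorescence-spectroscopy readouts of lipid-membrane physical state, for
screens of compound–membrane interactions in liposome (LUV) models.
Planar lipophilic polyphenols and other pan-assay interference compounds
(PAINS) can act by perturbing membranes rather than binding targets; this
package implements the three readouts such a screen rests on, together
with a ground-truth simulator so that every stage is verifiable by
parameter recovery.

## What it computes

**Membrane dipole potential (di-8-ANEPPS ratiometry).**  The
blank-corrected excitation intensity ratio
`R_ex = I(420 nm) / I(520 nm)` (emission 635 nm) is a linear reporter of
the dipole potential ψ<sub>d</sub>.  Two calibrations are provided:

```
psi_d (mV)       = (R_ex + 0.3 ± 0.4) / (4.3 ± 1.2)e-3      absolute
delta_psi_d (mV) = (365 ± 102) * delta_R_ex                  shifts vs control
```

with shift uncertainties propagated in quadrature over replicate
dispersion and slope uncertainty:
`sd = sqrt((k*s_dR)^2 + (k_sd*dR)^2)`.

**Membrane order (DPH-PC steady-state anisotropy).**
`<r> = (I_VV − G·I_VH) / (I_VV + 2G·I_VH)` with the instrumental
G factor `I_HV/I_HH` estimated per repeat, per-reading blank subtraction
and the 7-repeats × 3-samples aggregation hierarchy of the protocol.

**Membrane polarity (TCSPC lifetimes).**  Decay histograms are fitted by
nonlinear least-squares iterative reconvolution (Levenberg–Marquardt)
with multi-exponential models `I(t) = Σ α_i exp(−t/τ_i)`, Neyman
weighting, a free IRF shift and background, and automatic model-order
selection; results are summarised by the intensity-weighted mean lifetime
`<τ> = Σ α_i τ_i² / Σ α_i τ_i`.

**Synthetic studies.**  `generate_study()` forward-simulates the full
condition grid (3 lipid systems × 8 compounds × triplicates, all three
measurement arms) at the published acquisition settings — 400–625 nm
spectra, blanks under 0.7% of the labelled peak, 0.055517 ns/channel
decays with 15,000 peak counts and Poisson statistics — and writes
plain-text files plus a ground-truth table keyed by sample id.

## Worked example

Simulate a reduced two-system study, analyze it, and fit one decay:

```r
library(memfluor)

design <- study_design(lipid_systems = c("POPC", "POPC_CHOL"),
                       compounds = c("CONTROL", "PHLORETIN", "NOTHOFAGIN"),
                       arms = c("dipole", "anisotropy"))
study   <- generate_study(design, dir = "demo_study", seed = 42)
results <- analyze_study(study$manifest)

results$rex
#>   lipid_system   compound mean_rex      sd_rex n
#> 1         POPC    CONTROL 2.036909 0.011932195 3
#> 3         POPC  PHLORETIN 1.743647 0.008993543 3
#> 2         POPC NOTHOFAGIN 1.980262 0.020938018 3
#> 4    POPC_CHOL    CONTROL 3.017430 0.014229473 3
#> 6    POPC_CHOL  PHLORETIN 2.158309 0.010612959 3
#> 5    POPC_CHOL NOTHOFAGIN 2.974857 0.018541648 3

dipole_table(results$rex, wide = TRUE)
#>     compound      POPC POPC_CHOL
#> 1  PHLORETIN -107 ± 30 -314 ± 88
#> 2 NOTHOFAGIN  -21 ± 11  -16 ± 10

dec <- generate_decay(seed = 42)   # bi-exponential, tau = 3 and 7 ns
fit_reconvolution(dec$histogram, n_components = 2)
#> <lifetime_result> synthetic: <tau> = 5.783 ns, chi2_r = 1.075
#> <decay_model> 2 component(s): alpha=0.507 tau=3.009 ns, alpha=0.493 tau=7.008 ns
```

Reading the numbers: the control ratios recover their ground truths (2.03
and 3.05 — the ~1.5-fold cholesterol increase).  Phloretin depresses the
ratio strongly, giving calibrated dipole-potential drops of about
−107 mV (POPC) and −314 mV (POPC:Chol) — the aglycone effect is largest
in the cholesterol-rich system.  Its C-glucoside nothofagin sits within
2 SD of zero in both systems once the slope uncertainty is propagated:
glucosylation abolishes the dipole-modifying activity.  The reconvolution
fit recovers both decay components (3 and 7 ns) within 0.3% at reduced
chi-square ≈ 1.

`build_report(results, "report/")` writes the condition tables (ratio
table with Tukey significance codes vs. control, dipole-shift table in
long and report layouts, anisotropy and mean-lifetime tables) as TSV.

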