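---
title: "Membrane dipole potential, order and polarity from fluorescence readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane dipole potential, order and polarity from fluorescence readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfluor)
```

memfluor implements the analysis chain of a liposome fluorescence screen
for compound–membrane interactions: large unilamellar vesicles (LUVs) of
three compositions — pure POPC (liquid disordered), POPC:cholesterol 1:1
(liquid ordered) and the raft-mimicking ternary POPC:Chol:PSM 1:1:1 — are
labelled at a 1:500 probe:lipid ratio and read out through three probes.
This vignette describes the models behind each readout, the tunable
parameters, the synthetic-data generator used to validate the chain by
parameter recovery, and the numerical decisions taken where the design was
genuinely open.

## Dipole-potential ratiometry

The membrane dipole potential $\psi_d$ (roughly 200–400 mV depending on
composition) arises from oriented lipid-headgroup and interfacial-water
dipoles.  The styryl dye di-8-ANEPPS reports it through an electrochromic
shift of its excitation spectrum: the blank-corrected excitation intensity
ratio

$$R_{ex} = \frac{(I_{lab} - I_{blank})(420\,\mathrm{nm})}
                {(I_{lab} - I_{blank})(520\,\mathrm{nm})}$$

(emission 635 nm) rises with $\psi_d$.  `compute_rex()` reads both
wavelengths off the spectra by linear interpolation — acquisition grids
need not contain 420/520 nm exactly — and warns when the blank exceeds
0.7% of the labelled peak, the bound the acquisition protocol guarantees.

Two linear calibrations connect ratios to potentials:

* the absolute form $\psi_d\,(\mathrm{mV}) = (R_{ex} + b)/m$ with
  $b = 0.3 \pm 0.4$ and $m = (4.3 \pm 1.2)\times 10^{-3}$ per mV
  (`psi_from_rex()`, `calibration_linear()`);
* the rescaled difference form $\Delta\psi_d = k\,\Delta R_{ex}$ with
  $k = 365 \pm 102$ mV per ratio unit (`delta_psi()`,
  `rescaled_slope()`).  The rescaling absorbs the wavelength conventions
  of the absolute calibration; only changes are reported for compound
  conditions, because the intercept (the poorly determined parameter)
  cancels in differences.

`rescale_slope()` refits $k$ by ordinary least squares when the user
supplies anchor conditions with reference potentials from probe-free
measurements; the package default stays at the fixed constant because no
anchor table ships with it.

**Error propagation.** The uncertainty of a shift combines the replicate
dispersion of both ratios with the slope uncertainty in independent
quadrature,

$$s_{\Delta\psi} = \sqrt{(k\,s_{\Delta R})^2 + (s_k\,\Delta R_{ex})^2},
\qquad s_{\Delta R} = \sqrt{s^2_{sample} + s^2_{control}},$$

so $s_{\Delta\psi}$ can never fall below the slope-term floor
$s_k\,|\Delta R_{ex}|$ — about 28% of the shift itself.  Replicate
dispersion enters as the sample standard deviation over triplicates (the
mean ± SD convention of the condition tables), not the standard error;
consumers comparing a shift against zero should keep in mind that the
triplicate-mean difference then has sampling variance $s^2_{\Delta R}/3$.

Because the slope term dominates for large shifts, a compound can depress
$R_{ex}$ measurably (a replicate-level ANOVA flags it against control)
while its calibrated $\Delta\psi_d \pm 2s$ interval still covers zero.
The package treats the calibrated scale as authoritative for the
"does this compound change the dipole potential" question: the
glucosylated compounds in the default study design all stay within
$2s$ of zero in every lipid system, while the parent aglycones do not.

## Steady-state anisotropy

Membrane acyl-chain order is probed by DPH-PC, whose diphenylhexatriene
fluorophore sits deep in the bilayer parallel to the acyl chains.  Its
steady-state anisotropy

$$\langle r \rangle = \frac{I_{VV} - G\,I_{VH}}{I_{VV} + 2G\,I_{VH}},
\qquad G = \frac{I_{HV}}{I_{HH}}$$

rises with lipid packing.  The measurement protocol records the four
polarized components seven times per sample with per-reading blank
subtraction.  Three aggregation decisions were open and are fixed as
follows:

* **Per-repeat anisotropy.**  Each repeat gets its own G factor from its
  HV/HH pair and its own $r$; the sample value is the mean of the seven
  per-repeat anisotropies (not a ratio of summed intensities).  Both
  conventions coincide in the zero-noise limit; per-repeat averaging keeps
  a drifting lamp from coupling the components.
* **Condition SD across samples.**  The reported dispersion is the SD over
  the three independent samples, matching the mean ± SD convention; the
  within-sample spread over repeats is diagnostic only.
* **Exclusion, not clipping.**  A repeat whose blank-corrected intensity
  is non-positive is dropped with a warning.  Clipping negative
  intensities to zero would bias $r$ upward; exclusion at most loses a
  repeat.

## TCSPC lifetimes by iterative reconvolution

Membrane polarity around the DPH fluorophore is read from the fluorescence
intensity decay, modelled as a sum of exponentials
$I(t) = \sum_i \alpha_i e^{-t/\tau_i}$ with normalized amplitudes.  The
expected histogram is the decay law convolved with the measured instrument
response function (IRF), plus a flat background, and the fit minimizes the
Neyman-weighted sum of squares $\sum (c_i - \hat c_i)^2/\max(c_i, 1)$ with
the Levenberg–Marquardt algorithm (`minpack.lm`).  Free parameters:
amplitudes, lifetimes, an IRF shift and the background.  Results are
summarised by the intensity-weighted mean lifetime
$\langle\tau\rangle = \sum \alpha_i\tau_i^2 / \sum \alpha_i\tau_i$, which
is bounded between the amplitude-weighted mean and the largest lifetime
and is far more stable than individual $\alpha_i/\tau_i$ pairs, whose
well-known trade-off makes them individually soft.

Numerical decisions:

* **Channel treatment.**  The acquisition grid is 0.055517 ns/channel.
  The decay law enters the discrete convolution through its exact average
  over each channel's lag window (`bin_avg_exp`), not a point sample at
  the channel center; at the rising edge the curve changes by orders of
  magnitude within a channel, and point sampling there distorts the peak
  channels far beyond Poisson noise.  The synthetic generator
  bin-integrates its analytic curve for the same reason.
* **Under-sampled IRFs.**  The stated detection resolution, 50 ps FWHM,
  is *narrower than one channel*.  A histogram of such an IRF carries no
  sub-channel shape information, and using it directly as a point-mass
  kernel leaves a large systematic residual in the two or three channels
  that hold its mass.  When the empirical IRF width (after removing the
  binning variance $w^2/12$) is below two channels, the fit therefore
  refines the kernel by fitting a bin-integrated Gaussian to the
  histogram and convolving on an 8× oversampled grid; IRFs wider than two
  channels are used empirically, as measured.  With this refinement the
  noiseless bi-exponential test case is recovered with reduced chi-square
  below 0.01 and lifetime errors below 0.1%.
* **Fit window.**  From the rising edge (first channel at 2% of peak) to
  the last channel above `max(background, 10)` counts.  The background
  starts from the median of the pre-rise channels and is refined in the
  fit.
* **Initialisation and restarts.**  Lifetimes start log-spaced between
  10 channel widths and a fifth of the record; amplitudes equal; up to two
  lognormally jittered restarts are taken when the first attempt converges
  poorly (reduced chi-square above 1.5), keeping the best.
* **Degenerate components.**  Lifetimes that collapse within 1% of each
  other demote the model to one fewer component with a warning;
  non-convergence is flagged in the diagnostics rather than thrown.
* **Model order.**  `select_model()` fits one to three components and
  returns the smallest order with reduced chi-square below 1.3 whose next
  order improves it by less than 5%; ties go to fewer components.  The
  study's decays are bi-exponential with components near 3 ns and 7 ns,
  and the selector finds order two in well over 90% of simulated
  histograms at the acquisition settings (peak counts 15,000, inside the
  10,000–20,000 protocol band).

## The synthetic study generator

Because the screen's raw data exist only as published summary values, the
package ships a forward simulator whose defaults *are* the study
conditions, so that every analysis stage is testable by parameter
recovery:

* Triplicate independent samples per condition; 3 lipid systems × 8
  compounds (vehicle control, phloretin, nothofagin, phlorizin, genistein,
  8-glucosylgenistein, resveratrol, 4-glucosylresveratrol at 50 µM).
* **Spectra**: two Gaussian bands on a 400–625 nm grid with amplitudes
  solved so the blank-subtracted 420/520 ratio equals the ground truth
  exactly before noise; the band shape itself is nuisance (the real dye
  spectrum is not two Gaussians, but only the two ratio wavelengths carry
  information here).  Control ratios: 2.03 (POPC), 3.05 (POPC:Chol — the
  1.5-fold cholesterol increase), 2.20 (ternary).  Compound conditions
  shift the truth by $\Delta R_{ex} = \Delta\psi_d / 365$ from the
  reported shift table (`default_delta_psi_table()`).
* **Noise model**: multiplicative log-normal of mean one for analog
  detection (spectra and polarized readings), Poisson for photon counting
  (TCSPC) — matching the physics of each detection mode.  The pointwise
  spectral CV defaults to 0.007, chosen once so that replicate $R_{ex}$
  SDs land at the reported 0.02–0.03 ratio units; it is the generator's
  one calibration knob, since within-spectrum noise is not itself
  reported.
* **Polarized sets**: noiseless components
  $I_{VV} = s(1+2r)$, $I_{VH} = s(1-r)/G$, $I_{HV} = Gs$, $I_{HH} = s$
  reproduce the truth exactly through the estimator; the per-component
  noise CV is derived per condition from the target across-sample SD by
  the delta-method inversion `anisotropy_noise_cv()` (one repeat has
  $s_r = 2\,c_v (1-r)(1+2r)/3$).  Control anisotropies: 0.165 (POPC,
  SD 0.002) and 0.247 (POPC:Chol, SD 0.007); the ternary mixture is set
  slightly more fluid (0.240, a value chosen once to reflect the small
  but significant fluidity increase reported for the raft mixture, whose
  exact anisotropy is not printed).
* **Decays**: bi-exponential with $\alpha = (0.5, 0.5)$,
  $\tau = (3, 7)$ ns in every condition (the mean lifetime was
  composition-independent), Gaussian IRF of 50 ps FWHM centred at 1.5 ns,
  1024 channels of 0.055517 ns, expected peak scaled to 15,000 counts,
  channel-wise Poisson draws.  The expected curve is the analytic sum of
  exponentially modified Gaussians, bin-integrated.
* **Blanks** are emitted at 0.5% of the labelled peak (the protocol keeps
  them under 0.7%) and are present both inside the labelled signal and as
  separate blank files, so blank subtraction is exercised end to end.
* All randomness flows from one explicit seed through a deterministic
  child-seed scheme; the same `(design, seed)` pair is byte-identical on
  disk, and generation restores the caller's RNG state.

What the generator deliberately does **not** emulate: photobleaching,
scattering and inner-filter effects, probe partitioning equilibria,
probe–compound interactions, and any molecular mechanism connecting a
compound to its shift — compound effects enter only as shifted truth
parameters.  Passing recovery tests therefore demonstrates that the
analysis chain is unbiased and correctly calibrated *for data of this
structure*; it cannot certify robustness against instrumental artifacts
the generator does not model.

## Statistics

Condition comparisons follow the screen's conventions: one-way ANOVA with
Tukey's post-test within each lipid system (`one_way_anova_tukey()`,
all-pairs with the vs-control and vs-aglycone families flagged,
Tukey–Kramer for unbalanced groups so replicate dropout cannot crash
reporting), and a fixed crossed two-way ANOVA with interaction across
compounds and lipid systems (`two_way_anova()`; whether the original
analysis included the interaction is not stated — it is included here).
Significance codes follow the four-star ladder at 0.05, 0.01, 0.001,
0.0001.

## Problem sizes

The shipped tests validate the chain at desk scale: 1000-seed ratio
recovery, 500-seed anisotropy recovery, 200 simulated triplicate studies
for the shift-dispersion calibration, 100 Poisson realizations for
lifetime bias and chi-square calibration, 50 seeds for model-order
reproducibility, and 32 study realizations for the glucoside
null-equivalence check.  These sizes keep Monte-Carlo error comfortably
below the tolerances they guard while the whole suite runs in a few
minutes on one core.

## Known limitations

* The dipole calibration is linear by construction; strongly nonlinear
  dye responses (very large shifts, unusual sterols) are out of model.
* The absolute potential `psi_from_rex()` inherits the large intercept
  uncertainty of the published calibration and should only be used for
  differences.
* The reconvolution fitter targets per-curve least squares with one to
  three discrete exponentials; no Poisson-deviance (MLE) estimator,
  global multi-curve analysis, or lifetime distributions.
* Decay and IRF must share binning; resampling mismatched records is
  refused rather than interpolated, to keep the fit contract exact.
* The Gaussian IRF refinement assumes a unimodal, roughly symmetric
  response; heavily tailed IRFs wider than two channels bypass it and are
  used as measured.
```{r session}
sessionInfo()
```
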