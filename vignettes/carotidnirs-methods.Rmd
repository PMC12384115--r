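---
title: "Models and methods behind carotidnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carotidnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidnirs)
```

## The measurement problem

Wearable continuous-wave near-infrared spectroscopy (CW-NIRS) patches placed
over the radial and carotid arteries record diffusely reflected light at a
few wavelengths (here 670, 780, 808 and 850 nm) and two source-detector
separations (25 and 32 mm), sampled at 2.24 Hz. Changes in tissue
oxy- and deoxyhemoglobin concentration (HbO~2~, Hb) modulate the absorption
coefficient $\mu_a(\lambda)$, hence the detected intensity. During a
structured 150 s breathing protocol — normal breathing, a breath hold (BH),
normal breathing, deep breathing (DB), normal breathing, 30 s per segment —
the total hemoglobin HbT = HbO~2~ + Hb rises during the hold and both HbT
and the tissue oxygen saturation StO~2~ = 100·HbO~2~/HbT oscillate during
deep breathing. The package asks, with simulated cohorts: do the carotid
patches report the same protocol-evoked changes as the radial (reference)
patches, in the sense of statistical *equivalence*?

Because no raw recordings are deposited anywhere, everything here runs on
synthetic cohorts whose per-location feature distributions are set to the
published summary statistics. The pipeline is therefore a self-consistency
instrument: forward model and inverse model are the package's own, and the
statistical battery is exercised under the cohort conditions the study
describes.

## Forward optics

Photon transport is modelled with the diffusion approximation for a
homogeneous semi-infinite medium and an extrapolated boundary (dipole
solution). With $\mu_t' = \mu_a + \mu_s'$, source depth $z_0 = 1/\mu_t'$,
diffusion constant $D = 1/(3\mu_t')$, $\mu_{\mathrm{eff}} =
\sqrt{3\mu_a\mu_t'}$ and extrapolation length $z_b = 2AD$:

$$
R(\rho) \propto
z_0\!\left(\mu_{\mathrm{eff}} + \tfrac{1}{r_1}\right)\frac{e^{-\mu_{\mathrm{eff}} r_1}}{r_1^2} +
(z_0 + 2z_b)\!\left(\mu_{\mathrm{eff}} + \tfrac{1}{r_2}\right)\frac{e^{-\mu_{\mathrm{eff}} r_2}}{r_2^2},
$$

with $r_1 = \sqrt{\rho^2 + z_0^2}$ and $r_2 = \sqrt{\rho^2 + (z_0+2z_b)^2}$.
The boundary constant defaults to $A = 2.95$ (tissue-air, refractive index
about 1.4) and only rescales the absolute signal, which cancels in every
change-based quantity. The wearable device this emulates reconstructs
hemoglobin with a proprietary diffusion-theory algorithm whose equations are
not public; any self-consistent forward/inverse pair supports the round-trip
and equivalence questions this package answers, which is why the canonical
published CW solution was adopted. Assumptions worth keeping in mind:
homogeneous bulk tissue (no skin/fat/vessel layering — layering is not
identifiable from two distances), $\mu_s' \gg \mu_a$ (the constructors warn
when $\mu_a/\mu_s' > 0.1$), and a point source/detector geometry.

Absorption links to chromophores through
$\mu_a(\lambda) = \ln 10\,[\varepsilon_{\mathrm{HbO_2}}(\lambda)C_{\mathrm{HbO_2}}
+ \varepsilon_{\mathrm{Hb}}(\lambda)C_{\mathrm{Hb}}] + \mu_{a,\mathrm{bg}}(\lambda)$,
with decadic molar extinction values at the four wavelengths shipped as a
CSV resource (transcribed to 2-3 significant figures from the standard
compiled literature values) and a small water/background term. The
differential pathlength factor
$\mathrm{DPF} = \frac{1}{\rho}\frac{\partial(-\ln R)}{\partial \mu_a}$
is evaluated analytically from the dipole solution; the tests check it
against a central finite difference at $10^{-6}\ \mathrm{mm}^{-1}$ steps.

## Synthetic cohorts

`generate_cohort()` draws, per subject and location, the nine generator
parameters (baselines, BH maximum % changes, DB peak-to-peak amplitudes,
DB oscillation half-period times, HbT response delay) from normal
distributions whose means/SDs default to the published per-location
summaries; right-side values for the parameters whose summaries are only
published for the left side mirror the left-side values. Within a subject,
locations share a latent factor giving an equicorrelation of 0.5 (paired
physiology; the value is a modelling choice, configurable, because no
between-arm correlation is published). Draws are floored only where
validity requires it (amplitudes at 0.02 units, oscillation half-periods at
1 s, baselines at physiological minima); the floors are far enough in the
tails that cohort means stay within sampling error of the targets, which
the tests check at n = 200 subjects against 3 standard errors.

Waveforms are deliberately simple shapes reproducing the protocol
phenomenology:

* **Breath hold** — a smoothstep ramp from 5 s into the segment to the hold
  end, peaking at the drawn maximum change, then exponential relaxation
  (8 s time constant).
* **Deep breathing** — StO~2~ is a sinusoid starting at the segment onset
  whose half-period is the drawn oscillation time; HbT oscillates at half
  the StO~2~ frequency and starts at zero phase after the drawn response
  delay (the chemoreflex-mediated HbT response lags the breathing-driven
  saturation swing). Per-half-cycle amplitude jitter (10% CV by default)
  keeps cycles from being identical. A 1.5 s smoothstep envelope avoids a
  discontinuity at onset.
* **Normal segments** — baseline plus low-pass Gaussian fluctuation
  (moving-average filtered white noise, default 0.1 uM HbT and 0.03% StO~2~).

Baseline absolute levels default to HbT 60 uM and StO~2~ 70%, typical
soft-tissue values; the study only reports changes from baseline, so these
anchors are needed to give % changes a denominator.

`truth_to_recording()` pushes the latent concentrations through the forward
model per channel and applies the instrument noise model: per-channel
log-normal gains, multiplicative photon noise (0.1% default — a realistic
photodiode noise floor at this sampling rate), slow linear gain drift
(0.5% per trial), and Poisson-timed motion-artifact bumps shared by all
channels of a patch. What the generator does *not* emulate: cardiac
pulsation, respiratory mechanics coupling, skin-tone-dependent optical
coupling, electrode-style pop artifacts, or any systematic left/right
asymmetry beyond the drawn parameters. Passing tests therefore demonstrate
pipeline self-consistency under plausible noise, not device performance on
real tissue.

## Reconstruction

The inverse chain is the linearized modified Beer-Lambert law:

1. `delta_optical_density()`: $\Delta OD(\lambda,\rho,t) = \ln(I_{\mathrm{ref}}/I(t))$
   against the mean intensity over the first 20 s (the same window as the
   feature baseline, so HbT traces read as change from baseline). Constant
   gains cancel here exactly.
2. `absolute_baseline()`: the two-distance attenuation of the
   gain-corrected reference intensities is inverted per wavelength to
   $\mu_a(\lambda)$ by root-finding the model-consistent log-ratio
   $\ln[R(\rho_1)/R(\rho_2)]$, given a power-law reduced-scattering prior
   $\mu_s'(\lambda) = a(\lambda/800)^{-1.2}$, $a = 0.9\ \mathrm{mm}^{-1}$.
   The textbook slope formula $\mu_a = \mu_{\mathrm{eff}}^2/(3\mu_s')$ with
   $\mu_{\mathrm{eff}}$ read off the $\ln(\rho^2 I)$ slope carries a
   20-25% near-field bias at 25-32 mm (the $\mu_{\mathrm{eff}} + 1/r$ terms
   are not negligible there), so it serves only as the initial bracket;
   the root-finder removes the bias and the round-trip test recovers a
   60 uM / 70% baseline within 3%. Unphysical estimates fall back to the
   configured default baseline with a warning. Note the absolute step needs
   calibrated relative channel gains (the recording's `gain` column);
   change-based features never do.
3. `unmix_concentrations()`: per time sample, weighted least squares over
   all 8 channels of
   $\Delta OD/(\mathrm{DPF}\,\rho) = \ln 10\,(\varepsilon\,\Delta C)$,
   weights inverse to each channel's reference-window $\Delta OD$ variance.
   The DPF is evaluated at the baseline optical properties and held fixed
   for the trial (standard CW practice, consistent with a real-time
   reconstruction). Samples with flagged channels are refit on the
   channels that remain.
4. `reconstruct_trial()` composes the above, forms
   $StO_2(t) = 100\,(HbO_{2,0} + \Delta C_{\mathrm{HbO_2}})/(HbT_0 + \Delta C_{\mathrm{HbT}})$,
   clamps to [0, 100] while counting clamps (excursions are a quality
   signal, not an error), and marks trials with more than 20% flagged
   samples low-quality. Optional per-channel linear detrending over the
   first and last normal segments (off by default, as the reference
   analysis describes none) removes pure gain drift.

## Feature extraction and quality control

Six parameters per subject and location: BH maximum % change and DB mean
oscillation time and mean peak-to-peak amplitude, each for HbT and StO~2~.
Conventions that the generator and extractor share by construction:

* **Oscillation time** is the mean time between *adjacent alternating*
  extrema (peak to trough), i.e. a half period. The published definition
  ("time between one peak/trough to the next") admits a full-period
  reading too; the printed HbT (about 7 s) and StO~2~ (about 3.5 s) values
  are consistent with either given the 2x frequency relation, and the
  half-period reading matches the wording most directly. A shared package
  constant asserts both sides use the same convention.
* **Peak-to-peak amplitude** is the mean |peak − adjacent trough| over
  consecutive alternating pairs.
* **Extrema** come from slope sign changes of a 3-sample moving average,
  with enforced alternation (keeping the more extreme of same-type
  neighbours) and a prominence floor of 20% of the segment IQR applied on
  the smoothed series, with the segment's first/last samples as virtual
  neighbours — this last detail rejects plateau artifacts at segment
  edges, e.g. before the delayed HbT oscillation onset. Detection is fully
  deterministic.
* **BH % change** uses the absolute baseline estimate as denominator
  (change-only traces have no natural % scale).

Trial selection mirrors the sinusoid-assuming SNR definition: the DB
segment of the HbT trace is linearly detrended, Hann-windowed and
periodogram-transformed; the largest non-DC bin is the fundamental
(±2 bins absorb leakage at non-integer cycle counts), its first five
harmonics (±1 bin) are excluded, the two lowest bins are treated as
residual-trend leakage, and the noise level is the chi-square-corrected
median of the remaining bins extrapolated over the band. The result is
capped at 100 dB. The least-noisy trial is analysed; when every trial at a
location scores below the threshold the location is excluded. The
threshold "1" is read in dB (the published rule invokes a function whose
output is in dB); at 0 dB the dB and linear-ratio readings coincide, and
1 dB vs a ratio of 1 shifts the cut by only 12%. Ties go to the earliest
trial. Outlier screening is the published 2-SD rule, applied exactly once,
per feature within each location group across subjects.

## Equivalence statistics

`wilcox_tost()` implements the continuity-corrected Wilcoxon signed-rank
TOST on paired differences $d = x - y$ with bound $\Delta$: the lower test
shifts by $+\Delta$ and tests for a positive centre, the upper by
$-\Delta$ for a negative centre; each one-sided p uses the tie-corrected
normal approximation with a ±0.5 continuity correction (identical to base
R's approximation, checked against it and against exhaustive
sign-enumeration for n ≤ 10, where agreement is within 0.02), and the TOST
p is the larger of the two. The reported effect is the median of
differences (MoD), computed as the Hodges-Lehmann pseudo-median (median of
all Walsh averages), with a 95% CI from signed-rank inversion. Equivalence
is declared when the Bonferroni-adjusted p (default m = 4, the four artery
pairs tested per parameter — the published multiplicity statement is
ambiguous, and this is the reading that matches "tests per location for
each parameter") is at most 0.05.

The six default thresholds are the published values (HbT: 3.7%, 1.2 uM,
2.1 s; StO~2~: 3.2%, 0.5%, 1.4 s), shipped as immutable defaults. The
published derivation "from the standard deviations of the datasets" does
not reproduce all six (e.g. the 1.2 uM HbT bound matches neither arm SD of
0.8 and 1.1), so a pluggable `threshold_from_sd()` rule (max of the two arm
SDs) is provided but clearly not equal to the printed table.

`kendall_tau()` reports tau-b with exact p for untied n ≤ 8 and the
tie-corrected normal approximation otherwise, with the |tau| > 0.2 / > 0.4
marginal/moderate classes gated on adjusted significance.
`kruskal_eta2()` computes tie-corrected H and
$\eta^2 = (H - k + 1)/(n - k)$, floored at 0. `tost_sample_size()` uses the
parametric paired-TOST noncentral-t power approximation (the same family
as the parametric power package the reference analysis cites); a
Monte-Carlo power simulation in the tests brackets its answer within one
subject.

## Numerical choices and degenerate inputs

* Root-finding for baseline $\mu_a$ brackets $[10^{-6}, 1]\ \mathrm{mm}^{-1}$
  at tolerance $10^{-10}$; a non-positive attenuation slope (identical
  intensities at both distances) or out-of-bracket slope triggers the
  default-baseline fallback with a warning.
* Signed-rank zeros are dropped (the usual convention); if every
  difference ties with the shifted bound the p-value is returned as 0.5
  with a warning — no information either way at that bound.
* The SNR estimator returns 100 dB when the noise estimate underflows.
* Extremum detection needs at least 5 samples and returns an empty table
  (features flagged `NA`) when fewer than 2 extrema survive pruning.
* All cohort randomness flows from one seeded generator; `generate_cohort()`
  restores the caller's RNG state, and regeneration under the same seed is
  bit-identical (tested).

## Problem sizes used by the checks

The test-suite simulations use the study design itself (20 subjects, 4
locations, 3 trials) for end-to-end replicates, 12 pipeline replicates and
500 stats-stage replicates for the equivalence-rate checks, 10,000
replicates for boundary type-I calibration, 100 random datasets for the
enumeration comparison, and a 100,000-photon Monte-Carlo walk for the
forward-model cross-check. These sizes were chosen so each property is
resolved well inside its assertion margin.

## Known limitations

* No claim of numeric parity with the physical device: its reconstruction
  equations are unpublished, so the package targets self-consistency with
  its own forward model.
* The homogeneous semi-infinite geometry ignores layering and vessel
  depth; at carotid depths (> 20 mm) the real measurement is a bulk-tissue
  proxy, and so is the simulation.
* Generator shapes are idealized (smoothstep/sinusoid); real traces carry
  cardiac and vasomotor structure the feature extractor never sees in
  testing.
* Demographic fields are generated to the cohort proportions but have no
  effect on hemodynamics by default (the reference analysis found
  negligible effect sizes); injected effects are available for power
  studies but are not part of any default.
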