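---
title: "Methods: single-trial analysis of perturbation-evoked cortical responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial analysis of perturbation-evoked cortical responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepstep)
```

## The scientific problem

When the surface a person stands on suddenly translates, the EEG over
midfrontal scalp shows a stereotyped response: a small positive deflection
(P1) followed by a large negative peak (the *N1*, roughly 90–160 ms after
perturbation onset) and a burst of theta/alpha/beta power. If the
perturbation is strong enough, the person must take a reactive step;
otherwise balance is recovered with the feet in place. `pepstep` implements a
complete analysis chain for asking how these cortical responses relate to
perturbation intensity, to the eventual stepping response, and to their
interaction — the interaction being the interesting part, because it ties the
cortical response to the behavioural stepping-probability curve rather than
to stimulus strength alone.

The chain is: reactive-step detection from force plates; EEG conditioning;
ICA source separation with automatic selection of the midfrontal N1
component; single-trial N1 amplitude/latency and Morlet time–frequency
features on an N1-locked grid; and a pooled mass-univariate regression

$$C_x \sim \beta_0 + \beta_1\,\mathrm{ACCEL} + \beta_2\,\mathrm{STEP} +
  \beta_3\,\mathrm{ACCEL}\times\mathrm{STEP}$$

fitted independently at every time(-frequency) bin, with
Benjamini–Yekutieli FDR control at $\alpha = 0.01$.

Because raw laboratory recordings of this kind are not openly deposited, the
package ships a first-class synthetic-data generator with known ground truth;
every downstream stage is tested against what the generator injected.

## The synthetic generator

`ground_truth()` collects everything the generator injects, and
`generate_trial_schedule()` / `simulate_stepping()` / `generate_grf()` /
`generate_eeg()` realise it. Design choices, in order of importance:

* **Effects live on the log-power (dB) scale.** The regression downstream
  operates on `10*log10(|x|^2)` parameters, so the generator draws a per-trial
  effect value $E = \beta_0 + \beta_1 a + \beta_2 s + \beta_3 a s +
  \varepsilon$ in dB and scales waveform amplitudes by $10^{E/20}$. Defaults
  $\beta = (0, 4, 2, -3)$ dB encode the qualitative finding the pipeline must
  recover: responses scale with intensity (about a factor 3 in amplitude over
  the tested range for feet-in-place trials), stepping responses are larger,
  and the intensity scaling is attenuated on stepping trials
  ($\beta_1 + \beta_3 < \beta_1$). The magnitudes are calibrated to the
  measurement chain: per-trial baseline estimation at low frequencies adds
  roughly 3 dB of noise to every baseline-corrected log-power value (the
  baseline window holds only one or two independent samples of a narrowband
  process), so dB-scale effects must be of this order to be detectable at the
  study's trial counts.
* **Stepping law.** Stepping is Bernoulli with
  $p = \mathrm{logit}^{-1}(k(a - a_{50}))$. Defaults put the 50% point at
  1.02 m/s² (backward sway) and 1.28 m/s² (forward), with steepness
  $k = \log 3 / \text{(half-width of the 25–75% interval)}$, i.e. 25/75%
  points at [0.87, 1.18] and [1.10, 1.46] m/s² — the group-level values the
  study conditions state. These are configuration, not hard-coded constants.
* **N1 waveform.** The source literature does not specify a canonical N1
  shape, only a small positive lobe followed by a large negative one. The
  generator uses a Gaussian-windowed biphasic template (positive lobe 45 ms
  before the trough at 30% amplitude); it is a single function
  (`pepstep:::n1_template`) and deliberately swappable. Latency follows
  `base − slope·accel` (defaults 195 ms, 6 ms per m/s²), 12 ms shorter on
  stepping trials, with 4 ms trial jitter — reproducing the observed ordering
  (stepping N1 earlier than non-stepping, latencies shortening with
  intensity).
* **Foot-off latency** is truncated-normal with an affine decreasing mean
  (650 − 120·accel ms, SD 80 ms) on (150, 1000) ms, consistent with a 1-s
  detection window and the published per-participant means.
* **Band bursts.** Theta/alpha/beta bursts are Gaussian-windowed sinusoids
  co-timed with the N1 whose log power follows the same linear structure;
  the per-band `band_burst_gains` are interpreted as *amplitude* multipliers,
  so they move the per-band intercept but leave $\beta_1..\beta_3$ identical
  across bands — which is what makes a single injected-region recovery check
  well-defined. The gamma gain defaults to 0, keeping high frequencies as a
  null region for false-positive calibration. Bursts are phase-locked to the
  N1 (trough aligned): with random phase, the burst and the broadband N1
  deflection interfere as complex amplitudes in low-frequency wavelet bins,
  adding several dB of per-trial noise that has no physiological counterpart;
  phase locking mirrors the phase-reset account of midfrontal rhythms.
* **Noise model.** The midfrontal background is 1/f noise; nuisance sources
  are blink transients and broadband (>30 Hz) muscle noise. Muscle noise and
  per-channel sensor noise are amplitude-modulated by independent slow
  rectified envelopes. This matters: real EMG and electrode noise are bursty,
  and the modulation makes these directions non-Gaussian so that an ICA
  contrast exists for them. With stationary Gaussian noise the unmixing of
  the noise subspace is unidentifiable and ICA oscillates without
  converging.
* **Trial-level noise** `amp_noise_sd` (default 1.5 dB) is a free parameter
  the source literature cannot pin down; together with the effect sizes it
  was set once against the scale of the pooled determination coefficients and
  is not otherwise tuned. Note that the realized design is strongly
  collinear — stepping is nearly deterministic in acceleration — so pooled
  R² stays well below what a balanced design would give, and the step main
  effect carries large standard errors by construction.
* **Seeding.** All randomness flows from one master seed through named
  substreams (`schedule`, `behavior`, `grf…`, `eeg`), so stages can be
  re-run in isolation and remain jointly reproducible.

What the generator does *not* emulate: platform biomechanics, EMG, electrode
geometry (mixing weights are abstract, not forward-modelled through a head
model), habituation or attention effects, and non-stationarities beyond the
slow noise envelopes. Passing tests therefore demonstrate that the pipeline
recovers the statistical structure it assumes, on data satisfying those
assumptions — not that the assumptions hold for any particular laboratory
recording.

## Step detection and behavioural statistics

`detect_step()` low-pass filters each vertical force trace at 20 Hz (order-5
Butterworth, forward–backward for zero phase) and reports the first sample
within 1 s of onset at which either trace drops below 10 N. Latency is
`floor(samples/fs*1000)` — detection is a first-crossing index, so flooring
(not rounding) is the faithful conversion. A simultaneous crossing of both
feet is broken toward the left foot (documented tie-break; it never occurs
on generated data).

`behavioral_report()` computes the group-level battery from per-participant
summary tables: stepping proportions, a 2×2 Pearson chi-square *without*
continuity correction (validated against the published value), paired t
tests on per-participant means (11 values — the published tests operate at
participant level), trial-count-weighted pooled means, and N1-to-foot-off
latency differences. The packaged `table1.csv`/`table2.csv` transcribe the
published per-participant summaries of an 11-participant study; note that
the transcribed counts give a backward stepping proportion of 63.6%
(442/695) whereas the source prose prints 63.3% — the package asserts the
recomputed value and does not force agreement. The KS uniformity test uses
the asymptotic p-value (sessions have several hundred trials; the discrete
acceleration grid introduces ties that an exact test would reject).

## EEG conditioning

Filtering is 1–200 Hz (order-5 Butterworth high- then low-pass, each
forward–backward), then anti-aliased polyphase resampling to 512 Hz, then
common-average referencing over scalp channels. Event indices are kept
1-based (R convention) and rescaled on resampling. Channel rejection
replaces visual inspection with a robust-variance rule (squared MAD above
5× the channel median, overridable); the generator's defaults produce no
rejections. Because common-average referencing leaves the scalp data exactly
rank-deficient, the principal component with the smallest eigenvalue (the
null space) is removed before ICA and the reduced basis is carried along
with its back-projection.

## ICA and N1-component selection

`fit_ica()` uses symmetric FastICA with a log-cosh contrast (`ica::icafast`),
components scaled to unit variance, deterministic given the seed.
`select_n1_component()` replaces per-participant visual inspection: for each
component the trial-averaged onset-locked potential is computed, its
largest-magnitude peak within (0, 300] ms — sign-flipped negative, since
component signs are arbitrary — is scaled by the RMS of the component's
back-projected scalp map, and the largest score wins. The canonical
90–160 ms N1 window is deliberately widened to (0, 300] ms to match the
single-trial search window used downstream. Components whose post-onset
trough does not exceed 3× the pre-onset ERP SD are ineligible, so data
without a time-locked response raise an informative error rather than
selecting noise. Equivalent-current-dipole localisation is out of scope
(no electrode geometry exists for synthetic mixing); the scalp map itself is
reported for plausibility checks.

## Time–frequency decomposition

The Morlet bank is parameterised directly by the temporal FWHM of the
Gaussian envelope: $w_k(t) = e^{i 2\pi f_k t}\, e^{-4\ln 2\, t^2 /
\mathrm{FWHM}_k^2}$, 30 frequencies log-spaced 2–50 Hz, FWHM log-spaced
800→200 ms (the source states only that FWHM decreases with frequency;
log spacing mirrors the log-spaced frequency axis). Kernels are unit-energy
normalised — downstream analyses (within-bin regression, baseline
subtraction) are invariant to per-frequency gain, so any consistent
normalisation is valid. Kernel support is ±3·FWHM and samples within half a
kernel of a segment edge are flagged invalid and excluded from baselines and
grids. A consequence worth knowing: at 2 Hz the invalid margin is ~2.4 s, so
the pipeline convolves per-trial segments cut from the *continuous*
component activation with a ±3·FWHM margin rather than convolving (−2, 9) s
epochs, keeping the (−1.5, −0.5) s baseline and the ±500 ms N1-locked grid
edge-valid at every frequency.

Note that the analytic spectral FWHM of Gaussian-envelope wavelets with
800/200 ms temporal FWHM is about 1.1/4.4 Hz; `measure_wavelet_fwhm()`
reports the measured values, and the package asserts monotone widening with
frequency rather than any printed spectral range.

Log power is `10*log10(|x|^2)` floored at 1e−12 to avoid `−Inf` on exact
zeros. Baseline correction subtracts the per-frequency mean log power over
(−1.5, −0.5) s per trial. `bootstrap_significance()` bootstraps the
across-trial mean per bin (percentile CI, n = 200 by default) for the
event-related spectral modulation maps.

## Single-trial N1 features

The N1 is the most negative local minimum of the 30 Hz low-passed activation
in (0, 300] ms after onset; trials without one are flagged, not errors.
Rejection is a single-pass ±3 SD rule on amplitude and latency *within
participant* (a zero SD rejects nothing). The 101-point ±500 ms grids are
sampled at 10 ms steps relative to the trial N1: time-domain values are
taken from the 30 Hz low-pass copy — the same signal in which the N1 is
defined — because log power of near-zero broadband samples is dominated by
noise; this is an interpretation (the source does not say which copy was
sampled) and `use_filtered = FALSE` switches to the raw activation.
Time-frequency values come from the baseline-corrected dB map by
nearest-sample lookup.

## Pooled regression and FDR

Cortical parameters are z-scored within participant across all trials (both
directions jointly), pooled over participants, and regressed per bin,
separately per sway direction, by ordinary least squares — no participant
random effects, which is faithful to the published analysis but means the
inference is conditional on the pooled-trials exchangeability caveat.
Coefficient t tests, the model F test, adjusted R² (with the $n-p-1$
denominator) and 95% CIs are reported per bin. P-values are
Benjamini–Yekutieli corrected, one family per coefficient across all bins of
one analysis (one direction × one domain); the source is silent on the
family definition, so the choice is recorded in the result metadata.
Degenerate bins yield `NA` and are listed, not fatal. The acceptance
experiments run the recovery regressions with normalization disabled so the
estimated coefficients are on the injected dB scale and directly comparable
to the ground truth.

## Problem sizes and numerical choices

The package's own validation experiments use: 11 simulated participants × 7
blocks (140 trials each) for the pipeline-level recovery experiment; 20
seeded two-block sessions for the ICA selection-rate experiment; 2,800
trials for the stepping-probability round trip; and 500 repetitions of a
300-trial × 606-bin null grid for FDR calibration. FastICA runs to a
convergence tolerance of 1e−4 (up to 500 iterations) — on generated data it
converges in a few dozen iterations, and the tolerance is far below the
sampling variability of the unmixing estimate. Filters are `signal`
Butterworth designs applied with `filtfilt`. Ties and degenerate cases are
handled explicitly: simultaneous foot crossings break left, zero-variance
features reject nothing, complete separation in the logistic fit warns and
returns boundary estimates, and constant regression responses report `NA`
determination coefficients.

## Known limitations

* The pipeline is validated on its own generative model; claims about
  laboratory EEG require the real recordings it was designed for.
* Pooled OLS ignores participant heterogeneity beyond z-scoring; a
  mixed-effects alternative is deliberately out of scope.
* Source localisation (dipole fitting, anatomical labelling) is not
  implemented — synthetic mixing has no geometry.
* The generator's stepping and latency laws are smooth and monotone;
  detection of non-monotone or saturating relations is untested.
* `signal::resample`'s polyphase filter has finite stop-band attenuation;
  resampling is validated to 1% amplitude fidelity in the passband, not to
  machine precision.
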