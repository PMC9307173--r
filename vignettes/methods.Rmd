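---
title: "Methods: synthetic narcoleptic sleep physiology and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic narcoleptic sleep physiology and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxsleep)
```

## Scope

`oxsleep` re-implements, as a tested pipeline over fully synthetic data, the
analysis chain used to evaluate OX2R-selective orexin-receptor agonism in
narcoleptic (orexin-knockout, OXKO) mice: vigilance-state simulation and
EEG/EMG synthesis, per-epoch spectral features, rule-based Wake/NREM/REM
staging, cataplexy-like episode detection, sleep-architecture metrics, the
conditioned-place-preference (CPP) score, and four-parameter logistic (4PL)
dose-response fitting with EC50, selectivity and potency ratios. No animal
data ships with the package; every in-vivo-style quantity is computed on
recordings the simulator generates, which is what makes each downstream
stage testable against a known ground truth.

## The vigilance-state simulator

`simulate_states()` is a semi-Markov chain at 1-s resolution over
{Wake, NREM, REM, Cataplexy}. Bout durations are gamma-distributed with
per-state mean and shape; shape 2 (default) avoids the pile-up of 1-s bouts
an exponential would give and keeps downstream epoch statistics stable.
Transitions: Wake ends in NREM; NREM ends in REM with probability
`rem_entry_prob` (default 0.2) and otherwise in Wake; REM returns to Wake.
Cataplexy is entered only from Wake, with hazard `cataplexy_hazard` per
hour of sustained wakefulness (default 3/h), and returns to Wake.

The defaults — mean bouts of 80 s (Wake), 100 s (NREM), 70 s (REM) over a
3-h dark-phase window — produce the short-bout, high-transition phenotype
of an orexin-deficient mouse: roughly 50 wake/NREM alternations and a few
cataplexy-like events per 3 h. The literature this emulates reports no
quantitative bout or spectral parameters for OXKO mice, so all numeric
defaults are this package's own conventions, chosen once to look like a
plausibly fragmented dark phase, and documented here as such.

Two deliberate features serve the detector's contract:

* **Decoy events.** 10% of cataplexy-channel events are preceded by only
  10–39 s of wakefulness (uniform), below the 40-s criterion. Without them
  the prior-wake criterion would have no true negatives to reject.
* **Ground-truth ledger.** The returned track carries every event the
  generator emitted (onset, duration, prior wake, decoy flag), so recall
  and precision are computable without re-deriving the truth.

A "drug" arm is a configuration transform, not a new generator:
`apply_drug_effect(cfg, 3, 0.2)` triples the mean wake bout and cuts the
cataplexy hazard to 20%, emulating the direction of an OX2R agonist's
effect on wake consolidation and cataplexy. Everything else is untouched,
so seed-matched vehicle/drug contrasts isolate exactly those two knobs.

## Signal synthesis

`synthesize_signals()` builds the EEG as a mixture of three band-limited
Gaussian noise carriers (delta 1–4 Hz, theta 6–9 Hz, fast 10–30 Hz),
generated by Fourier masking of white noise and normalized to unit RMS.
Per second, each carrier's amplitude is the square root of the current
state's band weight times the overall EEG RMS (50 µV default); amplitudes
are linearly interpolated between second midpoints, so state boundaries
cross-fade within one second. Filtered-noise mixtures were chosen over
autoregressive models because band powers — the exact features staging
uses — are then directly controllable. Default weights: Wake
(0.25, 0.30, 0.45), NREM (0.70, 0.15, 0.15), REM and Cataplexy
(0.15, 0.70, 0.15).

The EMG is Gaussian noise with per-state RMS: wake 30 µV (modulated
second-to-second by a lognormal factor with CV 0.3 — waking muscle tone is
bursty), NREM 10 µV, REM/Cataplexy atonia 2 µV.

What the generator does *not* emulate: circadian drift within the dark
phase, chocolate-triggered cataplexy clustering, infusion stress, scoring
artifacts (movement, electrode noise), and spectral nonstationarity within
a state. Passing tests therefore demonstrate that the pipeline's logic is
correct under controlled conditions, not that the stager would reach ~99%
agreement on real mouse recordings, where semiautomatic scoring exists
precisely because signals are messier.

## Spectral features

`epoch_features()` tiles the recording into half-open epochs (trailing
partial dropped) and averages periodograms of non-overlapping 1-s
rectangular windows, each mean-subtracted (DC rejection only, no taper).
A 1-s window has exactly 1-Hz resolution, so the thirty reported bins are
the periodogram ordinates at 1…30 Hz; delta = 1–4 Hz, theta = 6–9 Hz,
fast = 10–30 Hz. The 5-Hz bin belongs to no band, so band sums never
exceed the 1–30 Hz total. Scaling satisfies Parseval: the sum over all
positive-frequency ordinates equals the window variance, which an
independent summation oracle checks in the tests. The windowing scheme is
the simplest one delivering 1-Hz bins; it is a documented convention and
can be swapped without touching the staging logic.

Two EMG statistics are computed per epoch: the RMS over the raw samples,
and `emg_rms_median`, the median of the per-second RMS values. The
classifier uses the median. The reason is concrete: in a 20-s epoch
containing 12 s of NREM and 8 s of wake, the raw RMS is dominated by the
high-amplitude wake seconds and the epoch looks awake, whereas the
predominant-state rule says it is NREM. The median follows the majority
state and restores that behavior; switching to it raised ground-truth
agreement from ~92% to ~99% and is what makes the epoch-length properties
below hold on scored (not just ideal) hypnograms.

## Staging

`classify_epoch()` quantifies the standard qualitative criteria with
explicit thresholds, calibrated per recording (`calibrate()`: wake EMG
reference = 0.9 quantile of the epoch EMG tone; the upper EMG tail of a
dark-phase rodent recording is waking tone). Decision order:

1. **REM** if theta/delta ≥ 1.5 and EMG tone ≤ 0.2 × wake reference
   (atonia is the more specific condition, so it is tested first);
2. else **NREM** if delta/theta ≥ 1.5 and EMG tone ≤ 0.5 × reference;
3. else **Wake** — the total fallback, so every epoch gets a label.

No post-hoc smoothing is applied: smoothing would confound the
epoch-length comparisons, which depend on counting genuine short
interruptions. Ground-truth Cataplexy seconds map to REM for staging
comparisons; the three-state scoring alphabet is fixed, and separating
cataplexy from REM is the event detector's job.

`predominant_label()` implements the predominant-state rule for mixed
epochs; ties go to the previous epoch's state when it is among the tied
states (hypnogram continuity), else to the fixed priority
Wake > NREM > REM (a tie involving Wake in a narcoleptic dark phase is
more plausibly wakefulness).

**Epoch length.** Scoring at 20 s versus rescoring at 4 s has a known
systematic effect: longer epochs absorb brief interruptions, so mean
episode durations come out larger and total stage-transition counts
smaller, while group-contrast conclusions are unchanged. The tests assert
this per recording for the quantities the effect is actually about — wake
mean episode duration, overall mean episode duration, and total
transitions — and per state on battery means. The per-state inequality is
*not* asserted per recording for REM: with only ~10–15 REM episodes per
3-h dark-phase recording the sample means are noisy enough that even an
ideal predominant-rule scorer applied to ground truth occasionally
reverses the inequality, so asserting it per recording would test sampling
noise, not the effect.

## Cataplexy detection

`detect_cataplexy()` operates at 1-s resolution (a 10-s minimum duration
is sub-epoch at 20 s). A qualifying second has EMG at or below 0.2 × wake
reference *and* theta/delta ≥ 1.5. Maximal qualifying runs separated by
fewer than 2 s are merged; runs of ≥ 10 s whose immediately preceding
continuous wake run (tolerating non-wake gaps ≤ 1 s, which do not count
as wake) reaches ≥ 40 s are emitted as events. "Abrupt" onset is thereby
operationalized as wake-to-atonia with no intervening non-wake run longer
than 1 s. The front end (`detect_cataplexy_recording()`) smooths the
per-second EMG RMS with a 3-s running median before thresholding —
second-scale EMG dips inside a wake run would otherwise fragment the
prior-wake count — and takes wake flags from the same classifier used for
staging, applied to 1-s epochs. Events are counted by onset time within
the analysis window; latency to the first event is right-censored at the
window length when no event occurs.

The detector is verified two ways: exact equivalence with an independent
brute-force enumerator on 1,000 random 600-s flag tracks, and recall and
precision ≥ 0.9 against the generator's ground truth, with every decoy
(< 40 s prior wake) rejected.

## Architecture metrics and CPP

Totals per state are sums of epoch lengths; mean episode duration is total
time in a stage divided by the number of maximal same-label runs of that
stage, with window-truncated runs counted (the formula has no stated
exclusion). Transition counts cover the six ordered stage pairs,
including Wake→REM — direct wake-to-REM transitions are the narcolepsy
signature and are reported, not suppressed. Hourly profiles use 3600-s
bins aligned to the window start (the administration time); a wake episode
spanning an hour boundary is split at the boundary, and each hour's mean
wake episode duration divides the hour's wake seconds by its fragment
count. NREM delta power averages un-normalized delta (µV²) over
NREM-labeled epochs only. The CPP score is post-conditioning minus
pre-conditioning time on the drug-paired side, both bounded by the 900-s
test duration; negative scores (aversion) are legal.

Descriptive group summaries (means over seeds) are what the analysis
scripts report; inferential statistics (ANOVA and friends) are standard
library calls outside this package's contribution and are deliberately not
wrapped.

## Dose-response fitting

`fit_4pl()` fits response = baseline + (emax − baseline) /
(1 + (EC50/dose)^hill) by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on log10(dose). Initialization is deterministic
from the data (baseline = min, top = max, EC50 = dose nearest the
half-range response, hill = 1); bounds keep log10(EC50) within the dose
range widened by two decades and hill in [0.1, 10]. Replicates are fitted
pointwise. Flat curves are returned with `converged = FALSE` rather than
an error, and the ratio functions refuse unconverged fits. Whether the
original Prism analyses constrained asymptotes is unknowable from the
outside; the bounded 4PL is this package's documented convention, and the
tests pin down the properties that matter — ≤ 1% recovery on noiseless
curves for hill ∈ {0.5, 1, 2}, ≤ 15% median EC50 error at 5% noise with
triplicates, exact dose-scale equivariance, and response-scale invariance
of the ratios.

Fold-selectivity is EC50(low-affinity receptor) / EC50(high-affinity
receptor); the potency ratio is EC50(a)/EC50(b) at one receptor. From the
printed EC50s (AL-OXB: 58 nM at OX1R, 0.055 nM at OX2R; OXA: 0.50 and
0.20 nM) these give ≈ 1054-fold OX2R selectivity for AL-OXB, 2.5-fold for
OXA, and a 3.6-fold OX2R potency advantage of AL-OXB over OXA.

## Problem sizes and determinism

The routine battery is six seed-matched vehicle/drug pairs of 3-h
recordings sampled at 250 Hz — large enough for ~100 bouts and several
cataplexy events per arm, small enough to iterate on freely. Every
stochastic operation takes an explicit integer seed and restores the
caller's RNG state; two calls with the same seed are byte-identical, which
the tests assert. Property suites run 1,000 random cases under fixed
seeds. Recordings travel as a documented CSV dialect (comment-line
header with sampling rate and ZT origin, then `eeg`/`emg` columns);
state tracks, hypnograms, events and summaries are plain CSV.

## Known limitations

* The stager is tuned to the synthesizer's clean spectral contrast; real
  recordings need artifact handling the package deliberately omits.
* Cataplexy and REM are spectrally identical here; only the behavioral
  context (preceding wake) separates them, as in the three criteria.
* The simulator's hazard stands in for chocolate-triggered cataplexy;
  event clustering after palatable food is not modeled.
* Hourly wake-episode-duration binning splits episodes at hour edges;
  other conventions (assign-to-onset) would shift hourly values for long
  episodes.
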