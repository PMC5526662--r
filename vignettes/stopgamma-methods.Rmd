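---
title: "Methods: stop-signal tapping electrophysiology with stopgamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stop-signal tapping electrophysiology with stopgamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental model

`stopgamma` analyses recordings from a stop-signal finger-tapping
paradigm: a participant taps in synchrony with an isochronous metronome
(900 ms interval), and after a random 5–9 taps an auditory stop cue —
delivered a fixed ~707 ms after the last registered tap — instructs
immediate interruption of the upcoming tap. Because taps anticipate the
metronome (negative tap-to-sound offsets), the movements are
self-initiated rather than cue-triggered, and the cue timing makes
stopping succeed in only ~55% of attempts. Stopping performance is
graded: the post-cue downward excursion of a finger-flexion
(goniometer) trace, as a percentage of the preceding upward movement,
is the *movement extent* (0% = full stop, ~100% = failed stop, i.e. the
pressure sensor was touched).

The electrophysiological question is how subthalamic (STN) local field
potentials and scalp EEG respond in the short window between the cue
and the time the tap would have occurred (the *stopping window*,
operationalized per dataset as the mean latency of unsuccessfully
inhibited taps after the cue, ~156 ms). The package implements the full
chain: signal conditioning, behavioral scoring, Hilbert-filterbank
time-frequency power, bipolar contact selection, intersite phase
clustering (ISPC) connectivity, and cluster-based permutation group
statistics — plus a synthetic-data generator so that every stage can be
validated against known ground truth without patient recordings.

## Signal conditioning

* **DC removal** — first-order IIR high-pass with RC = 2 s, applied
  forward only. A forward-only filter mirrors acquisition-style AC
  coupling; no zero-phase property is claimed for this stage. The
  first/last `2 * RC` seconds are flagged as edge regions and epochs
  may not touch them.
* **Re-referencing** — linked earlobes when earlobe channels exist,
  otherwise the common average of the six scalp channels (EOG, EMG and
  LFP channels are never part of the reference).
* **Bipolar derivation** — differences of neighbouring depth-electrode
  contacts; the montage with the strongest movement-locked 60–90 Hz
  modulation is selected (below).
* **Resampling** — FFT-domain resampling to 1000 Hz. The installed
  polyphase routine showed ~3% amplitude error and phase drift at this
  rate ratio, so the package uses spectrum truncation with reflection
  padding, which is exact for band-limited content (tone amplitude
  preserved to <1%).
* **EOG regression** — the EOG is low-pass filtered (40 Hz Butterworth
  order 6, forward–backward) and subtracted from each EEG channel after
  amplitude matching. The matching scale is the closed-form
  least-squares projection `<eeg, e> / <e, e>`; an iterative optimizer
  finds the same optimum, so the closed form is used for exactness and
  reproducibility. One scale per channel over the whole recording, and
  the regression runs after re-referencing. With short recordings the
  chance correlation between slow (1/f) components of EEG and EOG
  limits how close to zero the scale can be under a blink-free null;
  the test suite checks the scale against the injected leakage rather
  than against exactly zero.
* DC removal is applied to electrophysiology channels only; pressure
  and goniometer channels keep their baselines, which tap detection
  and movement-extent scoring rely on.

## Time-frequency power

Power is computed with a Hilbert filterbank: 3 Hz-wide bands stepped by
1 Hz covering 3–40 Hz, and 10 Hz-wide bands stepped by 2 Hz covering
50–120 Hz. Each band is an order-6 Butterworth **band-pass** applied
forward–backward; this design has unit gain at band center (a cascade
of separate order-6 low- and high-pass filters would attenuate a
10 Hz-wide band's center by ~50% in amplitude and make envelope
amplitudes uninterpretable). "Power" is the squared magnitude of the
analytic signal; a flag exposes the plain envelope for sensitivity
analyses. Power is smoothed with a centered 100 ms moving average and
decimated to 200 Hz. High-band filtering happens at 1000 Hz before the
decimation, as 120 Hz content cannot exist at a 200 Hz rate. A centered
(rather than causal) smoothing window is assumed; this choice can shift
apparent latencies by up to half the window.

Epochs are cut half-open around three alignments: the stop cue, tap
onsets, and the *virtual stop* — the previous tap plus the stop delay,
i.e. where the cue would have fallen had it come one tap earlier. Every
map is converted to percent change relative to the per-frequency mean
power over all regular-tap epochs, excluding the first tap and the last
tap before each cue; this normalization makes differently sized
electrode contacts and references comparable across subjects.

**Bipolar selection.** For each candidate bipolar the median 60–90 Hz
power time course across taps is computed in a window spanning twice
the tapping interval around each tap, and the modulation index
`(max − min) / mean` ranks the candidates; the montage with the largest
index is analysed. For a time course `m + (r/2)·cos`, the index is
exactly `r/m`.

**Peak latency** is the argmax of a band time course within a search
window, ties resolving to the earliest sample. The success/fail peak
comparison searches 0–300 ms: failed-stop bursts peak near 179 ms,
beyond the ~156 ms stopping window, so the search window must extend
past it.

## Intersite phase clustering

ISPC between the contralateral STN seed and EEG targets is the modulus
of the mean unit phasor of instantaneous phase differences,
`|Σ e^{i(φ_STN − φ_EEG)}/n|`, computed per trial over fixed-width
windows slid in 10 ms steps (200 ms width for 50–120 Hz, 250 ms for
6–40 Hz; bands below 6 Hz are excluded because 250 ms would hold barely
one cycle). Windows are timestamped at their centers. Trial-averaged
maps are normalized by subtracting the per-frequency mean over the
−350–0 ms pre-cue baseline; subtraction keeps the no-change null at
zero for the against-zero cluster test (a ratio mode exists behind a
flag). Averaging precedes normalization.

A caution for interpreting null levels: for band-limited signals the
phase difference decorrelates on the inverse-bandwidth timescale, so a
200 ms window contains only a few effective samples and the
independent-channel ISPC sits near 0.5 — far above the i.i.d.
`√π/2·n^{-1/2}` floor, which applies only to white phase differences.

## Group statistics

Per pixel, a paired t-statistic over subjects is mapped to a z-score
via the probit of its two-sided p-value (the sum over a cluster is then
a "z mass"; a raw-t mass is available behind a flag). Suprathreshold
pixels (|z| above the two-sided p < 0.05 threshold) form 4-connected
clusters, positive and negative separately. The null distribution
collects the single largest absolute cluster mass per permutation under
subject-level sign flips (2000 by default), giving max-statistic
family-wise control; `p = (1 + #{null ≥ |mass|}) / (n_perm + 1)`, so p
is bounded below by `1/(n_perm+1)`. Two-sided by default; a one-sided
flag exists. Correlation analyses use Spearman's rho with percentile
bootstrap CIs, per-subject coefficients are Fisher-z transformed and
t-tested against zero at the group level, and families of tests are
BH-FDR corrected. Paired comparisons fall back from the t-test to the
Wilcoxon signed-rank test when a Lilliefors test rejects normality of
the differences (the established `nortest` implementation is used).

The permutation inner loop and cluster labeling, and the bootstrap
resampler, are compiled (Rcpp) — the type-I-error validation alone
labels ~125 million pixels. Both consume R's RNG, so `set.seed()`
reproduces them bit-exactly.

## The synthetic-data generator

`simulate_behavior()` draws, per trial: 5–9 metronome-paced taps with
Gaussian anticipatory jitter (mean offset −30 ms, SD 40 ms), a stop cue
at last tap + stop delay, a Bernoulli(0.55) stopping outcome, a latent
movement extent per class (full < 10%, intermediate 10–80%, failed
90–100%), and — in failed trials — the inhibited tap at last tap +
N(864, 36) ms, putting it ~156 ms after a 707 ms cue and thereby
defining the stopping window. Per-subject stop delays are drawn from
N(707, 49) ms, and 3 of 9 subjects tap left-handed.

`simulate_signals()` builds 12 channels at 2048 Hz: 1/f background
(exponent 1) on all electrophysiology channels; movement-locked beta
(20 Hz) amplitude reduction and a broad 40–95 Hz gamma increase on the
contralateral motor channels around each tap; an outcome-coupled gamma
burst at 70 Hz on the contralateral STN after each cue (Gaussian
envelope, FWHM 90 ms, peaking 106 ms post-cue on successful and 179 ms
on failed stops, trial SD 25 ms); a slow 4 Hz evoked wave at Cz after
every cue regardless of outcome; blinks (Poisson, 8/min) on EOG leaking
into the EEG with per-channel coefficients; a goniometer trace whose
post-cue descent is truncated at the latent extent; pressure pulses for
every registered tap; and EMG bursts wherever a movement is executed.

Choices worth explaining:

* **Burst waveform** — an amplitude-modulated sinusoid under a Gaussian
  envelope makes peak latency well-defined for recovery tests.
* **Amplitude calibration** — burst amplitudes are expressed in units
  of the broadband background SD. `amp_success = 1.2` was calibrated so
  the success-vs-fail gamma contrast reproduces the published effect
  size of this paradigm (Cohen's d ≈ 1.2 averaged over the
  window of interest, ≈ 2.6 at its maximum) on a 9-subject cohort;
  `amp_fail = 0.45` keeps the late failed-stop burst measurable while
  preserving the graded full > intermediate > failed pattern. Burst
  amplitude interpolates linearly with movement extent, which induces
  the negative extent–gamma correlation the analysis searches for;
  burst latency is class-based, not extent-interpolated, so the
  configured 106/179 ms latencies are recoverable. Trial-to-trial
  amplitude variability (log-normal, σ = 0.2) is a free parameter: the
  paradigm's literature does not constrain it.
* **Connectivity** — a shared narrow-band 70 Hz component links the STN
  and contralateral M1. After each cue the STN side crossfades
  (power-preserving) to an independent same-band component for 250 ms:
  the phase relation collapses while band power is unchanged. Gating
  the shared component off instead would imprint a spurious post-cue
  power *decrease* on the STN — a confound, since the paradigm's
  stop-related power change is an increase.
* **What is not emulated** — volume conduction, biophysical neural-mass
  dynamics, non-stationary background spectra, line noise, electrode
  drift and movement artifacts beyond blinks. Passing recovery tests
  therefore demonstrates correctness of the analysis chain under the
  model's statistical structure, not robustness to every artifact class
  of real recordings.

## Numerical choices and degenerate inputs

* Half-open windows `[start, end)` everywhere; times in seconds
  internally, milliseconds for display.
* Peak-latency ties resolve to the earliest sample; flat series
  therefore report the window start.
* Zero across-subject variance at a pixel maps to a guarded |z| of 37
  and is flagged; all-zero differences give an empty cluster result.
* Zero-variance EOG yields scale 0 with a warning; a degenerate upward
  movement flags the trial rather than producing an extent.
* `|rho| = 1` subjects are excluded (with a warning) from Fisher-z
  group tests; all-equal rhos short-circuit to t = 0, p = 1.
* Subjects missing an outcome class are dropped from paired contrasts;
  recordings without EEG skip the EEG-specific stages.

## Problem sizes used in validation

The test suite runs the full pipeline on scaled-down cohorts chosen as
the package's validation conditions: 9 subjects with 10–12 stop trials
each for effect/latency recovery (20 seeded replicates per condition),
500 null datasets x 500 permutations on a 40 x 50 grid for the
family-wise error calibration, and 2000 datasets of n = 60 pairs for
bootstrap CI coverage. Generator physiology (sampling rate, timing,
effect sizes) keeps its defaults in all of them; only cohort/trial
counts and permutation counts are scaled. The reported behavioral
means (~55% success, ~707 ms delay, ~156 ms stopping window, ~864 ms
pre-failed-tap interval) follow directly from the generator's
configured conditions. Latency recovery is asymmetric: the strong
successful-stop burst yields group-mean estimates within a few ms of
the configured 106 ms, while the weaker failed-stop burst makes the
argmax latency a high-variance statistic at desk-scale trial counts —
consistent with the wide across-subject peak-latency spreads this
paradigm reports, and the reason the failed-stop latency check is the
strictest test in the suite.

## Known limitations

* The arrhythmia exclusion replaces the original visual inspection of
  spurious goniometer deflexions with a threshold rule; an optional
  amplitude-outlier proxy is deliberately conservative.
* The EOG scale is estimated once per recording; slow drifts in blink
  amplitude are not tracked.
* ISPC window widths trade temporal resolution against cycle counts;
  results below ~6 Hz are undefined by design.
* The cluster test controls family-wise error per contrast, not across
  the set of contrasts run in a pipeline invocation.
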