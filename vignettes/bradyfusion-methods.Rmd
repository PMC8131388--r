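---
title: "Detecting neonatal bradycardia early: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neonatal bradycardia early: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bradyfusion)
```

## The problem

Preterm infants in intensive care are continuously monitored; apneas
lead to desaturation and then bradycardia, and the heart-rate alarm is
in practice the most reliable trigger for intervention. A threshold
alarm is inherently late: the heart rate must already be below the
alarm level, and confirmation logic adds seconds. This package
implements an online detector meant to fire earlier at equal
reliability: three beat-by-beat detectors with complementary behavior,
fused by majority vote. Everything operates on the RR tachogram
`RR(k) = t(k+1) − t(k)` in milliseconds; heart rate is `60000/RR` bpm.
An interval is *stamped at the beat that closes it* — a real-time
system only knows an interval once its second beat has been observed —
so every statistic below is causal by construction.

## The three detectors

**Fixed threshold.** The current run of consecutive intervals with
`RR > U0` is tracked; the alarm level is 1 while the run's cumulative
duration (the sum of its intervals) exceeds 4 s *and* at least two of
its intervals exceed the confirmation threshold `U1`. The run — and the
alarm — resets at the first interval at or below `U0`. Two published
operating points are bundled in `detector_config()`: red
(`U0 = 750`, `U1 = 800` ms, targeting HR < 80 bpm) and yellow
(`U0 = 600`, `U1 = 640` ms, targeting HR < 100 bpm). Two readings of
"for more than 4 s" are possible (wall clock vs. accumulated beat
intervals); we accumulate the run's own intervals, which keeps the
detector purely beat-driven, and count the two confirmation intervals
anywhere in the run rather than in a sliding sub-window.

**Relative adaptive threshold.** Identical run logic, but
`U0'(k) = 1.33 × RR_mean(k)` with `RR_mean(k)` the mean of the
intervals stamped in the half-open window `[t(k) − 20 s, t(k))` — the
current interval is excluded, reading "values preceding beat k"
strictly. An infant with a basal rate of 160 bpm (375 ms) gets an
effective threshold near 500 ms, so the run starts much earlier in the
deceleration than the fixed rule's 750 ms. The detector is disarmed for
the first 20 s of a record (one full window of history); a cold-start
convention the rule itself does not define.

**Page-Hinkley.** The bradycardia is modeled as an upward jump of size
`ν` in the mean of a piecewise-constant-plus-noise RR series. The
generalized likelihood ratio test for an unknown jump time reduces to
the classic cumulative-sum recursion: per beat,
`Λ ← Λ + RR(k) − RR₀(k) − ν/2`, `m ← min(m, Λ)`, alarm when
`Λ − m ≥ λ`. The baseline `RR₀(k)` is the trailing 290 s mean (same
half-open convention); `λ = 717`, `ν = 415 ms`. Until enough history
exists the increment degenerates to `−ν/2`, pinning the statistic at
its floor. Two behaviors are underdetermined by the recursion alone and
fixed here: after an alarm the statistic resets (`Λ = m = 0`) and the
level stays raised until the first beat with `RR < RR₀ + ν/2`, which
re-enters accumulation — this "latch" prevents continuous re-alarming
inside a single event; and the baseline mean keeps updating during an
evolving event (no freezing clause; with a 290 s window the
contamination from a 20 s event is below 2 ms). Both detectors' trailing
means are recomputed every beat, and the streaming recursion is tested
beat-for-beat against the direct `max_t Σ_{k=t..n}` formulation.

Only one Page-Hinkley triple is published, so the red and yellow
configurations share it; the threshold detectors differ between tiers.

## Fusion

The fused level at beat k is 1 iff at least 2 of the 3 local levels are
1 (`Σ d_i > n/2`). Votes are taken on the per-beat *level* signals, not
on point detections with a simultaneity window: the majority rule is
instantaneous, needs no extra parameter, and makes the fused detection
time exactly the second order statistic of the local rise times — the
property the early-detection claim rests on. Traces must share a beat
grid (they do when produced from one RR series); fusing traces from
different grids is rejected rather than resampled.
`attribute_detections()` labels each fused detection with the set of
detectors active at that instant, computed *at the detection instant*
(not over the whole event), which is the natural reading for an
instantaneous vote.

## Event annotation

Two threshold definitions are used for ground truth: `B100_5`
(HR < 100 bpm for at least 5 s) and `B80_10` (HR < 80 bpm for at least
10 s, "severe"); severe events are by construction a subset of the
yellow-tier events. HR is the instantaneous `60000/RR` per beat; a
sub-threshold run spans from the *start* of its first interval to the
beat closing its last, i.e. elapsed time between first and last
sub-threshold beat plus one interval.

Real bradycardias are often multiphasic: the HR re-crosses 100 bpm
briefly between dips. Runs separated by a recovery shorter than 10 s
are merged into one event (`n_phases` counts the dips). The recovery is
measured at the 100 bpm level for *every* definition: between two
sub-80 dips, only time spent at or above 100 bpm counts as recovery, so
a dip pair bridged by a 90 bpm plateau remains a single severe event no
matter how long the plateau — the clinically sensible reading, since
the heart rate never actually recovered. `merge_gap = 0` disables
merging.

Clinical significance (`classify_clinical()`): severe events always;
yellow-tier events only with apnea and an SpO2 drop of at least 10
points, and never when explained by low basal heart rate or
periodic-breathing oscillations.

## Sigmoid onset adjustment

Manual onset annotations jitter by seconds. `adjust_onset()` fits
`f(t) = A + B/(1 + exp(−(t − t0)/s))` to the RR series in a ±15 s
window around the annotation (Levenberg-Marquardt via `minpack.lm`) and
moves the onset to the first point where `f'(t) > 1`. The derivative
threshold is read in **ms/s** — RR in ms against time in s is the only
unit pairing under which a threshold of 1 is meaningful for decelerations
of hundreds of ms over a few seconds. The crossing is computed in
closed form: `f'(t) = (B/s)·u(1−u)` with `u` the logistic, so
`u = (1 − sqrt(1 − 4s/B))/2` and `t = t0 + s·log(u/(1−u))`; the smaller
root is the earliest crossing. When the fit is degenerate or the
maximum slope `B/(4s)` never reaches 1, the annotation is returned
unchanged with a warning. Starting values (window-third means for `A`
and `B`, steepest finite difference for `t0`, `s = 1 s`) are a
pragmatic choice that converges on every morphology the generator
produces. Offsets are adjusted by applying the same procedure to the
time-reversed recovery; the stamping convention flips by one beat under
reversal, which is below the annotation jitter being corrected.

## The synthetic cohort

No public data set of annotated preterm RR recordings with event-level
ground truth exists, so validation uses a seeded generator
(`simulate_cohort()`) whose defaults define the study conditions used
throughout the tests and the acceptance script:

- 50 records of 20 min; basal HR drawn per record from 155 ± 10 bpm;
- beat-to-beat RR noise: AR(1), coefficient 0.8, stationary sd 10 ms —
  a realistic short-term variability magnitude for preterm infants —
  clipped to [250, 600] ms at baseline;
- severe events at 6/h (≈ 2 per record, ≈ 100 per cohort), nadir
  55–75 bpm, 15–25 s below 100 bpm, shaped as double-logistic
  descent/plateau/recovery with a 0.8 s transition scale;
- morphology mix 66/24/10 % mono/bi/triphasic (roughly a third of
  observed events are multiphasic), inter-phase recoveries of 4–8 s;
- sensor artifacts at 5/h (missed beat → doubled RR, spurious beat →
  split RR), placed away from events;
- periodic-breathing HR oscillation (10–15 s period, 5–15 bpm
  amplitude) in 30 % of records;
- SpO2 at 1 Hz with desaturations of ≥ 10 points beginning 2–5 s before
  each flagged event's onset (desaturation precedes bradycardia);
  deep events always flagged, shallow ones with probability 0.5.

Ground truth is computed *analytically* from the continuous injected
profile (threshold crossings by root finding, the adjusted onset from
the closed-form slope-1 crossing of the descent), not from the realized
beats, so the round-trip test — `find_events()` recovering every
injected event with onsets within one beat — is a genuine check of the
annotation logic against an independent description of the event.

What the generator does **not** emulate: real QRS-detection error
structure (only isolated missed/spurious beats), movement-artifact
bursts, autonomic variability beyond AR(1) + sinusoid, feeding or
handling context, or drift in basal rate within a record. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not clinical performance; the published clinical
figures (sensitivity ≈ 95–98 %, FAR ≈ 64 %, delays ≈ 10–13 s on real
NICU recordings) are not reproducible from synthetic data, and the
cohort-level acceptance checks accordingly assert *directions* (fusion
at least as sensitive, not more false-alarm-prone, significantly
earlier), not magnitudes.

## Evaluation protocol

Detections within `[onset − 5 s, onset + 30 s]` are true positives;
duplicates within one window are ignored (first wins); one detection
serving two annotations yields one TP and the second annotation is
ignored; everything else is FP/FN. Matching is greedy in time order —
with a 30 s separation enforced between generated events, window
overlaps are rare and a globally optimal assignment would coincide.
Delays are reported against the *adjusted* onsets. The 1512 ms
acquisition/QRS latency of a real-time chain is added to algorithmic
detection instants. In the synthetic benchmark both the monitor-like
baseline and the fusion detector run on the same RR series through the
same simulated chain, so both receive the same compensation — the
comparison is then a pure algorithm comparison, and any constant
latency cancels in the paired delay difference. (For detections
captured at a physical monitor's alarm output, set `latency = 0` for
that detector in `benchmark()`.) Delay comparisons use the two-sided
Wilcoxon signed-rank test on common TPs at α = 0.05, as delay
distributions are not normal.

## Problem sizes and numerical tolerances

The test suite checks streaming/oracle equivalence on 100 random series
of 150 beats, the Page-Hinkley recursion against the exhaustive
change-point formulation on 200-beat series, the closed-form slope
crossing on 1000 random noiseless sigmoids (tolerance 1e-6 s; observed
agreement is at machine precision), parameter recovery under 5 ms noise
over 100 seeds (< 5 % mean relative error), and the cohort-level
benchmark on the 50-record default cohort — all within a couple of
minutes on one CPU. Floating-point comparisons of beat grids use a 1e-9 s
tolerance; window membership is half-open `[t − w, t)` everywhere, so a
beat exactly at the window edge belongs to the older window.

## Known limitations

- The adaptive and Page-Hinkley baselines are not frozen during
  suspected events; on very long events (minutes) the contaminated
  baseline would slow re-detection. The published description gives no
  freezing rule, and the windows are long enough that the effect is
  negligible at realistic event durations.
- Only one Page-Hinkley parameter set is used for both alarm tiers.
- The clinical-significance rule takes apnea and desaturation as given
  flags; no apnea detection from respiratory signals is attempted.
- `n`-detector fusion is implemented for general `n` but exercised only
  at `n = 3`.
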