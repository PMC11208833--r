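---
title: "Methods: autonomic sleep staging and trial statistics in somnohrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic sleep staging and trial statistics in somnohrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnohrv)
```

## The problem

Wearable chest sensors can record two streams during a night of sleep: the
R-R interval (RRI) series — the time between successive heartbeats, at
millisecond resolution — and 3-axis acceleration at 125 Hz. From these two
streams alone, somnohrv derives a per-minute picture of autonomic nervous
activity (the LF/HF heart-rate-variability indices), an actigraphic estimate
of when the wearer fell asleep and how long they slept, a three-stage
autonomic hypnogram, and group-level trial statistics of the kind reported
in small sleep-intervention studies (two groups, repeated measurement days).

Because studies of this kind rarely release participant recordings, the
package ships a first-class synthetic-data module: every downstream stage is
validated against recordings with known ground truth, and all quantitative
claims made by the test suite are claims about that generator's output.

## Heart-rate variability model

The spectral engine operates on the *tachogram*: RR as a function of time,
resampled to a uniform 4 Hz grid (cubic spline through the clean beats).
Per non-overlapping 60 s window it computes a mean-removed, Hann-tapered
FFT periodogram with power normalization — the PSD is scaled by
`1 / (fs * sum(w^2))` so that band integrals estimate variance in ms².
Band powers are Riemann sums over half-open frequency bins:

* LF: 0.05 ≤ f < 0.15 Hz (joint sympathetic + parasympathetic drive),
* HF: 0.15 ≤ f < 0.40 Hz (parasympathetic, respiratory sinus arrhythmia).

The half-open assignment means the 0.15 Hz boundary bin belongs to HF and
LF + HF equals the power of the combined 0.05–0.40 Hz band exactly; with a
rectangular taper the sum over all bins equals the windowed-signal variance
to machine precision (Parseval). We use the Riemann sum rather than a
trapezoid over the selected bins because only the sum preserves these two
invariants; a trapezoid half-weights the edge bins and breaks additivity.

Per minute the engine reports the band powers, their square-root-of-integral
amplitudes `lf_amp = sqrt(lf_power)` (ms) — the smoothed "LF value"/"HF
value" used for reporting — and the LF/HF power ratio. When the HF power of
a window falls below 10⁻¹² ms² the ratio is undefined and the frame is
marked invalid instead of propagating an infinity. Per-night summaries
average the per-minute ratios (not the ratio of mean powers); the
alternative convention is available via `ratio_of_amplitudes` and the raw
powers are always carried alongside.

Numerical choices: 60 s windows give a frequency resolution of 1/60 Hz — the
LF band spans 6 bins, the HF band 15 — with no zero-padding; the Hann taper
keeps leakage from the strong LF components out of the HF band across the
0.15 Hz boundary; a rectangular-taper mode exists mainly so tests can use
exact Parseval identities.

## Preprocessing

Two artifact mechanisms are handled separately and never alter data values,
only per-interval flags:

* **Body movement.** An interval is flagged when any gravity-removed
  acceleration-magnitude sample within its span reaches 0.5 g. Gravity is
  taken as the per-axis median over the recording (a constant for a sensor
  in fixed orientation).
* **Ectopic / outlier beats.** Intervals outside 300–2000 ms, or deviating
  more than 20% from the median of the five previous accepted intervals,
  are flagged. This physiological screen is standard HRV practice; its
  thresholds are config-exposed.

Flagged intervals are excluded from the spline support, and tachogram grid
points farther than 5 s from any clean beat are masked. A 60 s window is
analyzed only if at least 80% of its grid points are valid; within an
accepted window, masked points are replaced by the window mean (zero after
mean removal) rather than spline extrapolations. The rationale throughout
is to avoid fabricating data across movement bouts: a window dominated by a
movement gap yields no spectral frame at all. Whether a vendor device
deletes or interpolates artifacts is generally unknown; exclusion is the
default here.

Timing convention: interval *i* spans `(t_{i-1}, t_i]` with the first
interval starting at t = 0; the movement check uses the half-open span
`[t_{i-1}, t_i)` so each acceleration sample belongs to exactly one
interval.

## Actigraphy

Activity counts per 60 s epoch are zero crossings of the band-passed
(0.25–3 Hz, 4th-order zero-phase Butterworth) gravity-removed acceleration,
ignoring excursions inside a 0.01 g dead zone. The crossing count is taken
on the signed sum of the three band-passed axes rather than on the unsigned
magnitude: rectification doubles the frequency of an in-band oscillation and
pushes it outside the pass band, which would destroy the 2-crossings-per-
cycle property the count is meant to have.

Sleep/wake scoring uses the published one-minute weighted-sum equation

\[ D_t = 0.001\,(106 A_{t-4} + 54 A_{t-3} + 58 A_{t-2} + 76 A_{t-1}
        + 230 A_t + 74 A_{t+1} + 67 A_{t+2}), \]

epoch *t* scored sleep iff `D_t < 1`, with zero-padding at the record
boundaries. The kernel, scale and threshold are injectable, since vendor
implementations differ (10 s vs 60 s epochs, rescoring rules); no
wake-after-sleep rescoring is applied by default. Sleep onset is the first
epoch opening a run of ten consecutive sleep-scored epochs — a persistence
rule that suppresses transient false sleep during quiet wakefulness — and
total sleep time counts sleep epochs at or after onset.

## Autonomic sleep staging

During scored sleep, each minute with a valid spectral frame is assigned to
one of three stages:

1. **S sleep** (sympathetic dominance) when `lf_hf >= theta_s`;
2. otherwise **deep PS sleep** when `hf_amp` is at or above a per-night
   depth threshold;
3. otherwise **shallow PS sleep**.

Both thresholds adapt per night, making the rule robust to the large
between-subject differences in absolute HRV scale. `theta_s` defaults to 4
times the night's median sleep LF/HF: most sleep minutes are
parasympathetic, so the median sits inside the PS cluster, roughly an order
of magnitude below the S-sleep cluster, and a multiplier of 4 lands in the
gap between them. (A multiplier as low as 1.5 sits *inside* the shallow-PS
cluster — its LF/HF spread reaches past 1.5× the median — and mislabels a
quarter of shallow sleep; this was measured on the generator's pure-stage
distributions.)

The depth threshold is the midpoint of a 2-means split of the night's
PS-epoch HF amplitudes. A fixed quantile (the natural first idea, retained
as `theta_d_method = "quantile"`) force-labels a fixed share of sleep as
deep regardless of the night's true mix; since the deep fraction varies
substantially from night to night while the shallow/deep HF clusters are
far apart, the cluster split is both more accurate and more honest about
what it estimates. When the two centres are not clearly separated (relative
gap < 0.2 — a night without deep sleep, or a degenerate constant-amplitude
input) the rule falls back to the 0.60 quantile.

Minutes with invalid frames inherit the previous minute's label (shallow PS
when there is none yet); minutes before onset or scored wake are labelled
WAKE. Stage minutes therefore always sum exactly to total sleep time.

The three-stage rule itself is an explicit operationalization: the field
method it follows describes staging "based on the autonomic balance" without
publishing an equation, so all staging validation here is ground-truth
recovery on synthetic nights, never a literature value.

## Trial statistics

The comparison scheme mirrors a two-group (Mi = intervention, nMi =
control), three-day (1, 5, 9) design:

* **Between groups** per day and measure: two-tailed t tests (Welch by
  default; the pooled-variance Student variant is available since standard
  software reports both) and Pearson correlations as effect sizes.
* **Within groups**: one-way ANOVA and Games–Howell post-hoc contrasts —
  for each pair, `SE = sqrt(s_i^2/n_i + s_j^2/n_j)`,
  `q = |mean_i - mean_j| * sqrt(2) / SE`, Welch–Satterthwaite df, and p from
  the studentized-range distribution with k groups. `stats::ptukey`
  performs that integration; for Welch df below 2 (reachable when a pair
  has n = 2) it is undefined and the package integrates the range CDF
  directly.
* **Bonferroni recheck**: adjusted values are the raw product `p * k`,
  uncapped by default, matching the reporting convention of printing values
  above 1 (equivalently, testing against α/k); capping is available.

At k = 2 Games–Howell collapses to the Welch t test and ANOVA's F equals
the squared pooled t — identities the suite verifies, alongside a
numerical-quadrature oracle for the studentized-range p and null
simulations calibrating each test's type-I error.

One reporting convention cannot be recovered from the trial literature this
mirrors: a Pearson r between two *independent* groups requires a pairing
rule. The builder pairs subjects by within-group order and reports NA for
unequal group sizes; the column should be read as a convention, not an
estimand.

## The synthetic-data generator

The generator is deliberately the simplest model that realizes the features
the pipeline measures:

* **Stage dynamics**: a first-order Markov chain over {WAKE, S, shallow PS,
  deep PS} with ~2-minute dwell times, a stationary sleep mix of roughly
  20% S / 46% shallow / 34% deep, and rare mid-sleep wake re-entry (~0.3%
  per epoch, one or two brief arousals per full night, the low end of
  healthy young sleepers). A configurable onset latency forces leading
  wake.
* **RRI**: `RR(t) = mean_rr + A_LF(stage) sin(2π f_LF t) + A_HF(stage)
  sin(2π f_HF t) + ε`, carriers at 0.10 and 0.25 Hz, rounded to integer
  milliseconds; an additive tachogram-domain model rather than an
  integral-pulse-frequency-modulation point process, because it is
  analytically checkable (band powers are `A²/2` by Parseval). Default
  amplitudes give S sleep a strongly LF-dominant signature, shallow PS a
  mildly HF-dominant one, and deep PS the largest HF amplitude. Mean RR is
  900 ms; the beat-noise SD default is 15 ms — note that beat noise,
  resampled onto the 4 Hz grid, concentrates below the beat Nyquist
  (~0.55 Hz) and therefore raises both band powers, which is why the
  default was calibrated against the realized per-stage index
  distributions rather than set blind.
* **Accelerometry**: constant 1 g gravity on one axis plus Hann-enveloped
  2.5 Hz movement bursts, Poisson per epoch: frequent, large, long in wake
  (1.5/min, 0.3–0.7 g, 0.8–1.4 s) and rare, small, brief in sleep
  (0.06/min, 0.03–0.12 g, ≤ 0.35 s — the regime of small posture shifts,
  chosen so a lone sleep movement stays below the wake threshold of the
  scoring kernel). Every burst is returned as ground truth.
* **Cohorts**: per-(group, day) amplitude multipliers impose intervention
  effects; a per-subject lognormal multiplier (CV 0.10) adds
  between-subject heterogeneity, constant across days as in a
  repeated-measures design. All randomness derives from one master seed
  through a documented arithmetic, so any single night is reproducible in
  isolation.

What the generator does *not* emulate: respiration and its coupling to HF
(the HF tone is a fixed carrier, not a respiratory signal), circadian and
ultradian cycle structure (stage dwell is memoryless), apnea, ectopic-beat
physiology (the ectopic filter is tested by explicit injection), sensor
drift, and any effect of the intervention beyond amplitude scaling.
Passing recovery tests therefore demonstrates that the pipeline measures
what this model encodes — not that it would reach the same accuracy on real
recordings.

## The effect-recovery experiment

`lf_decline_design()` encodes the power experiment: n = 9 per group,
days 1/5/9, the intervention group's LF tone amplitude declining
30 → 20 → 15 ms (S stage; all stages scaled proportionally) against a flat
control. Two of its parameters differ from the generator defaults, by
design: the beat-noise SD is 6 ms so that the spectral noise floor does not
swallow the smallest (5 ms) amplitude step, and the between-subject CV is
0.06 so that the configured steps correspond to standardized effects in the
strongly significant regime such trials report. Nights are 60 min and skip
accelerometry (summaries are taken over the ground-truth hypnogram): the
experiment probes the spectral-plus-statistics chain, and the per-night LF
summary is stable well below a full-night duration.

## Problem sizes

The suite and the acceptance script size their simulations to run on one
CPU in minutes: onset recovery uses 50 nights of latency + 60 min, staging
recovery 20 nights of 110 min with the full accelerometry chain, null
calibration 200–1000 replicates of 3 × 9 normal samples, and the
effect-recovery experiment 50 cohorts of 54 sixty-minute nights. Full-night
(420 min) cohorts run through exactly the same code paths via
`run_pipeline()`.

## Known limitations

* The staging rule is an operationalization; against real
  polysomnography-scored nights its two thresholds would need re-tuning,
  and nothing here validates it against EEG.
* The Cole-family scoring coefficients were fit to wrist actigraphy; a
  chest-worn sensor sees different movement statistics, which is part of
  why every coefficient is injectable.
* Games–Howell p values at very small df (< 2) rest on a direct numerical
  integration whose accuracy target (~10⁻⁴) is far below any decision
  threshold used here, but extreme-tail values in that regime should not be
  over-read.
* The between-group Pearson column depends on an arbitrary pairing
  convention (see above).
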