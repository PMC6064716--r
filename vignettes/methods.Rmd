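---
title: "Methods: quietest-period Z-scores, epoch-scramble bootstrap, and developmental desynchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quietest-period Z-scores, epoch-scramble bootstrap, and developmental desynchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casync)
```

# The analysis problem

Longitudinal two-photon calcium imaging of layer 2/3 neurons in developing
barrel cortex poses three linked questions: how strong is spontaneous
population synchrony at each age, which neurons respond to whisker
stimulation in a time-locked way, and how do both change as the cortex
matures. `casync` implements the full chain from movies (or trace tables)
to those answers, together with a synthetic-data generator that emulates
the recordings closely enough that every stage can be validated against
ground truth.

The statistical spine of the package is:

1. **Modified Z-score.** Each neuron's \(\Delta F/F\) trace is
   standardized by its own *quietest period*:
   \[
   Z_F(t) = \frac{F(t) - \mathrm{mean}(\text{quietest period})}
                 {\mathrm{SD}(\text{quietest period})},
   \]
   where the quietest period is the 10-s window with the lowest
   \(\Delta F/F\) SD (exhaustive stride-1 search; ties go to the earliest
   window). Standardizing against the quietest window rather than the whole
   trace keeps the scale meaningful for neurons that are active much of
   the time. All downstream statistics operate on \(Z_F(t)\).

2. **Activity epochs.** An epoch is a maximal run of consecutive frames
   with \(Z_F(t) \ge 3\). Epochs are the unit of activity used by the
   active-cell filter and the unit preserved-and-shuffled by the bootstrap
   null. No minimum duration is imposed by default.

3. **Epoch-scramble bootstrap.** A neuron is called whisker-responsive
   when the Pearson correlation between its \(Z_F\) trace and the stimulus
   time-course exceeds what is expected from 1,000 scrambles of all its
   activity epochs. Each scramble reinserts the epoch segments — values
   verbatim, order shuffled — at uniform-random non-overlapping positions
   (an exact stars-and-bars draw over gap compositions) and fills the
   remaining frames by resampling the trace's own non-epoch frames with
   replacement. This destroys epoch *timing* while conserving epoch
   content, count and total trace length, which is precisely the null the
   classification needs. The one-sided add-one p-value is
   \(p = (1 + \#\{r_{\mathrm{null}} \ge r_{\mathrm{obs}}\})/(N+1)\), with
   \(\alpha = 0.05\) and no correction across neurons (an optional
   Benjamini–Hochberg step can be applied to the returned p-values).

4. **Synchrony.** Network synchrony is the mean of the strict upper
   triangle of the Pearson correlation matrix over neurons, computed on
   AR(1)-deconvolved traces of neurons active at every age.

# The stimulus regressor

The stimulus time-course could enter the correlation as a raw binary
boxcar (1 during each 1-s stimulation epoch) or convolved with the
indicator response kernel. We made the **convolved regressor the
default** after a direct power analysis: with GCaMP6s-like kinetics
(decay \(\tau \approx 1.5\) s) the bulk of the evoked fluorescence falls
*after* the 1-s stimulation window, so the boxcar overlaps only the rising
edge of each transient. On designed responders (per-stimulus response
probability 0.85, evoked peak \(Z \approx 10\)) the boxcar regressor
detected only ~50–60%, whereas the convolved regressor detects
essentially all of them while leaving the null calibration untouched
(empirical type-I error 0.05; the same regressor is applied to the
observed trace and to every scramble, so exchangeability is preserved).
`regressor = "boxcar"` restores the raw boxcar.

# The synthetic-data generator

`generate_spikes()` draws population-wide network events as a Poisson
process; each neuron joins each event independently with a participation
probability, and additionally fires its own independent Poisson events.
`spikes_to_traces()` turns event trains into \(\Delta F/F\) via a
difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s — chosen so a
single transient spans several frames at 7.8 Hz; the kernel peak is
normalized on the sampled frame grid so a drawn amplitude is exactly the
transient's peak), per-event amplitudes from a Normal(1.0, 0.25) truncated
at zero, linear superposition, and additive Gaussian noise with SD 0.1.
These defaults put single-event peaks near \(Z = 10\), so threshold-3
epochs are unambiguous. `generate_evoked_session()` adds, for each
designed responder and each stimulus, one evoked event with the stage's
response probability at a latency uniform within the 1-s stimulation
window (the literature gives no evoked-latency distribution at these
ages; uniform is the least committal choice).

Acquisition defaults mirror the targeted recordings: 7.8 Hz frame rate,
60-s spontaneous sessions, and 120-s evoked sessions carrying 10 stimuli
of 1 s at 10-s interstimulus intervals (first onset at 10 s, 11-s cycle).

## Stage presets

The three age presets encode the developmental trajectory: infrequent
population-wide events joined by most neurons at P11, mostly independent
sparse firing by P15 and P30. The preset rates were calibrated so the
*measured* mean pairwise correlations of the default dataset reproduce
the magnitudes reported for these ages (≈ 0.25 / 0.05 / 0.01 for
P11/P15/P30 across seeds):

| stage | network events (Hz) | participation | independent events (Hz) | designed responders | response prob. |
|-------|--------------------:|--------------:|------------------------:|--------------------:|---------------:|
| P11   | 0.10 | 0.75 | 0.02 | 20% | 0.50 |
| P15   | 0.08 | 0.40 | 0.06 | 60% | 0.85 |
| P30   | 0.03 | 0.20 | 0.07 | 40% | 0.85 |

One network event per 10–17 s is still "large but infrequent"; with 60-s
sessions the Poisson fluctuation of event counts is the dominant source
of seed-to-seed variance in stage synchrony, which is why the presets
keep P15 and P30 well separated. The responder presets encode the
qualitative finding that time-locked responsiveness emerges by P15 and
declines somewhat by P30; at P11 broad network bursts make time-locking
ambiguous, hence few, unreliable designed responders.

What the generator deliberately does **not** emulate: neuropil and
vasculature contamination, photon shot noise and the microscope PSF,
sub-pixel or non-rigid motion, dendritic geometry, and any dependence of
amplitude on event history (no indicator saturation). Passing tests on
this generator therefore validate the *statistics* of the pipeline — not
robustness to every nuisance of real recordings.

## Seeding

Every stochastic operation takes a seed; sessions, stages and ROIs get
independent substreams through one documented rule,
`split_seed(seed, index) = (seed * 10007 + index) mod (2^31 - 1)`, so any
module can be re-run in isolation and reproduce its slice of a full
dataset. The per-ROI substreams also make `bootstrap_responsiveness()`
results independent of ROI order.

# Preprocessing choices

**Registration** is rigid integer-pixel translation by FFT
cross-correlation against a reference frame (shift search bounded at ±10
px by default, vacated pixels filled with the frame median). Because every
downstream quantity is normalized per ROI, rigid correction is sufficient
for this analysis; sub-pixel and non-rigid motion are out of scope.

**\(\Delta F/F\)** uses a running 20th-percentile baseline over a 30-s
window by default — robust in the sparse-transient regime and tolerant of
slow drift. A constant-percentile and a global-median baseline are
selectable; outputs record the method used. The field has no single
convention here, so results are method-tagged rather than presented as
canonical. Neuropil subtraction is not performed.

**Deconvolution** is the simplest AR(1) inversion,
\(d(t) = \max(0, x(t) - \gamma x(t-1))\) with
\(\gamma = e^{-1/(\tau f)}\) and \(\tau = 1.5\) s by default. Pairwise
Pearson correlation downstream only needs temporal sharpening, not spike
counts; tests confirm that event-frame recovery survives a 2× mis-set
\(\tau\). Synchrony is computed on spontaneous sessions only; evoked
frames would add stimulus-locked correlation that is not network
synchrony.

**OIS response maps** divide each trial's response image by its mean
baseline image, sum the ratios over trials, and threshold at 50% of the
maximum of the summed map.

# Group statistics

`friedman_with_posthoc()` computes the tie-corrected Friedman rank
statistic for related samples. For small complete designs (up to
\((k!)^n \le 10^5\) permutations, e.g. 3 stages × 6 subjects) the p-value
is obtained by **exact enumeration of all within-row rank permutations**
rather than the \(\chi^2_{k-1}\) approximation, which is noticeably
inaccurate at these sizes; larger designs fall back to the asymptotic
p-value, and the output records which path was taken. Post-hoc pairwise
comparisons are Wilcoxon signed-rank tests (consistent with the
rank-based omnibus), Bonferroni-multiplied by the number of stage pairs
and capped at 1. A fully tied design returns statistic 0, p = 1.

`rank_bootstrap_test()` compares two small unpaired groups: the statistic
is the difference in mean pooled ranks, the null is built by drawing both
groups with replacement from the pooled data (10,000 resamples by
default) and re-ranking, and the two-sided add-one p-value is reported.
A difference-in-medians statistic is available as an alternative.

# Numerical and convention details

- Frames and pixels are 0-based; epochs and frame ranges are half-open
  `[start, end)`. These conventions are recorded in every CSV sidecar.
- The quietest window length is `round(window_s × frame_rate_hz)` frames,
  minimum 2; window ties break to the earliest start, deterministically.
- Quiet-period SD below \(10^{-12}\) makes a trace non-standardizable;
  such ROIs are dropped with a warning (configurable to an error) rather
  than aborting a batch.
- Constant traces are likewise dropped from the correlation stage with a
  warning; they carry no correlation information.
- Scrambling requires at least 10% non-epoch frames; denser traces raise
  an infeasible-scramble error rather than returning a degenerate null.
- Within each stimulation epoch a frame counts as "stimulus on" if its
  time span overlaps the epoch (so a 1-s epoch covers 8 frames at
  7.8 Hz).

# Problem sizes used in the test and acceptance runs

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the bands they assert: 1,000 random traces for each
brute-force oracle comparison; 300 spontaneous-only neurons (1,000
scrambles each) for null calibration; 100 designed responders for power;
20 ROIs × 10,000 frames for the independence limit; 10 master seeds for
the developmental ordering; 1,000 simulations of n = 6 vs n = 6 groups
for rank-bootstrap calibration. The default longitudinal dataset carries
30 neurons per stage.

# Reading stage-level responsive fractions

The bootstrap's per-neuron type-I error is calibrated *across sessions*,
but within one session the errors are not independent: all neurons share
the same network events, so if a few population bursts happen to fall
near stimulation windows, many non-responders cross threshold together.
At P11 — where most activity is population-wide — a single session's
responsive fraction is therefore highly variable and can sit far above
the designed responder fraction. This is the synthetic counterpart of the
empirical observation that broad immature bursts make time-locked
responsiveness ambiguous at P11; P15/P30 fractions, where activity is
desynchronized, track the designed fractions closely.

# Known limitations

- The generator's amplitude and rate presets are calibrated to reproduce
  reported stage-level synchrony magnitudes, not fitted to any raw data;
  absolute values of, e.g., responsive fractions depend on those presets.
- The epoch-scramble null treats non-epoch frames as exchangeable white
  noise; slow sub-threshold structure (oscillations, neuropil bleed) in
  real data would make the null slightly optimistic.
- AR(1) deconvolution is not a spike-count method; only correlation-level
  statements should be read from its output.
- Registration is integer-pixel; residual sub-pixel motion appears as
  correlated noise in extracted traces.
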