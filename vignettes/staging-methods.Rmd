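---
title: "Sequence-to-sequence sleep staging from coarse wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-to-sequence sleep staging from coarse wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somnseq)
```

## The problem

Polysomnography (PSG) stages sleep in 30-s epochs into wake, N1, N2, N3 and
REM, but requires a sleep laboratory. Wrist wearables provide two kinds of
signal that survive the trip to a consumer device: movement (actigraphy
counts per epoch) and heart rate. `somnseq` stages nights from exactly
three coarse per-epoch channels — activity counts, the mean of the
instantaneous heart rate over the epoch (HRM, bpm) and its standard
deviation (HRSD, bpm) — optionally plus clock time, into three classes
(W/NREM/REM) or four (W/Light/Deep/REM, where Light = N1+N2 and Deep = N3).

Two physiological facts make this feasible and shape everything below. REM
sleep couples wake-like cardiac activity with near-zero movement (muscle
atonia), so the *combination* of channels separates REM from both wake and
NREM. And the four-class problem is severely imbalanced: deep sleep is
roughly 9% of epochs in a typical older-adult cohort, so an unweighted
classifier simply ignores it, while a recall-oriented reweighting floods it
with false positives.

## Model and assumptions

Windows of `L = 12` consecutive epochs (stride 1) are standardized
per channel with training-split statistics and passed through:

1. three 1-D convolutions, kernel 9, padding 4, stride 1 (length-preserving:
   `L + 2*4 - 9 + 1 = L`), each followed by a leaky ReLU (slope 0.01);
2. an LSTM encoder over the `L` feature vectors;
3. an LSTM decoder initialised with the encoder's final state, unrolled
   `L` steps. Step `t` consumes the epoch's CNN feature concatenated with
   the previous context vector (input feeding). The decoder state attends
   over all encoder states with a bilinear ("general") alignment score
   `d' W_a e_j` (configurable to dot product); softmaxed scores weight the
   encoder states into a context vector;
4. a linear projection of `[decoder state, context]` to `K` logits and a
   softmax.

Each epoch therefore receives one probability vector per covering window —
up to 12 for interior epochs — and the final label is the vote mode.
Ties go to the tied class with the highest mean predicted probability
across the contributing windows, then to the earlier class in scheme order;
the paper-level description of voting is silent on ties, so this is the
package's own deterministic rule. Edge epochs are voted over however many
windows cover them.

Hidden sizes, layer counts, the attention variant and the decoder input
scheme are not dictated by the method description; the defaults (64 conv
channels, hidden size 128, one recurrent layer each, general attention, no
teacher forcing) are declared choices, configurable in `stager_config()`.
Window widths 9, 12 and 15 are all supported; 12 is the default.

## Losses for class imbalance

With training frequencies `f_k`, `if_weights()` returns `w_k ∝ 1/f_k` and
`loss_if()` is the weighted categorical cross-entropy. For the four-class
problem `rw_weight_matrices()` builds `w_fn^k = 1/f_k` and
`w_fp^{kl} = sqrt(1/(f_k f_l))` (zero diagonal), and `loss_rw()` adds a
`log(1 - p_l)` charge for mass placed on wrong classes. Two design points:

* both weight constructions are normalised to mean 1 (mean off-diagonal for
  the matrix) so the two objectives live on comparable scales; the method
  description states no normalisation, and the choice affects only the
  effective learning rate;
* the false-negative vector is taken as inverse frequency, which makes
  `loss_rw` reduce exactly to `loss_if` when the false-positive matrix is
  zeroed — a reduction the test suite asserts to 1e-12.

Probabilities are clamped at `eps = 1e-7` for numerical stability. Both
losses return analytic gradients with respect to the pre-softmax logits;
the whole network's backward pass (convolutions, both LSTMs, attention) is
likewise analytic, and the suite checks it against central finite
differences at 1e-4 relative tolerance, ignoring entries at the
finite-difference noise floor.

## Training procedure

Subjects — never epochs — are randomly split into train/validation/test.
The default rule assigns `floor(0.75 n)` subjects to training and splits
the remainder evenly (validation first); `split_subjects()` also accepts
absolute validation/test sizes, the convention used by cohort studies that
fix 100 + 100 subjects and give the remainder to training. Windows never
cross subject-night boundaries.

Optimisation is mini-batch Adam (learning rate 0.00015, batch 50, 200
optimisation epochs by default). After every epoch the validation split is
scored and the best snapshot is returned; the selection metric is weighted
F1 over validation window positions (the reference recipe says only "best
set of model parameters", so this is a declared choice, configurable to
accuracy or validation loss). `fine_tune()` continues training of the
entire parameter set on a new cohort at learning rate 0.00001, the standard
transfer-learning recipe for small target cohorts; `cross_validate()` runs
subject-wise k-fold evaluation (folds of near-equal size, larger first).

All randomness is seeded; training is bit-reproducible on one machine with
one BLAS. Determinism across BLAS implementations is not guaranteed.

## Preprocessing rules

`ihr_from_rpeaks()` implements the cardiac chain: consecutive R-peak
intervals, assignment of each interval to the epoch containing its
terminating peak (half-open 30-s windows), artifact correction, conversion
to bpm, and per-epoch summary.

* Intervals below 0.33 s (>~180 bpm, spurious beats) are replaced by the
  arithmetic mean of the interval and its predecessor — the only reading of
  "midpoint of that interval and the previous interval" that yields an
  interval value. A first interval with no predecessor uses the epoch mean.
* Intervals above 1.33 s (<~46 bpm, missed beats) are split into
  `n = max(1, round(T/T_mean))` equal chunks (`T_mean` = epoch mean of raw
  intervals), rounding half up. This conserves the epoch's total duration.
* Per-epoch HRM/HRSD use a single-pass 2-SD outlier rejection: mean and
  sample SD (n−1) are computed once, values outside mean ± 2 SD are
  dropped, and the statistics are recomputed once on the survivors.
  Whether the source method recomputes after discarding is implied rather
  than stated; single-pass is this package's declared reading.

`upsample_activity()` replicates 60-s counts into two 30-s epochs.
`accel_to_counts()` band-passes the z-axis accelerometry (4th-order
Butterworth, default 0.5–3.5 Hz — voluntary limb movement — after
demeaning), quantises absolute amplitude into 128 uniform bins over a
configurable full scale (default 2 g), and sums bin indices over 15-s
windows. The exact band edges and the meaning of "128 bins" are not
published for the device chain this emulates; both are configurable
parameters, documented as package defaults rather than reference values.
`align_by_crosscorr()` recovers integer-epoch misalignment between
channels by maximising Pearson cross-correlation within ±`max_lag`.

## The synthetic cohort generator

Real training cohorts for this problem are access-controlled, so the
package ships a generator whose defaults encode the documented statistical
structure of such cohorts:

* **Hypnograms** are first-order Markov chains over the stage labels with
  stationary fractions 0.33/0.47/0.09/0.11 (W/Light/Deep/REM; three-class
  0.33/0.56/0.11) and persistence `rho = 0.9`, giving mean bout lengths of
  ~5 min, comparable to scored hypnograms. The transition matrix
  `P = rho I + (1-rho) 1 pi'` has exactly those stationary fractions, so a
  Monte-Carlo draw can be checked against an eigen-decomposition oracle.
  An optional clock-time multiplier `exp(-deep_decay t/T)` on transitions
  into deep sleep reproduces the early-night concentration of deep sleep;
  it is off by default so the stationary oracle stays exact.
* **Emissions** are stage-conditional Gaussians (activity truncated at
  zero): wake has high activity and elevated heart rate; light/deep sleep
  have low activity with progressively slower, less variable heart rate;
  REM has wake-like heart rate with the lowest activity. The defaults keep
  light and deep partially overlapping — deliberately, since their
  physiological signatures lie on a continuum and the four-class
  experiments below are only meaningful if the stages are confusable.
* **R-peak trains** lay down beats at the stage's heart rate with Gaussian
  jitter; artifacts insert spurious beats (intervals < 0.33 s) or drop
  beats (> 1.33 s), exercising the correction rules.

What the generator does *not* emulate: arousal/apnea microstructure,
device-specific noise floors, non-stationary heart-rate trends,
circadian-modulated emissions, or missing-data patterns of real wearables.
Tests passing on synthetic nights therefore validate the machinery —
shapes, rules, optimisation, metrics, the direction of the loss-function
effect — not field performance on any real cohort.

## Problem sizes used by the checks

The shipped experiments are deliberately scaled down so they run on a
laptop CPU: the learning-sanity check trains a reduced network (16 conv
channels, hidden 32) for 20 optimisation epochs on 50 synthetic subjects
with 120-epoch nights and stage emissions separated by ≥3 SD, and requires
test macro sensitivity ≥ 0.85; the imbalance experiment trains matched IF-
and RW-weighted four-class models (8 optimisation epochs, 16 subjects of
180 epochs, deep sleep at 9% prevalence) for three seeds each and compares
mean deep-sleep false positives. A full-scale run (hundreds of subjects,
full nights, 200 optimisation epochs) uses the same code paths with the
default configuration.

## Clinical metrics

All are derived from a hypnogram alone (`clinical_metrics()`): total sleep
time; sleep efficiency = sleep time / recording time (the in-bed time is
taken as the whole concurrent recording); onset latency = time to the first
run of three consecutive sleep epochs (the most stringent common
definition — all-wake nights return NA); fragmentation = post-onset
sleep-to-wake transitions per hour of sleep (a declared assumption, since
competing definitions exist); the sleep transition index = post-onset
epochs whose stage differs from their predecessor (any stage pair,
including into and out of wake), as a fraction of post-onset sleep epochs;
per-stage times and fractions of sleep time. `mae_of_metrics()` compares
predicted and reference nights subject-wise with pairwise NA exclusion.

Classifier quality is reported as the predicted-by-true confusion matrix
(columns sum to 100% when normalised — chance level 100/K on the diagonal),
per-class one-vs-rest sensitivity/specificity/precision/F1/MCC, overall
accuracy, and both macro and support-weighted aggregates of F1 and MCC
(reported tables in the field use both conventions). Cohen's kappa is
deliberately omitted: under severe imbalance it can rank a worse classifier
higher, which is the scenario this package targets.

## Degenerate inputs and numerical corner cases

Empty epochs yield NA HRM/HRSD and are masked; a single IHR value gives
SD 0; classes with zero test support are excluded (NA) from macro
aggregates; zero-variance channels make cross-correlation alignment return
lag 0 with a warning; zero-count classes abort weight construction with
guidance rather than producing infinite weights; a NaN training loss aborts
with a diagnostic rather than silently returning garbage; softmax is
computed with the row-max subtracted; vote ties and the `which.max`
fall-through are documented above.

## Known limitations

The network is CPU-bound base R; a full 200-epoch run on an 800-subject
cohort is feasible but slow (hours, not minutes), and no GPU path exists.
The generator's Gaussian emissions understate the burstiness of real
actigraphy. Sleep-onset latency from coarse channels is known to be
severely underestimated in this field, and nothing here fixes that.
Determinism holds per machine, not across linear-algebra libraries.
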