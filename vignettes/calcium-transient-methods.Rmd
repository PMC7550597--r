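---
title: "Methods: automated assessment of calcium-transient abnormality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated assessment of calcium-transient abnormality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Beating cardiomyocytes derived from human induced pluripotent stem cells
(hiPSC-CMs) cycle cytosolic Ca²⁺ once per beat. Under a Ca²⁺-sensitive dye
each beat appears as a fluorescence transient: a rapid upstroke followed by
a slower decay back to the diastolic level. Experts recognise dysfunction
from these traces — weak beats, incomplete Ca²⁺ reuptake, skipped or
irregular beats, diastolic oscillations, spontaneous Ca²⁺ release between
beats — but manual annotation of hundreds of cells is slow and subjective.
`catrans` automates the assessment at two levels: per transient peak and
per cell (one fluorescence signal per cell).

## Peak detection

Signals arrive as intensity series sampled at a fixed frame rate (default
5 Hz). The first derivative is estimated by central differences at interior
frames and one-sided differences at the ends, in AU/s with
`dt = 1/sampling_hz`. Scanning left to right:

1. the first frame with derivative above `t_up` (default 30 AU/s) opens a
   peak (*peak left*);
2. the first later frame with a negative derivative bounds the rise; the
   *peak maximum* is the intensity argmax over the frames after peak left
   up to that sign change (the sign-change frame itself can fall one frame
   past the true maximum with central differences, so the argmax is used;
   on a monotone rise both coincide);
3. the first subsequent frame whose derivative is positive and larger than
   `rt_up` (default 2 AU/s) closes the peak (*peak right*); the margin
   above zero avoids closing on noisy wiggles of the decay. With
   `rt_up = 0` the peak closes at the first positive derivative.

The scan resumes one frame past each peak right, so peaks are ordered and
non-overlapping by construction. Both thresholds are configuration-exposed
(`detection_config()`); they are absolute derivatives, so they implicitly
assume intensity units in which a healthy upstroke clearly exceeds
`t_up` — with raw camera units in the hundreds this is comfortably the
case.

A recording that ends during a decay leaves the final transient without a
closing upstroke. By default that peak is truncated at the last frame, so
the final beat of every recording is kept; `drop_partial_last = TRUE`
discards it instead. Truncation was chosen as the default because the
final transient is ordinarily complete apart from the tail of its decay,
and discarding it would systematically shorten every signal by one beat.

Frame indices are 1-based everywhere (the R convention), including CSV
exports.

Two exclusion rules follow detection. The first detected peak is removed
when it is both strongly asymmetric (left amplitude below 50% of the right
amplitude) and of low absolute intensity (below 5 AU at the maximum) — the
signature of a transient already underway when acquisition started. Then
any peak whose amplitude (max of left/right amplitude) falls below 15% of
the largest amplitude among the detected peaks is removed as noise. The
noise threshold is computed once, against the pre-filter maximum. Signals
with fewer than two surviving peaks are excluded from all further analysis
(a single beat carries no rhythm information), with the exclusion logged.

## The 14 peak variables

For a peak with boundaries (left, max, right) on intensities `y`:

| variable | definition |
|---|---|
| `A_l`, `A_r` | `y[max] − y[left]`, `y[max] − y[right]` (AU) |
| `A_d` | `A_l − A_r` |
| `D_l`, `D_r` | rise and decay durations (s) |
| `Dy_max` | max first derivative on the rise (AU/s) |
| `Dy_min` | absolute min first derivative on the decay |
| `D2y_max` | max second derivative on the rise (AU/s²) |
| `D2y_min` | absolute min second derivative on the decay |
| `R` | trapezoidal integral of `y` from left to right (AU·s) |
| `delta` | time from the previous peak maximum (s); undefined for the first peak |
| `delta_l2Dymax` | time from peak left to the `Dy_max` frame |
| `delta_m2Dymin` | time from peak max to the `Dy_min` frame |
| `Peak_distance_median` | median of the signal's `delta` values, identical on all its peaks |

Amplitudes are boundary-referenced (no baseline model is fitted) and `R`
integrates the raw intensity without baseline subtraction. Durations are
reported in seconds so that features are comparable across sampling rates.
The second-derivative extrema are assigned to the rise (`D2y_max`) and the
decay (`D2y_min`) respectively. Offset invariance holds for every variable
except `R`, which shifts by exactly `c·(right−left)·dt` under `y → y + c`;
scaling intensities by `k` scales the amplitude-, derivative- and
area-type variables by `k` and leaves all durations unchanged.

For classifier input the first peak's undefined `delta` is imputed with the
signal's `Peak_distance_median` — the least informative value available, as
it invents no rhythm irregularity. The rule engine (below) never sees
imputed values: it skips the phase test for first peaks natively.

## The analytical rule cascade

With `maxamp = max(A_l, A_r)` and `minamp = min(A_l, A_r)`, peaks are
assessed left to right:

1. **First-peak amplitude** — abnormal if `maxamp` is below 50% of the
   signal-mean `maxamp` (mean, following the word "average").
2. **Subsequent amplitudes** — abnormal if the preceding peak is abnormal
   and `maxamp` is below 50% of the signal mean, or if `maxamp` is below
   50% of the *most recent normal* peak's `maxamp`. Referencing the most
   recent normal peak (not merely the predecessor) means a run of
   consecutive weak beats is caught in its entirety.
3. **Asymmetry** — an amplitude-normal peak is abnormal if
   `minamp < 0.85 · maxamp`: the decay failed to return near the starting
   level, i.e. incomplete Ca²⁺ reuptake.
4. **Irregular phase** — a symmetric, amplitude-normal, non-first peak is
   abnormal if its `delta` deviates from the signal's median `delta` by
   more than 90% of that median.

A cell is abnormal iff any of its peaks is abnormal.

The phase rule deserves a note. Read literally as a one-sided threshold
("`delta` greater than 90% of the median"), the test would flag roughly
every peak of a perfectly rhythmic signal, since every `delta` equals the
median. The deviation form `|delta − median| > 0.9·median` preserves the
intent — flagging intervals inconsistent with the cell's own rhythm, e.g.
a skipped beat at roughly twice the median — while reducing to the literal
reading on the long side at `delta > 1.9·median`. The literal one-sided
form remains available via `rule_config(phase_mode = "literal")`. All
three thresholds (0.5, 0.85, 0.9) are configuration-exposed.

Rule 3's verdict is final: no later consideration reverts an asymmetric
peak to normal. Evaluation order matters only through rule 2's dependence
on earlier outcomes, which is why assessment is strictly left to right.

## The SVM cascade

The rule cascade encodes fixed expert heuristics; the learning pathway
instead leverages expert-labelled data. A **peak-level SVM**
(radial-basis kernel, C-classification) is trained on the 14 standardized
peak variables against expert peak labels. Training-set accuracy is
estimated by **leave-one-signal-out cross-validation**: all peaks of one
signal form the held-out fold and the model is refitted on the peaks of
all other signals — never one peak per fold, since peaks within a signal
are strongly dependent. Standardization statistics and the kernel width
are refitted inside each fold on that fold's training rows only, so no
information about the held-out signal (features or labels) can leak into
its own predictions; the test suite asserts this with label-flip and
marker-feature probes plus a naive refit oracle.

Six **cell variables** are then built per signal: the any-abnormal cell
labels from the rule cascade and from the peak-SVM predictions (encoded
0/1 and standardized together with the continuous variables), the
proportion of SVM-abnormal peaks, and the sample variances of peak
amplitude, of the defined peak distances, and of peak areas. A 2-peak
signal has a single inter-peak interval; its distance variance is defined
as 0 (no rhythm variability is observable). A **cell-level SVM** over
these six variables, with expert cell labels as outcome, produces the
final call; for new cohorts the full chain — detection, quantification,
rules, peak scoring with the stored training standardization, cell
features, cell scoring — is replayed by `predict_cells()`, which reports
unscorable signals (fewer than two peaks) as excluded rather than
dropping them.

Hyperparameters: the original work does not state kernel or cost. The
defaults are a radial kernel with `C = 1` and kernel width set by the
median heuristic (`gamma = 1/(2·median pairwise squared distance)` on the
standardized training rows, computed on a deterministic subsample of at
most 500 rows), with inverse-frequency class weights since abnormal peaks
are typically the minority. All are exposed via `svm_config()`. Constant
feature columns (possible in very small cohorts, e.g. a shared
`Peak_distance_median`) are flagged and excluded from the fit rather than
standardized to NaN. Decision scores are signed distances from the
separating hyperplane with abnormal positive.

## Evaluation

Abnormal is the positive class throughout: sensitivity is the recognition
rate of expert-abnormal instances, specificity of expert-normal ones,
reported as percentages. When decision scores are available the ROC curve
and its trapezoidal AUC are computed (mid-rank tie handling), equal to the
probability that a random abnormal instance outscores a random normal one;
the test suite checks this identity against a brute-force pairwise oracle
at 1e-12. Single-class truth leaves the ROC/AUC undefined (`NA`), not
silently 0 or 1.

## The synthetic cohort generator

No public dataset of labelled hiPSC-CM Ca²⁺ traces accompanies this
problem, so the package ships a seeded generator
(`generator_config()`, `generate_cohort()`) that emulates the study
conditions: 5 Hz sampling, recording lengths uniform on 12–32 s, and a
default study of 200 training plus 54 test cells. Each trace is a
baseline (50 AU) with a small linear drift, a quasi-periodic train of
transient templates, and Gaussian noise (SD 1.5 AU). The template is a
logistic upstroke (τ = 0.25 s) multiplied by an exponential decay
(τ = 0.30 s from the rise midpoint), with per-cell amplitude ~N(450, 50²)
AU clamped at 350 and small within-cell variation; the beat period is
2.6 ± 0.1 s, giving roughly nine peaks per signal and about 1900 training
peaks.

These constants were calibrated once, jointly, against the detector's
absolute thresholds: at 5 Hz the `dy > t_up` crossing must occur early in
the upstroke (otherwise the recorded peak-left frame sits mid-rise and the
boundary-referenced `A_l` fluctuates with sampling phase, producing
spurious asymmetry calls on healthy beats), and the decay must be
essentially complete before the next upstroke begins (otherwise the
previous beat's tail hides the gentle early rise and collapses the
`rt_up` and `t_up` crossings onto the same frame). Upstrokes spanning
4–5 frames with amplitudes of several hundred AU satisfy both. Even so, at
the worst sampling phases a healthy beat's `min/max` amplitude ratio can
graze the 0.85 asymmetry threshold; clean cohorts therefore show a
sub-percent rate of false rule firings, a documented edge of applying an
absolute-threshold detector at 5 Hz.

Abnormal signals carry exactly one defect type, drawn from a categorical
mix (probabilities 0.15/0.15/0.15/0.10/0.05, total abnormal fraction 0.6,
comparable to the study's test-set class mix):

* **small_amplitude** (↔ amplitude rules): one or two beats scaled to
  26–38% of the cell's amplitude;
* **asymmetric_decay** (↔ asymmetry rule): after one beat the diastolic
  level steps up by 30% of that beat's amplitude and stays elevated — the
  affected peak's `A_r` shrinks while, by offset invariance, later peaks
  are untouched;
* **irregular_phase** (↔ phase rule): a skipped beat — one interval
  lengthened by 1.2 periods;
* **baseline_oscillation**: an 18 AU sinusoid (period 3 s) across the
  recording; every peak is ground-truth abnormal, but the rule cascade has
  no oscillation rule and mostly misses these cells — they must be caught,
  if at all, through the amplitude-variance cell features;
* **spontaneous_release_bump**: a slow sub-threshold release event between
  two beats (8% of the cell amplitude); experts would flag it, the
  detector largely cannot see it. It is the generator's irreducible hard
  case.

Ground-truth labels are generative — they follow from the injected defect,
never from running the rule engine — so the rules and classifiers are
tested against an independent truth. The last two defect classes are what
gives the learning pathway its measurable edge over the fixed rules on
this benchmark, mirroring the qualitative finding that motivates the SVM
cascade.

What the generator does **not** emulate: photobleaching trends,
movement artifacts, cell-to-cell morphology families beyond amplitude and
period variation, drug-response shifts, and truly ambiguous borderline
morphologies that make expert labels noisy. Passing the closed-loop and
benchmark tests therefore demonstrates the pipeline's internal
correctness and the learnability of the injected phenotypes — not
field performance on real recordings.

## Numerical choices and degenerate inputs

* Derivatives: central differences interior, one-sided at both ends;
  traces shorter than 3 frames are rejected.
* Ties in argmax/argmin (e.g. two equal maxima on a rise) resolve to the
  earliest frame.
* Standardization uses the sample (n−1) standard deviation; zero-variance
  columns are an error in `fit_standardizer()` and are flagged-and-dropped
  inside classifier training.
* Peak area uses the trapezoidal rule on the raw intensities.
* Median peak distance with an even number of intervals is the usual
  midpoint of the two central order statistics.
* A cohort prediction over zero signals returns an empty table, not an
  error; single-class training sets and misaligned feature columns are
  hard errors.
* Reproducibility: all stochastic steps derive from the single generator
  seed; repeated runs with one configuration are byte-identical, and the
  effective configuration (with a fingerprint) is written next to every
  artifact set.

## Problem sizes used by the test suite

The default study replayed by `run_pipeline()` and `scripts/acceptance.R`
uses 200 training and 54 test signals (roughly 1900 + 500 peaks) — the
same cohort sizes as the motivating study — and completes in well under a
minute on a single CPU; unit and property tests use cohorts of 5–40
signals and 300–1000 randomized oracle comparisons.

## Known limitations

* The absolute derivative thresholds tie the detector to the intensity
  scale; traces in other units need rescaled `t_up`/`rt_up`.
* Boundary-referenced amplitudes inherit sampling-phase jitter at 5 Hz
  (see above); sub-percent false asymmetry rates on clean signals are
  expected rather than exceptional.
* The rule cascade has no test for diastolic oscillation or inter-beat
  release events; sensitivity to those phenotypes comes only from the
  learning pathway.
* The cell-level SVM consumes the rule cascade's label as a feature, so a
  systematic rule failure propagates; the variance features mitigate but
  do not eliminate this.
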