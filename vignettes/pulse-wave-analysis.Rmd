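---
title: "Pulse-wave cycle features for hypertension-history classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-wave cycle features for hypertension-history classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsehtn)
```

## The problem

The radial pulse wave carries more information about vascular state than the
two numbers of a blood-pressure cuff. In the elderly in particular, a
normotensive reading can belong either to a genuinely healthy subject or to
a treated hypertensive whose arteries retain the stiffness signature of
sustained high pressure. `pulsehtn` implements a pipeline that extracts
morphological and spectral features from 10-second single-channel wrist
pulse recordings and asks whether, **within** one blood-pressure grade,
subjects with and without a hypertension history can be told apart.

Cohorts are stratified into three grades from the resting reading, with the
rules applied in precedence order because they overlap:

* **HestG** — systolic above 140 mmHg *or* diastolic above 90 mmHg;
* **HerG** — systolic 130–139 mmHg *or* diastolic 80–89 mmHg;
* **NG** — systolic below 120 mmHg *or* diastolic below 80 mmHg.

The disjunctive NG rule is kept verbatim rather than "corrected" to the
conjunctive definition of normotension; with the precedence above it is
almost exhaustive, and the residual readings (a systolic of 120–129 or
exactly 140 mmHg paired with a diastolic of exactly 90 mmHg) are returned
as `unclassified` and excluded.

## The synthetic cohort generator

The original wrist-sensor recordings are not publicly deposited, so the
package treats the *generator* as a first-class module: it defines the
conditions under which every downstream claim is tested.

One beat is the sum of three positive Gaussian bumps — percussion `(t1, h1)`,
tidal `(t3, h3)` and dicrotic `(t5, h5)` — so the tidal onset `t2` and the
dicrotic onset (notch) `t4` arise as inter-bump minima of the summed curve.
Gaussians were chosen because the waveform stays smooth and differentiable
and the realized landmarks can be read off the noise-free curve exactly,
giving every detector an analytic ground truth. The default template
(`beat_template()`): period 1.0 s, percussion at 0.13 s with unit
amplitude, tidal crest at 0.32 s with amplitude 0.62, dicrotic crest at
0.52 s with amplitude 0.45, bump widths 0.04/0.07/0.08 s — a canonical
healthy-elderly three-wave cycle with `h1 > h3 ≥ h4`.

A recording concatenates beats with per-beat period jitter (SD 0.03 s) and
a 2 % log-normal amplitude jitter, then adds a baseline-wander sinusoid
(default 0.1 a.u. at 0.25 Hz, below the 0.5 Hz high-pass cutoff) and white
noise (default SD 0.02, i.e. 2 % of the percussion amplitude). The
recording closes at the final complete beat boundary: a truncated partial
beat at the edge cannot be annotated and only distorts the detection
envelope. Everything is driven by one integer seed; the same
`(config, seed)` pair reproduces recordings bit for bit.

Cohort defaults: 770 subjects split 78/25/68/65/225/309 across the
(grade × history) cells — the study population's cell proportions scaled
from cycle counts to subjects — with age ≈ 72 ± 6 years and BMI
≈ 24.5 ± 3.2 kg/m². The hypertension-history class receives additive
parameter shifts (`effect`): by default a higher tidal crest (+0.08), a
stronger dicrotic wave (+0.04), a shorter period (−0.05 s), one extra year
of age and +0.8 BMI — a modest "stiffer, faster, augmented" caricature of
the wiry pulse. These shifts are echoed in the output so recovery is
checkable; setting them to zero yields exchangeable classes, which the
test suite exploits as a null.

What the generator does **not** emulate: real hemodynamics (no Windkessel
model), motion artifacts, sensor drift other than a single sinusoid,
sex-specific physiology, arrhythmia, or between-beat morphology changes.
Passing tests therefore demonstrate that the pipeline recovers what it is
supposed to recover under controlled conditions — not that the synthetic
accuracies transfer to clinical data.

## Preprocessing and segmentation

All filters are order-4 Butterworth applied forward–backward (zero phase),
with odd-reflection padding of about two periods of the lowest cutoff.
Zero phase matters because every downstream feature is a latency. The
0.5–30 Hz band-pass is applied directly to the raw signal: its lower edge
already removes baseline wander, and cascading a separate 0.5 Hz high-pass
in front doubles the low-frequency roll-off and visibly smears the wave
feet in the first seconds of a recording. `remove_baseline()` remains
available as an explicit emulation of a device-side high-pass.

Beat detection follows the Shannon-energy-envelope + Hilbert-transform
scheme:

1. 1–4 Hz band-pass (`emphasize_percussion()`, order 2) isolates the
   beat-rate component;
2. the emphasized signal is half-wave rectified and mapped to its Shannon
   energy `SE(n) = −x̂² ln x̂²`. Rectification is essential here: the
   Shannon energy is sign-blind, and the broad negative diastolic trough of
   the 1–4 Hz signal otherwise contributes a second envelope bump per beat
   that drags the smoothed apex ~0.2 s away from the percussion wave —
   beyond the refinement window;
3. the envelope is smoothed with a 2 Hz zero-phase low-pass. 2 Hz keeps
   the beat-rate fundamental for heart rates of 40–120 bpm while merging
   within-beat lobes, so exactly one bump survives per beat;
4. the Hilbert transform of the smoothed envelope, minus a 2 s
   moving-average (long enough not to distort beat-scale structure),
   crosses zero from positive to negative at each bump apex. The
   quadrature sign convention is chosen so that the apex is a downward
   crossing;
5. each candidate is refined to the maximum of the 0.5–30 Hz signal within
   a 0.25 s window centred on it; duplicate refinements collapse.

Cycle onsets are wave feet: from the steepest upstroke preceding each peak,
the detector walks left until the signal stops decreasing. Cycles run foot
to foot; the final incomplete beat is discarded, so P peaks yield P − 1
cycles. Rule-based quality flags replace manual screening so the step is
reproducible: duration outside 0.3–2.0 s, peak amplitude below 25 % of the
recording's median, or membership in an explicit exclusion list.

On noise-free synthetic cohorts the detector recovers 100 % of beats with
peak error ≤ 2 samples at 500 Hz; with white noise at 5 % of pulse
amplitude it stays above 95 % within ±0.05 s (the test suite and the
acceptance script recompute both).

## Time-domain features

Cycles are first classed into eight morphologies by a deterministic
decision tree over (number of prominent smoothed local maxima, presence of
a descending-limb shoulder via the second-derivative sign pattern, presence
of a rebounding notch minimum). The original eight-class taxonomy exists
only in out-of-print reference material, so the tree here is the package's
own auditable reconstruction of the idea: class the shape first, then
search landmarks with shape-appropriate rules. Distinct tidal/dicrotic
crests come from the alternating extremum sequence after the percussion
peak; merged ("shoulder") tidal waves fall back to the inflection pair of
the second derivative. Landmarks a shape does not support are `NA`,
never zero.

Amplitudes are measured above the line joining the cycle's first and last
samples, which removes residual in-cycle drift. The 20 features are the
landmark times and amplitudes, the widths `w31`/`w51` (total time above
1/3 and 1/5 of `h1`, with linearly interpolated crossings — note
`w31 ≤ w51` since a lower threshold is crossed for longer), their ratios
to the period, the ratios `h1/t1`, `h3/h1`, `h4/h1`, and the trapezoidal
areas `As` (onset to `t4`) and `Ad` (`t4` to end), which sum exactly to
the total cycle area.

## Wavelet-packet features

Each cycle is decomposed with a four-level db6 wavelet *packet* transform —
both approximation and detail branches split at every level — giving
2 + 4 + 8 + 16 = 30 subbands in natural (breadth-first) order. Boundary
handling is periodization, chosen because it keeps the filter bank
orthogonal at every level: coefficient counts halve exactly and subband
energies sum to the input energy, which the tests verify to 1e−8. The
filter-bank convention was cross-checked coefficient-for-coefficient
against an independent reference wavelet implementation, and those values
are frozen into the test suite.

Per subband, three zero-lag cumulants are computed with biased estimators
after mean removal — `c2 = m2` (variance), `c3 = m3`, `c4 = m4 − 3m2²` —
*not* the standardized skewness/kurtosis ratios: the defining estimator
family is the un-normalized cumulant. The 90 HOS features are laid out in
order-major blocks (HOS1–30 = `c2` of subbands 1–30, HOS31–60 = `c3`,
HOS61–90 = `c4`); the mapping is a package convention, documented and
stable, since several layouts are equally consistent with the feature
names. The 30 E features are the non-normalized Shannon energy entropies
`E = −Σ s² ln s²` of the raw coefficients (convention `0·ln 0 = 0`; the
value may be negative, e.g. a single coefficient of 2 gives `−4 ln 4`).

## Feature selection and evaluation

Numeric columns are discretized by supervised entropy-based binning with
the minimum-description-length stopping rule; feature–class and
feature–feature associations are symmetric uncertainties on the binned
data. The CFS merit of a subset of size `k` is
`k·r̄cf / √(k + k(k−1)·r̄ff)` — reward class correlation, penalize
redundancy. Best-first search proceeds forward from the empty set with an
open list ordered by merit and stops after five consecutive non-improving
expansions; ties break lexicographically so the search is deterministic.
On banks of ≤ 12 features the search attains at least 95 % of the
exhaustive-search merit in the tests (in practice it matches it).

Selection runs on the training portion of each of 10 stratified folds, and
each feature's occurrence frequency is `OF = folds chosen / 10 × 100` — a
feature chosen in 5 folds has OF = 50 %. Age and BMI enter the bank like
any other column, with no exemption from elimination. Selection folds and
evaluation folds use independent seeds by default.

Evaluation is 1-nearest-neighbour on features min–max normalized with
training ranges only (the bank mixes seconds, amplitudes and entropies;
zero-range features are inert), distance ties broken by the lowest
training row index. Confusions are pooled over folds — matching a single
ACC/SE/SP value per experiment column — with positive = hypertension
history, `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `ACC = (TP+TN)/total`,
`FPR = 100 − SP`, `TPR = SE`. Since a hard 1-NN emits no probability, the
ROC score is the margin `1/(1+d₊) − 1/(1+d₋)` between nearest-per-class
distances, and the ROC area uses the rank (Mann–Whitney) formulation with
half-credit for ties, which coincides with trapezoidal integration of the
empirical curve. The OF-sweep report evaluates the full bank, all
ever-selected features, and one subset per distinct OF level.

## Problem sizes, numerical choices, limitations

The shipped tests and the acceptance script run the study structure at
desk scale: cohorts of tens of subjects per cell for end-to-end runs,
200-recording cohorts for segmentation recovery, and 500-per-class feature
banks with standardized effect 1.5 on five designated columns for
selection/classification sanity; the original study's 770-subject, 6,075
cycle cohort is emulated in proportions, not size, and its reported
accuracies are not reproduction targets since the data are undeposited.

Numerical conventions worth knowing: odd-length subbands are extended by
repeating the last sample before each packet split; the wavelet stage
requires cycles of at least 16 samples; flat cycles and empty subsets are
errors, not silent zeros; degenerate metric denominators (no positives or
no negatives) raise errors; all-NA feature columns (landmarks never
detectable in a group) are dropped before selection; missing TD values are
median-imputed from the training portion inside the 1-NN only.

Known limitations: the shape taxonomy is a reconstruction, not the original
clinical rule set; the detector assumes a dominant percussion wave and will
mislocate beats in waveforms where the dicrotic wave rivals it; the
generator's independence of beats within a recording understates real
serial correlation; and synthetic separability says nothing about clinical
effect sizes.
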