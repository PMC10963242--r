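---
title: "Methods: cuffless blood-pressure estimation from PPG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless blood-pressure estimation from PPG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem and the signal

Cuff sphygmomanometry is accurate but intermittent and uncomfortable; a
fingertip photoplethysmogram (PPG) is cheap and continuous but measures
blood *volume* changes, not pressure. The premise of this package is that
the shape of a single PPG pulse — the relative heights and timings of its
systolic peak, dicrotic notch and diastolic wave, the sharpness of its
upstroke, its harmonic content — carries enough information about arterial
stiffness and peripheral resistance to regress systolic (SBP), mean
arterial (MAP) and diastolic (DBP) pressure directly, without calibration
against a cuff or a second sensor. MAP is defined throughout as
(2 DBP + SBP)/3.

The input is deliberately minimal: 2.1-second fingertip segments sampled at
1 kHz (2100 samples), up to three per subject, plus the subject's age and
sex. This mirrors the public fingertip PPG database collected at a hospital
with a hardware band-pass of 0.5–12 Hz, reference pressures from an
upper-arm oscillometric monitor, and reference ranges of roughly 80–174
mmHg (SBP) and 42–104 mmHg (DBP).

## Pipeline

1. **Quality screening.** The skewness of a segment's amplitude
   distribution is used as a signal-quality index: a clean pulse hugs the
   diastolic baseline and spikes briefly at systole, so its histogram is
   right-skewed, while clipped, flat or inverted segments are not. We use
   the population third standardized moment,
   $\mathrm{SQI} = m_3 / m_2^{3/2}$, and keep segments with SQI at or above
   a threshold. No published cut-off reproduces the original study's
   keep/reject counts, so the default threshold is 0 (any right-skewed
   segment passes); it is a `sqi_threshold` argument everywhere. Zero
   variance segments are flagged with a distinct reason code rather than
   scored.

2. **Normalization and filtering.** Each segment is min–max normalized to
   [0, 1] and then low-pass filtered. Four filters are provided —
   7th-order Butterworth (default), centered moving average, windowed-sinc
   FIR, and db4 wavelet detail soft-thresholding. The cutoff defaults to
   12 Hz, the ceiling of the acquisition hardware's own band-pass, so the
   software filter never removes in-band pulse content. The Butterworth and
   FIR paths are applied forward and backward with odd-reflection padding
   and steady-state initial conditions, so they are zero-phase: fiducial
   *times* are the features, and a causal filter would bias every one of
   them. Baseline drift below 0.5 Hz is inside the passband and is *not*
   removed; per-cycle baseline correction (below) absorbs it. This is a
   documented limitation, not an oversight.

3. **Cycle selection.** Systolic peak candidates are local maxima with
   topographic prominence at least 0.1 on the normalized scale. Because a
   pronounced diastolic wave can also clear that bar, the pulse period is
   first estimated from the autocorrelation peak in the 0.33–1.5 s lag
   range and peaks closer than 55% of it are culled, keeping the more
   prominent one (with a hard floor of 60/180 s — no adult heart beats
   faster than 180/min). Cycles run onset-to-onset, where an onset is the
   minimum between consecutive systolic peaks; a leading/trailing onset is
   searched within about one period of the first/last peak so that a 2.1-s
   record holding only two complete beats still yields a usable cycle, but
   a trailing onset is only accepted when a full period of signal follows
   the last peak — truncated final beats never become cycles. Cycles whose
   length deviates more than 30% from the period estimate are dropped. Of
   the surviving cycles the one with the largest systolic amplitude —
   measured from the cycle-onset value, which makes the comparison robust
   to residual drift — is the *best cycle* used for feature extraction;
   exact ties go to the earliest beat.

4. **Features.** 48 slots: 21 from the waveform (amplitudes x, y, z of the
   systolic peak, diastolic peak and dicrotic notch, their times t1, t3,
   t2, the pulse interval tpi, the width at half systolic amplitude,
   three areas split at t1 and t2, and a set of printed ratios), 8 from
   the first derivative, 11 from the second derivative (a/b/e-wave
   amplitudes and timings), 6 spectral (the three largest harmonic peaks
   in 0.5–12 Hz with their magnitudes), plus age and sex (female = 0,
   male = 1). `ppg_feature_names()` is the canonical ordering. Conventions
   worth spelling out:

   * Amplitudes are measured relative to the cycle-onset sample, and times
     from the cycle onset, in seconds.
   * The notch is the most prominent local minimum in the window
     (t1, t1 + 0.6 (tpi − t1)); the 0.6 factor stops the search before the
     end-of-cycle trough. If no local minimum exists the maximum of the
     smoothed second derivative in that window is used; if that also fails
     the cycle is flagged and skipped — flagged, logged cycles are how
     notch-free ("unfit") waveforms are kept out of the feature table.
   * Slot 14 ("inflection point area ratio") is A3/(A1+A2) as printed in
     the source feature table; the closely related A2/A1 is attached as an
     auxiliary attribute because selection literature sometimes labels
     slot 14 that way. Slot 15 implements the printed formula
     (A2+A3)/A1. Slot 16 is t1/x exactly as printed — the physical rising
     slope would be x/t1 — with a `slope_convention` switch to flip it.
   * Slot 17's denominator (tpi − t3) is guarded: cycles with t3 within
     5 ms of the cycle end are rejected instead of emitting a near-infinite
     slope.
   * On the first derivative, a1/b1 are the global maximum and following
     minimum; tb1 is the *elapsed time from a1 to b1* (the printed
     definition) while ta1, te1 are measured from the cycle onset and tl1
     is the last zero-crossing of the derivative, linearly interpolated.
     On the second derivative the reference point l2 is the cycle onset;
     the a-wave is the maximum before the systolic peak, the b-wave the
     following minimum, the e-wave the largest maximum after the b-wave
     within the first 85% of the cycle. The second derivative is smoothed
     with an 11-sample moving average before landmark search (double
     differencing at 1 kHz amplifies noise by ~10^6), and the landmark
     amplitudes are read off the same smoothed signal.
   * The spectrum is computed from the full mean-removed 2.1-s record
     (zero-padded to 4096 points, no window), not from the single cycle —
     one cycle cannot resolve harmonics ~1.2 Hz apart. Peaks below 5% of
     the strongest in-band magnitude are ignored as leakage ripple.

5. **Feature selection.** Two methods, both authored here from their
   defining equations:

   * **CFS** scores a candidate subset by the Pearson correlation between
     per-pair response distances $E_y = y_i - y_j$ and signed per-pair
     feature distances $E_X = \mathrm{sign}(E_y)\sqrt{\sum_k \Delta_k^2 / p}$
     over all unordered instance pairs, maximized by greedy forward
     addition. Features are standardized first (the slots mix seconds,
     ratios and spectral magnitudes; unstandardized distances would be
     dominated by one unit). One property deserves emphasis: because the
     sign of $E_X$ is *copied from* $E_y$, the fitness of a pure-noise
     feature is not 0 but concentrates at $2/\pi \approx 0.64$ for
     Gaussian data — the method's null floor. Informative subsets push the
     correlation from that floor toward 1, and the greedy search only ever
     compares candidates against each other, so the offset is harmless;
     but anyone reading raw fitness values should know 0.64 means "no
     information".
   * **ReliefF** initializes all weights to zero and, for each target
     instance, subtracts the per-feature difference to its nearest *hit*
     and adds the difference to its nearest *miss*, each divided by the
     number of sampled targets. Features are min–max scaled so the
     continuous difference |v1 − v2| is already range-normalized and
     weights stay in [−1, 1]. Blood pressure is continuous, so "hit" and
     "miss" need a definition: instances whose response differs by less
     than the 10th percentile of all pairwise response differences are
     same-response, those above the 90th are different-response; a
     response with few distinct values falls back to the classic
     equal/unequal rule. Defaults follow the single-nearest-neighbour
     update (k = 1) and sample every instance (m = n), which makes the
     weight vector deterministic.

   Default subset sizes are per-target: CFS keeps 15 (SBP) / 16 (MAP) /
   16 (DBP) features, ReliefF 15 / 16 / 15. Ties in rank are broken by the
   lower slot index.

6. **Regression.** Four families behind one interface, with defaults: SVR
   (RBF kernel, C = 100, ε = 0.1), random forest (150 trees, max depth
   13), decision tree (min leaf 17, max depth 12, min split 5), and
   k-nearest-neighbour regression (K = 51, Euclidean distance). The
   forest and tree are fit with variance splitting: no installed R tree
   library exposes an L1/MAE split criterion, so that single setting
   deviates from the reference configuration while every other
   hyperparameter matches. The KNR `leaf_size` is a kd-tree build detail
   with no effect on brute-force neighbour search and is recorded but
   unused. K larger than the available training rows is clamped to
   n − 1 with a warning.

   Splitting is always by *subject*: 80% of subjects train, 20% test, and
   10-fold cross-validation runs over training subjects, so no subject's
   segments ever straddle a split. Features are standardized inside each
   training fold only. An optional grid search scores hyperparameter
   combinations by mean cross-validated MAE. Each segment is one training
   instance linked to its subject's reference pressures.

7. **Evaluation.** Six indices with errors defined as actual − estimated
   (R², MAE, MSE, RMSE, mean error, and error SD with the n − 1
   denominator), the AAMI device criterion (|ME| ≤ 5 mmHg, SD ≤ 8 mmHg,
   ≥ 85 subjects — inclusive limits, following the tabulated "≤5 ≤8 ≥85"
   form), BHS grading by cumulative percentages of absolute errors within
   5/10/15 mmHg (A = 60/85/95, B = 50/75/90, C = 40/65/85, else D), and
   Bland–Altman limits md ± 1.96 sd under the same sign convention.

## The synthetic cohort generator

Every stage above is testable without clinical data because the package
ships a generator with full ground truth. One beat is the sum of three
Gaussian bumps — systolic, a broad shoulder under the notch region, and
diastolic — tiled at the beat period with onsets at the pre-systolic
minimum; the configured amplitude ratios and time fractions position the
bumps, and the *realized* landmarks (which shift slightly because the
bumps overlap) are located on the rendered noiseless waveform and stored
as ground truth, so landmark-recovery tests compare against what the
waveform actually contains. Noise is additive: sub-0.5 Hz sinusoidal
drift, a powerline tone, and white Gaussian noise (defaults 0.05 / 0.02 /
0.01 of the unit systolic amplitude).

Cohorts draw SBP ~ N(127, 20²) clipped to [80, 174] and DBP ~ N(71, 11²)
clipped to [42, 104] (correlated, pulse pressure ≥ 15 mmHg), matching the
demographics of the reference database, and map them to morphology through
a fixed monotone rule: heart rate rises with MAP (0.3 bpm/mmHg around
70 bpm), the diastolic amplitude ratio rises (+0.003/mmHg) and the
systolic time fraction falls with SBP, the notch shoulder rises and the
diastolic timing falls with DBP. Small per-segment jitter models
beat-to-beat variability; the reference study does not describe its
subjects' variability, so the jitter magnitudes (e.g. 0.8 bpm, 0.006 on
the amplitude ratio) are our own choice, set well below the across-cohort
spread. Stored reference pressures are the true generating pressures plus
N(0, 3²) mmHg — the error floor of an oscillometric reference device.
One integer seed drives everything; the same seed reproduces a cohort
bit for bit.

What passing tests on this cohort do and do not show: they verify the
pipeline's internal consistency (landmarks recovered where they truly
are, features computed per their definitions, selection finding planted
signal, regression inverting a monotone feature→BP map at the label-noise
floor). They do not show clinical accuracy — real PPG morphology varies
with pathology, contact pressure and vasomotion in ways three Gaussians
do not capture, and the real feature→BP relation is far noisier than the
generator's. Numbers from the synthetic cohort are pipeline diagnostics,
not device-validation results.

## Numerical choices and edge cases

* Zero-phase filtering uses odd-reflection padding of three filter lengths
  with steady-state initialization; DC passes with error < 1e-6. The
  recursive 7th-order path in direct form carries ~1e-7 roundoff on
  broadband inputs, so exact-linearity checks use 1e-6 there (1e-9 for the
  FIR paths).
* Preprocessing twice is not bit-stable: re-normalizing rescales by the
  tiny amplitude the filter shaved off the peak, so repeated application
  moves samples by ~1e-3 RMS. Documented as passband stability, not exact
  idempotence.
* The wavelet path pads to a power of two by reflection and thresholds
  each detail level with its own universal threshold (level-wise MAD), so
  band-limited interference such as a mains tone, which concentrates in
  one level, is actually attenuated.
* Degenerate inputs fail loudly and specifically: constant signals cannot
  be normalized or scored for skewness; zero feature denominators name the
  feature; non-finite training features name the row and column;
  constant responses short-circuit every regression family to a constant
  predictor (SVR has no support vectors there).
* All tie-breaks are deterministic and documented: equal best-cycle
  amplitudes take the earliest beat, equal selection scores take the lower
  slot index, equal grid MAE takes the first combination.
* Problem sizes in the test suite — 100-record landmark cohorts, 100
  seeded selection runs at n = 200, a 150-subject end-to-end cohort with
  20 split seeds — were chosen as the smallest sizes at which the
  stochastic properties stabilize well away from their thresholds.

## Known limitations

* Baseline drift inside the 0–12 Hz passband is only mitigated (per-cycle
  baseline referencing), never removed; very large drift can still move
  cycle onsets within the flat inter-beat valley.
* The SQI threshold is a calibrated stand-in; the original study's exact
  keep/reject operating point is not reproducible from its description.
* Variance splitting for the tree ensembles (see above).
* The generator's beat-to-beat jitter model and the continuous-response
  hit/miss quantiles for ReliefF are package decisions where the source
  material is silent; both are exposed as parameters.
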