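---
title: "Measuring daily-life gait speed from a belt-worn accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring daily-life gait speed from a belt-worn accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbelt)
```

## The measurement problem

Usual gait speed — one walk over a timed walkway in a laboratory — is the
standard functional measure in geriatric assessment and a diagnostic
component of sarcopenia.  A waist-worn accelerometer instead observes
thousands of walking episodes per week in free-living conditions, which
raises two questions this package addresses: how to turn a raw triaxial
acceleration stream into gait-speed measurements, and how to summarise those
measurements into person-level descriptors that can be related to muscle
mass, strength and sarcopenia status.

The chain is:

1. **Magnitude.** The per-sample Euclidean norm of `(ax, ay, az)` minus its
   median.  The median subtraction removes the static 1-g gravity component
   without assuming which axis is vertical — a belt-worn device has a stable
   but unknown orientation, so all downstream processing is
   orientation-independent.
2. **Step detection.** Steps are local maxima of the (optionally band-passed
   and smoothed) magnitude, filtered by topographic prominence and a minimum
   peak separation.  When two candidates are closer than the separation the
   higher one wins; equal heights keep the earlier peak, so detection is
   deterministic.
3. **Step intervals.** The time between consecutive steps, quantized to the
   nearest multiple of 0.1 s — the interval resolution of the class of
   devices this models.  Decimal ties (x.x5) round up; an interval that
   would round to zero is clamped to 0.1 s because a step interval cannot be
   zero.  The implementation adds a 1 ns guard so decimal ties that sit a few
   ulp below the binary midpoint (0.35 is stored as 0.34999…) still round up.
4. **Stride model.** Step length is a sex-specific constant times body
   height, `L = k · h`, with the pedometry defaults `k_male = 0.415` and
   `k_female = 0.413` (both configurable).  Instantaneous speed over one
   interval is `L / τ`; a walking bout's speed is the arithmetic mean of its
   per-interval speeds.  The harmonic alternative (total distance over total
   time) was rejected for simplicity and because the per-interval speeds are
   the quantity the device model defines.
5. **Bouts.** A walking bout — the unit of one gait-speed measurement — is a
   maximal run of steps whose gaps never exceed `max_gap` (default 2.5 s),
   with at least `min_steps` steps (default 8, about 4 s of walking).  The
   defaults exclude shuffles and isolated steps; at free-living rates they
   yield on the order of 70 bouts and ~90 minutes of walking per day, the
   scale reported for belt-worn devices in older men.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `smoothing_window` | 0.15 | s | short enough to keep heel-strike peaks separate at 4 steps/s |
| `min_peak_separation` | 0.25 | s | cadence ceiling of 4 steps/s |
| `min_prominence` | 0.05 | g | below walking peaks (~0.2–1 g), above sensor noise |
| `band` | off | Hz | optional 2nd-order Butterworth; cadence lives in 0.5–3 Hz |
| `k_male`, `k_female` | 0.415 / 0.413 | – | pedometry step-length convention |
| `max_gap` | 2.5 | s | longer pauses end a bout |
| `min_steps` | 8 | steps | ~4 s of continuous walking |
| `min_wear_days` | 10 | days | eligibility threshold for person-level summaries |
| matching `tolerance` | 0.3 | s | about half a typical step interval |

The device family this models publishes neither its filter design nor its
thresholds, so all detection parameters are exposed as configuration rather
than claimed as faithful to any proprietary implementation.

## Daily-life analytics

* **Per-day summaries** average speed per calendar date and sum bout
  durations into walking minutes.
* **Diurnal profile** uses twelve 2-hour bins `[1,3), [3,5), …, [23,1)`,
  chosen so that the early-morning window 5–7 AM — where free-living cohorts
  walk fastest — is a single bin; edges are configurable and the last bin
  wraps midnight.  Empty bins are reported as missing, never zero.
* **Percentile vs usual speed.**  Each measurement is expressed as
  `100 · speed / usual`; the person-level summary is the *median* of these
  ratios, and the tails are the strict fractions above 125% and below 75%.
  Reading "percentile" as the ratio×100 is an interpretation: it is the only
  reading consistent with person-level values that have a median near 100
  and a range extending far above it.
* **Weekday/weekend split** partitions by calendar day; walking minutes per
  day normalise by the distinct days observed in each partition.
* Person-level mean/median/SD/CV pool all measurements rather than daily
  means, matching how large free-living datasets are usually summarised
  (hundreds of thousands of pooled measurements).  Whether group contrasts
  should pool measurements or average within person first is genuinely open;
  the statistics layer takes plain vectors, so both are available.

## Sarcopenia classification

The AWGS rule for men: low muscle mass (ASM/height² < 7.0 kg/m²) **and**
(low strength, handgrip < 28 kg, **or** low performance, usual gait speed
< 1.0 m/s).  All inequalities are strict, exactly as the cutoffs are
printed; a value at the cutoff is normal.  Handgrip is the mean of exactly
three dominant-hand trials.  The ASM index is always recomputed from mass
and height — a file-supplied index is ignored with a warning so there is a
single source of truth.  Cutoffs are a configuration block
(`awgs_cutoffs()`) so female values can be supplied; only the male defaults
ship because the cohorts this targets are male-only.

## The synthetic-data layer

The generators exist so that every stage is testable without any real
recording, with ground truth known by construction.

**Walking signals** are a two-harmonic sinusoid on the 1-g baseline:
`az(t) = 1 − A·cos(2πct) + fA·cos(4πct) + ε`.  The phases are chosen so
the fundamental's maxima — the true step times — fall at `(k + ½)/c`, and
the second harmonic peaks at those same instants; for `f < 0.25` the summed
noiseless signal therefore has its local maxima exactly at the true step
times, which is what makes zero-noise end-to-end recovery an exact test.
This is a signal-shape stand-in, not biomechanics: it exercises peak
picking, separation and quantization, but says nothing about double-support
asymmetry, arm swing, or surface effects.

**Measurement streams** draw Poisson bout counts per day (default rate 73),
bout times uniformly in waking hours (05–23 h), and speeds
`base + A_d·g(hour) + w·[weekday] + N(0, σ)` truncated above 0.3 m/s.
The diurnal shape `g` is a Gaussian bump centred at 06:00 (SD 1.5 h),
re-centred to zero mean over the waking hours so that `base` remains the
expected speed; its amplitude defaults to `A_d = 0.06` m/s and the weekday
effect to `w = 0.01` m/s — a visible morning peak and a just-detectable
weekday advantage, the magnitudes typical of free-living gait in older men.
The within-person SD defaults to `σ = 0.25` m/s; combined with the
between-person SD (0.08 m/s in the normal group) this reproduces the
pooled measurement SD of ≈0.26 m/s such cohorts report.  Bout durations are
gamma (shape 2, mean 72 s), so the default day holds ≈88 minutes of walking.

**Cohorts** default to 13 sarcopenic / 93 normal men with group-wise normal
attribute distributions — daily-life speed 1.12 (0.11) vs 1.23 (0.08) m/s,
usual speed 0.97 (0.12) vs 1.28 (0.16) m/s, grip 27.4 (5.4) vs 37.2 (5.8)
kg, ASM index 6.39 (0.34) vs 6.79 (0.77) kg/m², age 76.0 (6.2) vs 70.5
(7.6) years, BMI 25.0 (2.5) vs 24.5 (2.5) kg/m².  Height is N(1.67, 0.06) m
in both groups — not part of the published group tables, chosen as typical
for older Korean men.  Attributes are drawn independently within group
(only marginals are published); rejection sampling guarantees each
sarcopenic-group member satisfies the AWGS rule and each normal-group
member does not, with a budget of 10,000 attempts before an unsatisfiable
specification is reported.  Because attributes are drawn independently, the
generated correlation structure between, say, usual and daily-life speed is
weaker than in real cohorts; tests that pass on these data demonstrate the
*pipeline's* correctness, not physiological validity.

All generators accept a seed, are bit-reproducible given one, and never
disturb the caller's RNG stream.

## Validation metrics

Detected steps are scored against annotated truth by one-to-one greedy
matching: true steps in order, each to the nearest unmatched detected step
within ±0.3 s.  Greedy equals optimal assignment whenever inter-step spacing
exceeds twice the tolerance on both sequences (each step then has at most
one candidate partner); the test suite verifies this equality against an
exhaustive alignment oracle on short sequences.  Reported metrics are
sensitivity `100·tp/(tp+fn)`, positive predictive value `100·tp/(tp+fp)`,
and step-count consistency `100·(1 − |N_det − N_true|/N_true)` floored at
zero — the consistency formula is itself an interpretation, since published
device validations quote the number without defining it.  One behaviour
worth knowing: heavy noise makes the detector over-trigger, so sensitivity
under a loose window stays high while PPV and consistency fall; the
degradation tests therefore score timing with a tight 0.1-s window.

## Numerical choices and degenerate inputs

* Quantization ties round up via a floor(+0.5) with a 1 ns guard (above).
* Plateau peaks are represented by their first sample; separation conflicts
  resolve highest-first, then earliest.
* Truncated-normal draws resample rather than clip, so no synthetic speed,
  interval or mass is ever non-positive.
* Empty inputs are contracts, not accidents: an empty recording, an empty
  bout list, a profile with zero measurements and an empty truth sequence
  each raise a classed error naming the problem.
* Timestamps are timezone-naive local clock time, stored pinned to UTC so
  calendar arithmetic never crosses DST; day-of-week and hour-of-day always
  reflect the clock the device recorded under.

## Problem sizes used in the built-in experiments

The shipped tests and the acceptance script run at sizes chosen to make the
statistical checks decisive while staying desk-scale: zero-noise recovery
on 60-s signals at 50 Hz across cadences 1.0–2.5 steps/s; quantization and
segmentation properties over 10,000 and 500 random step trains; diurnal
argmax over 100 seeded 6-participant months; and cohort parameter recovery
over 200 seeded replicates of the full 106-participant, 4-week default
cohort (≈217,000 measurements each), where the group contrast is tested on
pooled measurements and group means are checked against the generator
targets within three standard errors of the participant-level means.

## Known limitations

* The stride model is static: step length does not adapt to cadence,
  amplitude or incline, so fast-walk speeds are compressed and slow-walk
  speeds inflated relative to adaptive models.
* Whether the sex constant × height product represents a step or a full
  stride in any particular commercial device is not public; the constant is
  configuration, and halving/doubling it rescales every speed linearly.
* Pathological gait (parkinsonian shuffling, hemiplegic asymmetry) violates
  both the signal model and the cadence priors; the package makes no claims
  there.
* The analytics assume gap-free uniformly sampled recordings; files with
  dropouts must be split upstream.
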