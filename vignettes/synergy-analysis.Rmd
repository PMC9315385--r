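---
title: "From surface EMG to knee torque and redundant muscle synergies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From surface EMG to knee torque and redundant muscle synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergylab)
```

## The problem

Surface electromyography (EMG) measures the electrical activity of
muscles, but not the joint torque that activity produces: many different
co-activation patterns ("synergies") of the muscles crossing a joint can
yield the same net torque, and the mapping from activation to torque runs
through muscle mechanics that cannot be observed non-invasively.
`synergylab` implements a desk-scale version of a three-stage workflow for
studying this redundancy in an isometric knee-extension task:

1. **EMG processing** — localize contraction trials in multichannel
   recordings, extract a per-muscle activation feature, and normalize it
   into the `[0, 1]` activation range a simulated muscle accepts.
2. **Musculoskeletal simulation** — drive a planar Hill-type knee model
   with those activations and measure the muscle-driven knee torque by the
   counter-torque method: increase an opposing torque until the limb
   settles back at the recording angle; at equilibrium the two are equal.
3. **Synergy search** — use a genetic algorithm (GA) to evolve alternative
   7-muscle activation vectors that reproduce the same torque, making the
   redundancy of the activation-to-torque map explicit.

The recorded protocol this package emulates is an isometric knee-extension
study: seven muscles (RF, VL, VM, Se, BF, MG, TA) sampled at 1.9 kHz with
a 20–450 Hz bandwidth, four knee angles (0°, 20°, 60°, 90°), six
5-second maximal contractions per angle separated by 3-minute rests.  The
original human recordings are not redistributable, so the package ships a
synthetic-session generator with full ground truth; every downstream stage
is tested against that ground truth.

## The synthetic EMG generator

`generate_session()` models each channel as *amplitude-modulated
band-limited Gaussian noise*.  A unit-variance carrier confined to the
recording band (synthesized spectrally, so the band limitation is exact)
is multiplied by a gain that equals the noise floor (default 0.05 of full
scale) at rest and rises, with 0.25 s raised-cosine ramps, to the muscle's
profile amplitude during each contraction.  Trial centres are jittered
(Gaussian, sd 0.5 s, truncated at 3 sd) and rest is placed before the
first and after the last trial, so detection cannot assume trials start at
the origin.

This is deliberately *not* a motor-unit action-potential model: the
downstream features (spectrogram power and the frequency-weighted sum
below) depend only on the time–frequency amplitude structure, which the
noise model reproduces.  What passing tests demonstrate is therefore that
the pipeline recovers amplitude structure correctly — not that it is
robust to MUAP waveform shape, electrode crosstalk, or motion artifacts,
none of which are modelled.

The default activation-amplitude profile encodes the empirical sign
structure of the task: quadriceps amplitudes fall strictly with knee
flexion angle while Se and TA rise weakly, with VM the dominant
quadriceps muscle.  Two consequences were engineered deliberately and
are worth knowing about:

* after per-trial max-normalization, the *reference* muscle switches from
  VM at 0–60° to Se at 90°; this is what makes the normalized quadriceps
  activations strictly decrease with angle (the package-level restatement
  of the negative quadriceps–angle Pearson correlation);
* the quadriceps force–length curve in the default knee model ascends
  through this angle range, so the measured balancing torque still
  *increases* from 20° to 90° even though quadriceps activation falls —
  mirroring the torque pattern expected of the physical task.

The profile values themselves (e.g. VM from 0.95 at 0° to 0.35 at 90°)
are stylized: they are chosen to reproduce sign structure and relative
ordering, not calibrated millivolt levels.  Full-scale units are
arbitrary throughout because the pipeline normalizes per trial.

## Trial localization

`compute_spectrogram()` (Hann window, 0.25 s, hop 0.125 s — resolving a
5-s trial into ~40 frames at 4 Hz frequency resolution) feeds
`summed_activity()`, which collapses the seven per-muscle spectrograms
into a single activity trace by summing over channels and frequencies.
Frames exceeding an SNR threshold become *activity events*;
`localize_trials()` clusters the event times into `n_trials` groups and
takes each cluster's median as the trial origin, with onset/offset at
origin ± 2.5 s.

Numerical choices that required care:

* **SNR threshold.** The threshold is `rest mean + 3 × rest sd`, with the
  rest statistics estimated from the lower tail of the trace (5th and 25th
  percentiles calibrated against a Gaussian bulk).  A plain lowest-quartile
  mean + 3 sd is biased low on rest-dominated sessions (the truncated
  quartile underestimates the rest spread so badly that the threshold can
  fall below the trace mean), while median + MAD fails when trials occupy
  close to half the session; the quantile-tail estimator behaves correctly
  in both regimes.  Events are strict exceedances (`>`, never `>=`).
* **Clustering.** Event times are 1-D, where the optimal
  within-sum-of-squares k-means partition is contiguous in sorted order
  and can be found exactly by dynamic programming.  The exact solver is
  deterministic and immune to the restart-dependent local optima that
  occasionally merge two trials when a general k-means routine is used.
* **Origins.** A 3σ threshold admits a ~0.1–0.5% false-event rate at
  rest by construction.  Cluster medians are therefore trimmed once:
  events farther than 2.5 s from the cluster median cannot belong to a
  5-s trial and are discarded before the final median.  With both fixes
  the localizer recovers all six origins within ±0.25 s on every tested
  study-scale session (20 seeds).

## Frequency cut-off and the activation feature

Most spectral amplitude sits at the low end of the band, and the
frequencies carrying high amplitude are a minority.  `compute_cutoff()`
turns that observation into a data-driven cut-off: average the full-record
FFT magnitudes over channels and sessions onto a 1 Hz grid, histogram the
frequency bins by amplitude, fit a scaled binomial probability-mass
envelope to the bin counts by least squares, and scan from low to high
amplitude for the first count deviating from the envelope by more than the
fit's RMS residual.  That bin centre is the amplitude threshold, and the
highest frequency still reaching it is the cut-off.  The construction is
scale-equivariant (doubling all amplitudes doubles the threshold and
leaves the cut-off unchanged) and, on band-limited synthetic sessions,
lands within one spectral bin of the 450 Hz generator band edge.  The
"binomial envelope" reading (a discrete distribution over amplitude-bin
indices, residual RMS as its standard deviation, scan from low amplitude
upward) is one of several defensible readings of the heuristic; it is
isolated behind `cutoff_from_spectrum()` so alternatives can be swapped.

The per-trial, per-muscle activation feature is the frequency-weighted sum

$$F_m = \sum_{f = f_\mathrm{low}}^{f_\mathrm{cut}} f \cdot v_m(f)$$

over the trial-segment FFT magnitude $v_m(f)$, with $f_\mathrm{low}$ = 20 Hz
(the hardware bandwidth floor).  Higher motor-unit recruitment raises both
amplitude and its high-frequency content, which the weighting tracks.  The
feature is linear in the spectrum and nonnegative.

`normalize_activations()` maps features to `[0, 1]` by dividing by the
maximal muscle (so one muscle is always at 1, the "maximal voluntary
effort" convention).  Normalizing to RF instead is available
(`method = "rf"`), but since RF is not guaranteed maximal that method may
produce values above 1, which are clipped with a warning — this is why
max-normalization is the default.  Note a structural consequence used by
the tests: per-trial max-normalization is *scale-invariant*, so a trial in
which all muscles were uniformly weaker is indistinguishable after
normalization; a sub-maximal execution is detectable only through a
changed extensor/flexor balance.

## The planar knee model

The musculoskeletal stage is a stylized sagittal-plane knee: a revolute
joint with the shank+foot as one rigid body (4.6 kg, 0.40 kg m² about the
knee, centre of mass 0.26 m distal), seven Thelen-style Hill muscles with
rigid tendons, viscous joint damping (1.5 N m s/rad) and soft joint stops
(50 N m/deg) outside 0–120°.  Gravity defaults to zero — the limb is
fully supported in the supine protocol — and is configurable for
sensitivity studies.

Each muscle produces
$F = F_{\max}\,(a \, f_L(\tilde\ell)\, f_V(\tilde v) + f_P(\tilde\ell))$
with a Gaussian active force–length curve (width 0.45, peak at
$\tilde\ell = 1$), an exponential passive curve engaging above optimal
length, and a hyperbolic force–velocity factor (1 at zero velocity,
saturating at 1.4 when lengthening).  Normalized fiber length is an
affine map of knee angle (quadriceps lengthen with flexion and stay on
the ascending limb through 90°; flexors shorten), and moment arms are
low-order polynomials in knee angle, signed anatomically (extensors
positive, flexors negative; TA crosses the ankle, not the knee, and has
zero knee moment arm — it is carried only for interface parity with the
7-channel recordings).  All values are literature-plausible
approximations for a ~75 kg adult, shipped as a semantically versioned
YAML file (`inst/extdata/knee_params_default.yaml`); analyses are
parameter-relative (compared against oracles computed from the same
parameters), never anatomy-absolute.

**Sign convention** (stated once, asserted everywhere): knee angle
increases with flexion, 0° is fully extended, joint torques are
flexion-positive, so extensor activity yields negative torque and drives
the angle toward 0°.

**Settling.** `settle()` integrates the damped dynamics with a
semi-implicit Euler stepper (dt = 2 ms) until the angular speed stays
below tolerance for 0.5 s.  Because activations are treated as
instantaneous (the task is static; no excitation dynamics) the settled
state is a static equilibrium, so a *fast settle path* solves the static
torque balance directly: locate sign changes of net torque on a
0.25°-grid, refine by root finding, and return the stable root (net
torque decreasing through zero) nearest the initial angle.  The two paths
agree to within 0.5° on test cases, and the static path is the default
for torque measurement and GA fitness, making the evolutionary runs about
three orders of magnitude faster than real-time integration.

**Balancing torque.** `balancing_torque()` reproduces the virtual
measurement protocol: increase a counter torque opposing the
muscle-driven one in 1 N m steps until the settled angle crosses back
over the target, then refine by bisection until the settled angle is
within 0.5° of the target *and* the torque bracket is tight (relative
width 10⁻⁴).  The second condition matters because 0.5° of angle maps to
~1 N m of torque at typical operating points; bisecting on torque keeps
the measurement within a fraction of a percent of the closed-form static
equilibrium value, which the test suite verifies on 50 random activation
vectors at max(2%, 0.05 N m).

## The genetic algorithm

`evolve()` searches over 7-gene individuals (one activation per muscle,
genes in `[0, 1]`) with the operator table: two-point crossover with
probability 0.5, per-individual mutation with probability 0.2 flipping
each gene independently with probability 0.05, tournament selection of
size 3.  "Flip" generalizes a bit flip to real genes as `g → 1 − g`,
which preserves the gene range; a uniform-resample mutation is available
behind `ga_config(mutation = "uniform")`.  Only modified offspring are
re-evaluated.  There is no elitism; the best-so-far individual is tracked
outside the population and its fitness trajectory is non-decreasing by
construction.

Fitness couples the GA to the simulation exactly as the torque
measurement does: the reference counter torque (measured from the natural,
EMG-derived activation) is held constant, the limb starts at the target
angle, and the individual's fitness is `cos(|a_current − a_target|)` with
the settled-vs-target angle difference converted to radians and capped at
π.  The conversion to radians keeps the cosine monotone over the whole
joint range (in degrees it would oscillate); fitness is 1 exactly when
the individual's muscle-driven torque equals the reference.  An
individual that cannot settle is evaluated at its end state.  Population
size (50) and generation count (40) are not dictated by the protocol;
they were fixed once so that the observed convergence scale (the
evolutionary search typically reaches the 0.9999 fitness threshold within
the first handful of generations, and always well before generation 20)
has headroom.

Because the fitness threshold is an *angle* criterion, the implied torque
precision varies with the local torque–angle stiffness: 0.9999
corresponds to 0.81°, which maps to roughly 1–2% of the reference torque
at the study angles.  This is the resolution at which "the same torque"
is meant whenever evolved and natural synergies are compared.

## End-to-end study and reporting

`run_study()` orchestrates the full reproduction for a synthetic cohort:
per subject and angle it generates the session, localizes trials, pools
the frequency cut-off across the subject's sessions (pooling across
subjects with different gains would mix histograms; a global pooling is a
config switch), extracts per-trial activations, and measures per-trial
balancing torques.  Failed trials are retained with a status column, and
trials whose in-trial activity does not exceed the rest level by a
contrast factor (default 1.5) are recorded as `no_activity` with zero
activations and torque — this gate is what makes a session with no
contractions at all report zero torque instead of amplifying noise
through the scale-invariant normalization.  A session in which nothing
exceeds the SNR threshold is classified the same way.

`pearson_by_muscle()` reports the per-subject, per-muscle Pearson
correlation between knee angle and normalized activation (raw features
via a flag), requiring at least three distinct angles and reporting
zero-variance series as undefined rather than zero.
`compare_synergies()` quantifies natural-vs-evolved similarity (per-muscle
differences, cosine similarity) and the relative torque error at the
target angle.

Problem sizes used by the shipped test suite and acceptance script: 20
study-scale sessions for localization recovery, 2 subjects × 4 angles × 6
trials for the correlation study, 20 GA seeds for the convergence median,
and 10 GA seeds per angle for torque recovery and the redundancy check —
sizes at which every stage's behaviour is already stable across seeds.

## Known limitations

* The EMG model omits MUAP shape, crosstalk, artifacts, and any real
  calibration; conclusions about real recordings require real data.
* The knee model is planar with rigid tendons and stylized geometry; its
  parameters are plausible, not subject-specific, and TA is inert at the
  knee by construction.
* The binomial-envelope cut-off heuristic is one reading of an ambiguous
  construction; alternative readings would shift the cut-off by a few
  bins (the feature sum is insensitive to this on band-limited data).
* Fitness equates torque matching with settling at the target angle under
  a fixed counter torque; this is exact for stable static equilibria but
  would need re-derivation for dynamic tasks.
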