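---
title: "Methods: simulating and analysing a VR interception task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a VR interception task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interceptvr)
```

This vignette is the package's account of its science: the task model the
synthetic-data generator implements, the signal-processing and
event-detection chain, the mixed-model analysis recipes, and the numerical
and design choices made where more than one defensible option existed.

## The task model

A participant stands 9 m behind the front wall of a 15 m virtual racquetball
court, 0.75 m left of the midline, and returns balls projected from a 2 m
high port on the front wall. Balls travel down the midline and bounce 3.5 m
in front of the start position. Two visually identical ball types differ
only in restitution: "normal" (coefficient 0.65) and "elastic" (0.85), mixed
at p(normal) = 0.67. After each trial the experimenter calls "hit" or "miss"
following a predetermined, outcome-independent schedule: 58% hits in the
low-failure-feedback condition, 42% in the high. Each participant completes
four 72-trial blocks -- the 2x2 crossing of pressure (low/high) and failure
feedback (low/high) -- and answers three probes after six pre-specified
trials per block: probability of failure (POF, 0-6), cost of failure (COF,
0-6) and an anxiety thermometer (0-10).

### Ball flight

The recorded constraints pin the flight down to one free choice. With
gravity $g = -9.8$ m/s², a launch height of 2 m and a floor-contact vertical
speed of $-9$ m/s, the vertical launch speed and flight time follow in
closed form:

$$v_{0y} = \sqrt{v_b^2 + 2 g h} \approx 6.47\ \mathrm{m/s}, \qquad
  t_b = \frac{v_b - v_{0y}}{g} \approx 1.58\ \mathrm{s}.$$

The horizontal speed is then set so the bounce lands 5.5 m from the front
wall ($\approx 3.49$ m/s). The launch angle is not recorded anywhere, so
this is one consistent solution, not the only one. The bounce is modelled as
an instantaneous reversal of the vertical velocity scaled by the ball's
restitution, with horizontal velocity conserved -- the simplest model
consistent with the stated coefficients; post-bounce vertical speeds are
therefore $0.65 \times 9 = 5.85$ m/s and $0.85 \times 9 = 7.65$ m/s. Both
ball types share the pre-bounce path exactly. All series are sampled at
90 Hz, the recording rate of the motion platform; the eye data in the
original set-up were sampled faster, but everything written to the trial
files lives on the single 90 Hz grid. Hit trials end with an abrupt
velocity change at a contact frame pinned to the sample grid; missed balls
continue past the player.

## The synthetic session generator

The generator produces what the downstream chain consumes -- per-trial
90 Hz time series (head, controller, gaze, ball), a manifest and a probe
table -- with known ground truth for every quantity a test might ask about.

**Gaze.** The injected sequence mirrors the predictive strategy of skilled
interception: pursuit of the early flight, one anticipatory saccade to a
point a configurable number of degrees above the bounce-point direction, a
fixation held from a configurable lead before the bounce until after it,
then a catch-up saccade back onto the ball and pursuit to the end of the
trial. Pursuit is modelled as a gain on the ball's angular displacement
(default 0.9). Saccades interpolate along the great circle with a
triangular velocity profile; their duration derives from the amplitude and
a nominal peak velocity (default 350 deg/s), floored at 100 ms. The head is
fixed at eye height (1.7 m), oriented at the bounce point -- players orient
toward the interception zone -- which makes the egocentric pitch of the
bounce fixation equal the configured offset exactly, a property the metric
tests exploit. Fixation jitter is Gaussian per frame (default 0.1 deg);
missing-sample runs start with a per-frame probability and have fixed
length.

**Swing.** The controller rests beside the hip, performs a backswing away
from the aim point, then a foreswing whose speed follows a sin² bell with
the configured peak (default 4 m/s) mid-swing, arriving at the aim point
exactly at the contact frame. Missed swings aim 0.5 m wide -- a realistic
whiff, large enough to clear the collision volume -- and rest on the
nominal contact-depth plane.

**Feedback schedules and probes.** Hit counts are the rounded nominal
proportions (42/72 and 30/72). Calls are a seeded permutation of that
multiset; probe trials are then drawn (rejection sampling, capped retries)
so that three probes follow hits and three follow misses, and the running
hit proportion at every probe is within one trial of the rounded nominal
count. Schedules are seeded per participant: whether the original sessions
reused one fixed order is ambiguous, and per-participant seeding is the
conservative choice for simulation studies.

**Self-reports.** POF and COF come from condition-effect linear models with
participant random intercepts and Gaussian noise; anxiety from POF, COF and
their product; all are clipped to their scales. The fixed-effect defaults
are the effect sizes the analysis recipes are designed to recover (feedback
on POF 0.46; pressure-by-feedback on COF 0.43; POF and COF on anxiety 0.18
and 0.29). Intercepts and variance components are generator choices made so
that every condition-cell mean sits at least three combined SDs from both
scale bounds: with meaningful boundary censoring a clipped linear model is
*not* recovered unbiasedly by a linear fit, and an early diagnostic showed
that even 1-2% floor contact attenuates the appraisal slopes by several
percent of their values. The package therefore prioritises exact
recoverability over matching any particular observed scale levels; the
generated anxiety level (~4 of 10) is a consequence of that choice, and
scale means are deliberately not recovery targets -- only the regression
coefficients are. True interception is drawn per trial from a participant-specific
hit rate (logit-normal around 0.75, SD 0.5 on the logit scale) independent
of the bogus feedback.

**What the generator does not emulate.** Head movement during a trial,
tracker latency and asynchrony between eye and motion streams, blinks (as
opposed to generic dropout runs), main-sequence curvature of saccade
profiles, smooth-pursuit catch-up dynamics coupled to retinal slip, swing
variability linked to anxiety, and any dependence of true performance on
feedback or appraisals (all couplings default to zero so that null-effect
calibration of the models can be tested). Passing tests therefore certify
the *chain* -- that events injected with known properties are recovered,
that estimators are calibrated when their assumptions hold -- not that the
detectors' thresholds are optimal for any particular human data set.

## Preprocessing

**Segmentation.** Release is the first frame of ball motion; a stationary
ball yields an exclusion flag, not an error. The bounce is the frame of
minimum ball height after release. Contact is detected as the first
post-bounce frame whose discrete second-difference acceleration deviates
from the gravity-only prediction by more than five times its pre-bounce RMS
residual (floored at 1e-3 m/s² so that exact, noise-free input does not
trip on rounding error); if no such frame exists the trial is a miss and
contact is the first frame where the ball's depth passes the racquet's. On
noise-free generator output all three landmarks match ground truth exactly,
which the tests assert.

**Filtering.** Head and controller positions are denoised with a dual-pass
(forward-backward, zero-phase) Butterworth low-pass at 10 Hz, second order
per pass -- the common motion-capture choice where the order is not
recorded. Gaze passes a three-frame median filter, then a second-order
zero-lag Butterworth at 50 Hz for saccade identification and 15 Hz for
positional tracking features. Each contiguous valid run is filtered
independently with odd-reflection padding after removing the run mean
(constants filter to themselves exactly, and the edge transient scales with
the fluctuation, not the level); runs shorter than the warm-up are left
unfiltered. A requested cutoff at or above the Nyquist frequency (the 50 Hz
saccade cutoff against 90 Hz data) is clamped to 0.99 x Nyquist with a
warning. One numerical subtlety: a second-order Butterworth at 0.99 Nyquist
has poles of radius 0.978 adjacent to $z = -1$ and rings visibly at the
Nyquist frequency when realised as a recursion, while its magnitude
response is unity to within $10^{-3}$; above 0.95 x Nyquist the package
therefore realises the filter as the identity, which is the numerically
sound implementation of "hardly any smoothing".

**Angles and kinematics.** World yaw is rotation about the gravity-aligned
vertical axis (zero toward the front wall), world pitch the elevation from
the horizontal plane at eye height; egocentric angles are the same
quantities for the gaze vector rotated into the head frame (quaternion
orientation, w-x-y-z). Angular velocity is the great-circle separation of
consecutive gaze direction vectors divided by the sample interval -- not
independent yaw/pitch differences -- and acceleration its first difference.
Missing samples propagate.

**Screening.** A trial's gaze analyses are excluded when more than 20% of
the segmented window is missing or any contiguous gap exceeds 100 ms; both
rules are strict inequalities, so a 9-frame gap (exactly 100 ms at 90 Hz)
is retained and a 10-frame gap is not. The missing fraction is assessed
over the segmented window (release to contact), the window every gaze
measure is computed on; swing and interception metrics are kept for such
trials and flagged, since the hand-tracking stream is unaffected.
Winsorization replaces values strictly beyond three SDs of their
condition-group mean with the boundary value, with mean and SD computed
once on the original data; zero-variance groups pass through unchanged.

## Event detection

**Saccades.** Candidates are contiguous runs where the absolute angular
acceleration of the 50 Hz-filtered gaze exceeds five times the trial's
median absolute acceleration (computed over non-missing frames of the
segmented window). Because the acceleration magnitude necessarily dips at
the velocity peak, candidates separated by at most three sub-threshold
frames are merged -- a slightly wider tolerance than a share-a-frame rule,
adopted after noise-free profiling showed a single saccade regularly
splitting into two lobes. A candidate becomes a saccade only if its gaze
velocity exceeds 40 deg/s for at least five consecutive frames *and* is at
least 20% above the ball's angular velocity over those same frames (the
same-five-frames reading is the stricter of the two possible ones);
candidates preceded, followed, or interrupted by missing data are rejected.
Onset and offset are then refined from the velocity peak outward to where
velocity re-enters a local baseline (median + 3 MAD of the flanking
pursuit/fixation samples, floored at 5 deg/s, bounded to 100 ms beyond the
candidate). This locates the outer edge of the flanking acceleration
extremum pair; the raw extrema themselves are degenerate for
triangular-profile saccades and unreliable when pursuit acceleration also
clears an adaptive threshold. On noise-free synthetic trials the refined
onsets sit within one frame of ground truth.

**Fixations.** A dispersion-threshold (I-DT) sweep grows a window while its
dispersion stays within 3 degrees and emits a fixation once the window
lasts at least 100 ms; windows never span missing samples. Dispersion is
the classic I-DT sum of yaw and pitch ranges; a maximum pairwise
great-circle metric is available behind a switch for users who prefer a
rotation-invariant criterion. The implementation uses incremental range
updates; the test suite checks it frame-for-frame against an exhaustive
recompute-from-scratch oracle. The detector cannot distinguish slow pursuit
that happens to stay within 3 degrees from a true fixation -- a known I-DT
property, which is why the bounce-fixation metric selects by time relative
to the bounce rather than by event labels.

**Bounce fixation.** The fixation whose interval contains the bounce frame;
otherwise the latest fixation ending before it. Its measures are the mean
egocentric pitch over the half-open event window and the window length in
seconds.

**Peak swing velocity.** Frame speeds are Euclidean norms of positional
differentials of the 10 Hz-filtered controller series times the sampling
rate. The foreswing is found by walking backward from contact to the last
sign change of the velocity component toward the interception point (the
ball's position at contact). Two robustness details: frames slower than 5%
of the recent peak speed count as no motion rather than sign changes (rest
holds and filter ringing would otherwise terminate the walk), and trailing
frames that point away from the interception point are skipped before the
walk starts, because a missed swing passes its closest approach just before
contact. A swing that never approaches yields a flagged missing value; a
stationary controller yields a peak of zero.

**Interception.** A sphere (the ball) against the racquet's oriented box --
the visible 0.6 x 0.3 m face with the collision thickness exaggerated to
0.21 m -- with an inclusive boundary, evaluated every frame.

## Statistical models

All mixed models use a participant random intercept. Condition factors are
0/1 indicators with the low-pressure/low-feedback cell as reference, so
main effects read as simple effects at the reference level of the other
factor, matching the "effect of feedback" phrasing the recipes are written
to reproduce. The recipes are:

* condition models: `pof` (or `cof`, `anxiety`) `~ pressure * feedback`,
  REML;
* appraisal model: `anxiety ~ pof * cof`, REML;
* outcome models: gaze and swing measures (Gaussian) or interception
  (logistic) `~ anxiety + pof * cof`;
* error dependency: `intercepted ~ prior_errors * anxiety`, logistic, where
  `prior_errors` counts the run of consecutive preceding "miss" calls
  (capped at 4, reset by any "hit") and `anxiety` carries the most recent
  probe value forward across the session, missing before the first probe.
  Counts are stored 0-based; any 1-based recoding for display is left to
  the caller.

Winsorization is applied to the probe measures per condition before
fitting. Linear models report Satterthwaite t intervals and p-values (via
lmerTest) rather than plain Wald normal intervals: at 43 participants the
normal approximation's true CI coverage is around 94%, which would quietly
undercut the ~95% coverage the parameter-recovery suite asserts; logistic
models use Wald. Singular random-effect fits are reported with a warning
and a flag, never hidden; degenerate inputs (zero-variance outcomes or
predictors, complete separation) raise errors naming the problem.

Standardized betas are `b * SD(x) / SD(y)` with full-sample SDs, interaction
terms standardized from their product column. For logistic models the
outcome SD is taken on the latent scale,
$\sqrt{\sigma^2_f + \sigma^2_u + \pi^2/3}$ -- an approximation, flagged as
such, and one of several conventions in circulation; published standardized
betas for logistic mixed models are not always derivable from the raw
coefficients, so the package documents its convention rather than forcing
agreement. Marginal and conditional R² follow the variance-decomposition
convention: fixed-effect prediction variance over the total
(fixed + random intercept + residual), with $\pi^2/3$ as the logistic
residual variance. Follow-up contrasts are paired t-tests on participant
cell means with a step-down Holm adjustment (monotone, never below raw).

## Power methodology

`simulate_power()` generates datasets from the probe design's
random-intercept truth on a standardized outcome scale -- random-intercept
variance equal to the ICC, residual variance its complement, total variance
one, so the effect is a standardized mean difference -- refits the
condition model, and reports the rejection fraction of the focal
coefficient with its binomial Monte-Carlo SE. Defaults mirror the study
design: 24 observations per participant split evenly over the 2x2 cells,
ICC 0.5, alpha 0.05, and a "small" standardized effect of 0.2 (the
conventional boundary between weak and moderate, used where the imputed
minimum effect of interest is described only as small). At 43 participants
and 200 replicates the power for the feedback effect is in the low 90s
percent, comfortably above the 85% planning criterion, and at a zero effect
the rejection rate sits at the nominal alpha.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and derived seeds
stay within 32-bit range; identical seeds give byte-identical written
sessions. The test suite's standing problem sizes -- chosen to exercise the
claims at the study's scale while keeping a full run in the low minutes --
are: 100 synthetic trials for detector scoring and 25 for brute-force I-DT
equivalence; 100 replicate datasets of 43 participants for parameter
recovery; 200 replicates for each power point; 100 seeds for schedule
invariants; 12-trial blocks in I/O round-trip fixtures (the full 72-trial
session is built once).

One caveat belongs with the recovery suite: a criterion composed of several
simultaneous two-sigma checks plus binomial coverage bounds has a
nontrivial false-alarm rate even for an exactly calibrated implementation
(roughly one run in four fails some sub-check by chance). The package's
seeds are fixed a priori; unbiasedness and coverage were additionally
verified once at 400 replicates, where all coefficient biases were within
two Monte-Carlo SEs of zero and coverage was 94-96%.

## Known limitations

* The generator's gaze is kinematically idealised (fixed head, replacement
  rather than additive saccades, triangular profiles); detector thresholds
  validated here should be re-examined on real recordings.
* The exclusion rule treats missing gaze as the only data-quality failure;
  controller dropouts are not modelled.
* The logistic standardized-beta convention is one of several; compare
  magnitudes across studies with care.
* The optional deposited-data suite (`scripts/acceptance-osf.R`) requires a
  manual download and a column mapping; the published coefficient values
  can only be checked against those data, and small third-decimal
  differences are expected from backend and df-approximation differences.
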