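---
title: "Models and methods behind gazecue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazecue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task this package models

gazecue is a desk-scale simulator and psychometrics toolkit for a
browser-based gaze-understanding task. In the task, an animated agent
watches a target (a balloon) fall to the ground; the agent's pupils
track the target so that their centers align with the target center.
The target's landing position is hidden, and the participant must use
the agent's gaze direction as the only cue, clicking where they believe
the target landed. Two versions exist:

* **hedge version** (continuous): the click lands anywhere on the
  ground line; the outcome is *imprecision*, the absolute horizontal
  distance between the target center and the click, in units of target
  widths;
* **box version** (discrete): the target hides in one of up to eight
  boxes; the outcome is a correct/incorrect box choice, with chance
  level $1/k$ (20% with five boxes, 12.5% with eight).

Everything downstream of the raw data — session randomization, scoring,
split-half and test–retest reliability, developmental trajectory
models — is implemented here and exercised end-to-end on synthetic
cohorts, so the full analysis pipeline is testable without human data.

## Scene geometry and the ideal observer

The scene lives on a normalized viewport: $x \in [0, 1]$ from left to
right, $y$ increasing upward, with a configurable horizontal ground
line at `ground_y`. This mirrors the scalable-vector-graphics stimulus
design, which keeps relative object positions constant at any display
size, so only relative geometry is meaningful. The published stimulus
does not fix pixel proportions, so the default eye positions
((0.47, 0.65), (0.53, 0.65)), pupil offset (0.02) and target width
(0.05) are package conventions, not measured values.

The forward model (`pose_for_target()`) places each pupil center at
distance `pupil_offset` from its eye center along the eye-to-target
direction — the same rule the animated agent uses. The inverse model
(`infer_ground_x()`) is the ideal observer: extend each eye-to-pupil
ray to the ground line and average the two intersection x-coordinates.
Both eyes are modeled, and the mean of the per-eye intersections is
used because it is the symmetric choice and reduces to the single-eye
answer when the eyes coincide. The forward/inverse round trip is exact
to floating-point tolerance for any ground target, and the inferred
position is strictly monotone in the target position.

Degenerate cases error loudly: a target coinciding with an eye center
has no gaze direction, and a ray parallel to or pointing away from the
ground has no intersection.

The attention-getter (pupils scaled to 130% at 75% opacity for 0.3 s)
and the 5-second response prompt are presentation constants carried in
the session-file metadata; they are never animated here.

## Constrained session randomization

Over the test trials of a session, agents (3) and target colors (4)
appear equally often up to a remainder of one, and no agent, color,
target bin or box repeats more than twice in a row. The hedge version
divides the viewport into ten equal bins and draws the exact target
coordinate uniformly within the selected bin's half-open interval; the
box version balances target boxes the same way (exactly equal counts
when the trial count divides evenly, e.g. five boxes three times each
in 15 child trials, eight boxes four times each in 32 adult trials).

Fifteen trials cannot spread equally over ten bins. The retest design
resolves this explicitly — each bin once, plus one repeat drawn at
random from each adjacent bin pair {1,2}, {3,4}, … — and because that
is the only fully specified resolution, this package applies the
10 + 5 scheme to *all* 15-trial ten-bin hedge sessions.

The generator uses rejection sampling: a balanced multiset of category
labels is shuffled until the run-length constraint holds, with a
bounded retry budget (2,000 draws) after which generation fails with
an explicit error. This happens only for genuinely unsatisfiable
constraint sets (e.g. a single box over 15 trials). Sequences are
deterministic functions of the config seed; fixed retest sequences are
simply sessions whose config (including seed) is held constant across
participants and days.

Training ramps visual access down: trial 1 full access, trials 2–3
partial access. The content of the fourth training trial is not
specified in the published design; here it is a fully covered practice
trial, completing the ramp toward test trials (which always have no
visual access). Voice-over flags sit on the first trial of each access
type and on the first test trial; the published analyses exclude
voice-over test trials, which `score_responses(drop_voiceover = TRUE)`
reproduces.

## The synthetic participant

The response model is deliberately mechanistic and makes no claim
about human processing: on each trial the participant perceives each
eye's gaze direction with independent Gaussian angular error
(`gaze_noise_sd`, degrees), inverts the perceived rays exactly as the
ideal observer does, adds Gaussian motor noise to the click, and with
probability `lapse_rate` ignores the cue and clicks uniformly at
random. Clicks are clamped to the viewport (the task records no
off-screen clicks). Box choices are the box containing the simulated
click; lapses choose a box uniformly.

Choosing angular noise on the gaze ray — rather than positional noise
on the ground — makes target eccentricity matter: a fixed angular
error projects to a larger ground displacement for lateral targets, so
central targets are located more accurately. That qualitative
eccentricity effect emerges from the geometry rather than being built
into the outcome model, and it is the reason the symmetric-position
covariate recovers the right sign in simulation.

The population model is log-linear in age:
$\log \sigma_{\text{gaze},i} = \beta_0 + \beta_{\text{age}} z_i +
\beta_{\text{mode}} \,[\text{remote}_i] + u_i,\;
u_i \sim \mathcal{N}(0, \tau^2)$. The log link keeps noise positive
and gives diminishing returns with age. Defaults emulate the study
conditions: 120 children aged 36–71 months, roughly half remote, two
test days for retest designs (nominally 14 ± 3 days apart, with a
multiplicative `day_shift` on noise). The noise intercept
($\log 6$ degrees) and age slope (−0.4 per age SD) were chosen once so
that mean child imprecision sits around two target widths with the
oldest children approaching adult-level precision, matching the
descriptive scale of child performance in this paradigm; the lapse
rate (3%) and motor noise (0.01 viewport units) are conventions. None
of these are fitted values.

What the simulator does *not* emulate: reaction times, learning or
fatigue across trials (the generating trial effect is zero by
default), caregiver interference in remote testing, head-orientation
cues, or any process-level account of gaze reading. Passing tests
therefore certify the *pipeline* — generator, scorer, estimators —
under a known generative model, not any claim about real children.

Two additional model-based generators exist for parameter recovery,
because the mechanistic simulator cannot impose an exact generating
coefficient: `simulate_retest_cohort()` draws day-specific person
effects from a bivariate normal with known correlation $\rho$, and
`simulate_trajectory_cohort()` simulates directly from the trajectory
GLMM below. Their defaults use the published coefficient estimates as
generating truths (e.g. a lognormal age effect of −0.32), which makes
recovery checks meaningful at the study's scale.

## Scoring

Imprecision is $|x_{\text{click}} - x_{\text{target}}| / w$ with $w$
the target width — invariant under uniform rescaling of all
coordinates, which is what makes the normalized viewport harmless.
Only the x-coordinate enters; y is carried in session files but
unused. Analysis covariates are `symmetric_position`
($|x_{\text{target}} - 0.5|$, smaller = more central = easier),
z-scored age (mean/SD stored as attributes for reproducibility), and
the z-scored 0-based trial index. Symmetric position enters the models
in raw viewport units (0–0.5); whether it was standardized in the
original analyses is not stated, and raw units keep the covariate
interpretable.

Because the lognormal likelihood excludes zero, exact zero imprecision
(possible after rounding or a perfect click) is replaced by half the
smallest positive observed value before log-scale fitting. This
affects at most a handful of trials in realistic data and none of the
model's qualitative behavior.

## Split-half reliability

Four splitting methods, each optionally stratified by target position:

* `first_second` — first ⌈n/2⌉ trials vs the rest;
* `odd_even` — by parity of presentation position;
* `permutated` — random equal-as-possible partition, resampled;
* `monte_carlo` — both halves drawn with replacement, resampled.

Per subject, performance is aggregated by the arithmetic mean within
each part (the mean is the aggregation consistent with both outcome
definitions), and part scores are correlated across subjects with
Pearson's r. Resampling methods average the coefficient over
replicates; the default of 1,000 replicates is justified by a
stability property (doubling the replicate count moves the coefficient
by less than 0.01). Stratification applies the split within each
target-position stratum and pools, so both halves cover the range of
target positions; a single-trial stratum contributes its trial to the
first part.

Both the raw half-test coefficient and its Spearman–Brown projection
$2r/(1+r)$ are always reported, because the published figure does not
state which it displays. Confidence intervals are nonparametric
bootstrap percentile intervals over subjects (500 resamples by
default).

The estimator is validated against a closed-form oracle: for Gaussian
trial scores with true-score SD $\tau$ and trial noise $\sigma$, the
half-test correlation is $\tau^2 / (\tau^2 + \sigma^2 / (n/2))$ and
the Spearman–Brown projection recovers the full-length value
$\tau^2 / (\tau^2 + \sigma^2 / n)$.

## Test–retest reliability

The simple estimator correlates per-subject mean performance across
the two test days (Pearson, bootstrap CI). The hierarchical estimator
fits trial-by-trial data with a fixed effect of age and day-specific
person effects:

$$
g(\mathbb{E}[y_{sdt}]) = \alpha + \beta_{\text{age}} z_s + b_{sd},
\qquad (b_{s1}, b_{s2}) \sim \mathcal{N}_2(0, \Sigma),
$$

with a lognormal likelihood for imprecision or Bernoulli-logit for
accuracy — the random-slope-only specification
`performance ~ age + (0 + day | subject)`. The correlation in
$\Sigma$ is the age-independent test–retest reliability: with age in
the model, a high correlation cannot be produced by shared
developmental level alone, and hierarchical shrinkage regularizes the
person-specific estimates without aggregating away trial-level
information. A simulation in the test suite verifies the construct:
when person effects are only moderately stable but age strongly drives
both days, the raw cross-day Pearson correlation inflates above the
model's age-corrected estimate.

The default backend is full MCMC in JAGS. The 2×2 covariance is
parameterized interpretably as two SDs and a correlation with weakly
informative priors: fixed effects $\mathcal{N}(0, 5)$, SDs (person
effects and residual) half-$\mathcal{N}(0, 2)$, correlation uniform on
$[-1, 1]$. The original analyses used a different sampler's default
priors, which are not printed; these choices are this package's own
and are wide relative to all quantities on the log/logit scale. Two
chains with 500 adaptation, 500 burn-in and 1,500 kept iterations per
chain recover a generating correlation of 0.9 to within 0.1 at 120
subjects × 15 trials × 2 days (about half a minute of sampling);
split-chain PSRF is reported in `glance()`. A `"laplace"` backend
(glmmTMB maximum likelihood with Wald intervals) provides an
independent fast cross-check and is used as such in the tests.

## Developmental trajectory models

The trajectory model is the trial-level GLMM

$$
g(\mathbb{E}[y_{st}]) = \beta_0 + \beta_1 z_s + \beta_2\,
[\text{remote}_s] + \beta_3\, p_{st} + \beta_4\, t_{st} +
b_{0s} + b_{1s}\, p_{st} + b_{2s}\, t_{st},
$$

with $p$ symmetric position, $t$ z-scored trial number, unstructured
random-effect covariance, lognormal or Bernoulli-logit likelihood, and
in-person as the reference data-collection mode.

The default backend here is the Laplace/ML fit (glmmTMB) with Wald 95%
intervals serving the interval contract. The reasoning is practical:
the package's recovery suite refits this model twenty times at 250
subjects × 15 trials to check interval calibration, which an MCMC
sampler of the 3-dimensional random-effect model cannot do at desk
scale, and at these sample sizes the Wald intervals are
well-calibrated (coverage of the generating coefficients, including
the −0.32 lognormal age effect, is ≥ 90% across seeded replicates). A
full MCMC backend (`backend = "mcmc"`) with the same weakly
informative fixed-effect priors and a Wishart prior (4 df, identity
scale) on the random-effect precision is available and is
cross-checked against the Laplace fit on a smaller problem in the test
suite. For the 2-dimensional retest model, where a single fit is the
product, MCMC remains the default.

`predict_trajectory()` returns population-level predictions at
reference covariates; the lognormal prediction is the expected
imprecision $\exp(\mu + \sigma^2/2)$, with interval bounds obtained by
pushing the 95% bounds of the linear predictor through the inverse
link (fixed-effect uncertainty only — random-effect and residual-SD
uncertainty are not propagated, which keeps the ribbon interpretable
as uncertainty about the mean trajectory).

Potential Bernoulli separation is flagged with a warning when any
logit coefficient exceeds 10 in magnitude.

## Session files and tidy export

One canonical JSON schema (`gazecue-session/1`) holds metadata, the
trial list, and responses, mirroring the structure of the web app's
output file; the app's exact field names are not published, so no
import of real app files is attempted. Reading validates the schema
tag, trial fields and response references with field-level messages;
missing clicks load as explicit `NA` and are dropped by scoring.
`export_tidy()` writes one row per subject × day × trial in a
deterministic order with full numeric precision.

## Problem sizes and numerical conventions

The test and acceptance runs use these scales, chosen to make every
statistical check informative while keeping a full run on one CPU in
minutes: geometry round trips at 100 targets (tolerance $10^{-9}$);
generator properties over 1,000 sessions; the split-half oracle at 500
subjects × 30 trials (the estimator's Monte-Carlo SD there is ~0.012);
retest recovery at 120 × 15 × 2 with the reduced-draw sampler above;
trajectory recovery over 20 replicates of 250 × 15. Violated
preconditions (too few trials, zero variance, non-positive outcomes,
unsatisfiable constraints, degenerate geometry) raise errors rather
than returning silently degraded results.

## Known limitations

* The simulator's parameters are testing conventions; nothing here
  estimates a human response process, and real-data idiosyncrasies
  (caregiver interference, device differences, attention drift) are
  out of scope.
* Stimulus proportions are conventions on a normalized viewport; only
  relative geometry is meaningful.
* Reliability tooling covers two test days and split-half designs;
  coefficient alpha/omega and multi-day designs are not implemented.
* The MCMC trajectory backend uses a Wishart prior on the
  random-effect precision, which is less flexible than scale-separated
  priors; it is provided as a cross-check rather than the default.
* Interval bounds for predicted trajectories ignore uncertainty in the
  random-effect covariance and (lognormal) residual SD.
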