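---
title: "Models and methods behind famlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famlift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlift)
```

## The scientific problem

When people repeatedly lift a set of visually similar objects whose size
and weight covary, how is the learned mapping from size to weight stored?
Two accounts make sharply different predictions for an *outlier* object —
one whose weight deviates from the size–weight regularity of its
companions:

* **Object families (categorical) account.** The objects are encoded as a
  category ("family") described by a shared parameter — here a density
  $\hat\rho$ — and an object's weight is predicted as
  $F = \hat\rho \, V g$ from its volume $V$. An outlier whose discrepancy
  stays inside the category boundary is treated as a family member: its
  true weight is *never* learned, no matter how many error-laden lifts
  occur. An outlier beyond the boundary is expelled and learned fully as
  an individual. Learning is therefore all-or-nothing at the level of a
  single participant.
* **Associative-map account.** Size and weight are linked by a smooth
  map built from local generalization. Any outlier is at least partially
  learned, with graded interference from its neighbors.

famlift implements the complete quantitative machinery of an
outlier-lifting study that separates these accounts: the task physics and
trial schedules, generative agents implementing both hypotheses,
preprocessing, the family-level statistics, a univariate Gaussian-mixture
bimodality analysis, and a simulation-based power analysis. Everything
runs on synthetic cohorts; no data download is required.

## Task, objects and schedules

The laboratory task uses five cylinders of common radius (4.61 cm) whose
heights give nominal volumes 400–800 cm³. The four *training* objects
(the two smallest and two largest) weigh 600, 750, 1050 and 1200 g — a
constant density of 1.5 g/cm³ — and the mid-size *test* object (600 cm³)
weighs 1200 g or 1500 g depending on condition, i.e. 2.94 N or 5.89 N
more than the family-predicted 8.83 N. Forces are carried in newtons
with $g = 9.81$ m/s² exactly; rounding happens only at display.

`condition()` defines eleven designs: `Linear+`, `Linear++`, `Uncorr+`
(uncorrelated size–weight assignment, $|r| \le 0.3$, drawn per
participant from the 14 admissible permutations), the reversed curricula
`+Linear`/`++Linear` (outlier first, family later, closing with a "1:1"
phase that equalizes outlier and family lift frequency), the gradual
ramps `LinearUp`/`LinearDown` (±50 g steps at trials 221, 261, 301, 341,
381, 421), and four web variants with training weights 300–700 g and
test weights 900/700/300/100 g.

`generate_schedule()` satisfies the scheduling constraints by rejection
sampling with a retry cap of $10^5$ per phase (the design specifies
constraints, not an algorithm), deterministically per `(condition,
seed)`: training cycles are permutations of the four training objects
with no repeats across cycle boundaries; test cycles lead with the test
object and counterbalance the position-2 object over every four cycles;
the 1:1 phase realizes an exact gap structure between successive
test-object lifts (13 back-to-back, 15/8/3 with one/two/three intervening
trials) by shuffling the gap multiset first and then checking the
per-cycle composition. Ramp steps fall on cycle boundaries (trial 221 and
its successors each open a cycle under the five-trial test cycles), so no
mid-cycle mass change arises.

## Release-phase physics

The release is simulated as a point mass on a stiff damped spring,

$$m \ddot x = (F_\mathrm{ant} - m g) - k x - c \dot x,$$

from rest, so the net force at release equals the anticipatory-force
error and the trace is a damped oscillation about $(F_\mathrm{ant} - m
g)/k$. The laboratory preset uses $k = 4000$ N/m, $c = 2$ N·s/m at 5 kHz;
the web preset uses $k = 1$, $c = 0.01$ (read as SI with masses in kg) at
the 60 Hz frame rate, where only qualitative behavior matters. The
damping coefficient is an ordinary viscous coefficient in N·s/m.
Integration is classical
fixed-step RK4; the suite verifies agreement with the closed-form
underdamped solution to better than $10^{-4}$ relative error and an
oscillation frequency within 1% of $\sqrt{k/m - (c/2m)^2}$. The trace is
open loop: post-release corrective responses are deliberately not
modeled, because the anticipatory force alone is the readout of interest.
Scores follow the task formulas: laboratory
$\max(0, 100 - 13|e|)$; web score $\max(0, 1 - e^2/2.25)\cdot 100$ and
time penalty $\min(0.4 e^2, 12)$ s on the spring-length error $e$ (cm).
The adaptive tolerance band grows 1 mm after a failed trial (cap 13 mm)
and shrinks 1 mm after five consecutive successes (floor 2 mm).

## The generative agents

The study's hypotheses are implemented as trial-by-trial learner agents
(`simulate_family_participant()`, `simulate_associative_participant()`).
Neither is fitted to data; their role is to generate synthetic cohorts
whose qualitative behavior under each hypothesis is known by
construction.

### Family agent

State: a shared density estimate $\hat\rho$, a member/individual label
per object, and per-object mass memories for individuals.

* **Founding.** The first object ever lifted founds the family:
  $\hat\rho \leftarrow m/V$. Before that lift, predictions use a visual
  prior density of 1.0 g/cm³ (a neutral "water-like" guess).
* **Member updating.** After a member lift,
  $\hat\rho \leftarrow \hat\rho + \alpha_f (m/V - \hat\rho)$ with
  $\alpha_f = 0.3$. Because every member shares $\hat\rho$, an error on
  one member generalizes to all — the source of single-trial
  generalization.
* **Expulsion.** Evidence for "this object does not belong" is the sum
  of the object's last three member-lift discrepancies $|w - \hat\rho V
  g|$ divided by three (a fixed-size window: a single lift contributes at
  most a third of its discrepancy, so expulsion needs accumulated
  evidence and, for a constant discrepancy $d$, occurs on the third lift
  iff $d$ exceeds the boundary). The boundary is
  $\theta + \tilde e$, where $\theta$ is the participant's category
  boundary and $\tilde e$ is an exponentially weighted mean (rate 0.05)
  of the discrepancies already tolerated for that object. This slow
  *broadening* term is what distinguishes gradual from abrupt change: a
  weight that creeps up in 50 g steps drags $\tilde e$ along and is never
  expelled, while the same final weight introduced abruptly is.
* **Individuals.** An expelled object starts from the family-predicted
  mass and converges to its true mass by a delta rule with
  $\alpha_i = 0.8$. With hysteresis on (the default), expelled objects
  stay individual even when their discrepancy later shrinks — the
  mechanism behind the asymmetric ramp conditions.

The boundary is expressed in force units (N); mass or density units would
be equivalent up to the fixed test-object volume, and force is the
quantity the task scores.

### Associative-map agent

Predicted force is a normalized Gaussian-kernel expansion over volume,
$F(V) = \sum_i w_i \phi_i(V) / \sum_i \phi_i(V)$, with one kernel per
object volume and width 0.75 times the kernel spacing (75 cm³ in the
laboratory set) — wide enough for substantial neighbor interference,
narrow enough that an outlier is mostly learned. Weights move by a
normalized delta rule with rate 0.5. In the degenerate limit (width
$\to 0$, rate 1) the agent is a lookup table; with overlapping kernels
its steady-state outlier prediction sits strictly between the
family-predicted and actual weights — partial learning in every design,
which is exactly the prediction that separates the two accounts.

### Population calibration

`default_population()` fixes the between-participant structure once; the
values are chosen to be realistic for this class of experiment, not
fitted:

* category boundaries $\theta \sim N(0.85 s,\, (0.25 s)^2)$, truncated at
  0.5 N, where $s$ is the training force span (5.89 N in the laboratory,
  3.92 N on the web). This puts the two laboratory discrepancies (2.94
  and 5.89 N) on opposite flanks of the boundary distribution: the small
  outlier is retained by nearly everyone, the large one splits the
  population into learners and non-learners — the all-or-nothing
  bimodality the mixture analysis targets.
* motor noise 1.0 N per trial (0.7 N web), plus a constant
  per-participant bias with SD 0.6 N for stable individual
  over/under-estimation of the force scale.
* response times (optional): $RT = 500 + 26.2 F_\mathrm{pred} + 40
  (C - 1) + \varepsilon$ ms, where $C$ counts the memory categories held
  (the family plus one per individual) and $\varepsilon$ has SD 80 ms
  with a 150 ms floor. The slope reflects the robust finding that larger
  prepared forces take longer; the selection cost makes uncorrelated
  designs slower throughout, as observed.

Cohorts derive per-participant seeds from the cohort seed by a splittable
counter, so extending a cohort never reshuffles existing participants.

### What the generator does and does not emulate

It reproduces the trial-schedule structure, learner/non-learner
heterogeneity, motor noise, response-time structure, and the qualitative
learning phenomena of both hypotheses. It does not emulate fatigue,
attention lapses, low-effort web strategies (the main driver of web
exclusions in practice), post-release corrections, or explicit reasoning.
Tests passing on these cohorts therefore validate the *pipeline* — that
the statistics detect the patterns each hypothesis implies — not any
claim about real participants.

## Preprocessing

Trial level: per participant × object (pooled over cycles — windowing is
not specified by the design and pooling is the stabler choice),
anticipatory forces more than 3.5 scaled MADs (MAD × 1.4826, the
normal-consistent convention implied by "scaled") from the median are
flagged, as are laboratory forces ≤ 1 N (accidental releases); response
times are screened on the log scale. Cells with zero MAD produce no
exclusions — the alternative (excluding every non-median value) would be
catastrophic on low-noise synthetic data. Flagged values are imputed from
the mean of other participants' non-flagged trials for the same object,
cycle and condition (arithmetic mean on the original scale), with the
participant's own cell median as a logged fallback. The web profile uses
4 scaled MADs and no force floor.

Participant level: retention requires a one-sided positive correlation
between force and weight over training objects — final 15 training cycles
at $\alpha = 0.01$ in the laboratory; on the web, both the final five
training cycles *and* the final five test cycles at $\alpha = 0.10$
(failure in either window excludes). Reversed-curriculum conditions are
exempt (their training phase has one object). Constant-force participants
have undefined correlations and are excluded.

## Family-level statistics

* **End-of-training correlation** (final eight training cycles): Pearson
  $r$ with 95% CI from $\tanh(\mathrm{atanh}\, r \pm 1.96/\sqrt{n-3})$.
  Pooling trials across participants makes the effective $n$ debatable,
  so both the pooled-$n$ closed form and a per-participant mean-$r$
  variant (z-averaged, t-interval over participants) are reported;
  neither is privileged.
* **Family-predicted weight**: per participant, OLS of force on volume
  over training-object trials in the final 16 test cycles, evaluated at
  the test volume. Because the test volume is the mean training volume,
  this equals the mean training force exactly (an algebraic identity
  tested to $10^{-10}$), which is also why the measure transfers to the
  uncorrelated design.
* **Outlier learning**: paired one-tailed t-test of outlier force minus
  family-predicted weight; the direction follows the sign of the
  outlier's discrepancy (greater for heavy, less for light), because
  "not learned" is a directional null.
* **Single-trial generalization**: only the trial immediately after a
  test-object lift carries unwashed-out generalization, so the metric
  compares position-2 forces with that object's own end-of-training
  baseline (final four training cycles) and scales by the outlier
  discrepancy (2.94 or 5.89 N), in percent. Windows: first four and final
  sixteen test cycles; two-tailed t-tests within windows and on the
  change.
* **Response-time ANOVA**: two-way mixed design (Group between, four
  epochs within) on log RTs, reported without sphericity correction,
  with per-epoch one-tailed follow-ups. The implementation delegates to
  `stats::aov` with an error stratum per participant; a hand-computed
  sums-of-squares oracle in the test suite pins the F ratios to
  $10^{-10}$.
* **Switch costs**: RT grows with prepared force, so costs are judged
  against a weight-matched prediction — a regression of RT on weight over
  non-switch test trials (excluding test-object trials and their
  successors); predicted switch RT adds slope × force difference.
* **Group comparisons** (ramp vs abrupt): pooled-variance two-sample
  t-tests on end-of-test outlier force, matching the conventional
  $n_a + n_b - 2$ degrees of freedom.

## Mixture analysis

`fit_gmm()` implements univariate EM with maximum-likelihood (1/n)
variances, a log-sum-exp E step, convergence at $10^{-8}$ log-likelihood
change, 20 initializations (quantile split plus random pairs), and a
variance floor of $10^{-6}$ times the data variance (flagged if hit).
Components are ordered by mean. Parameter counts are 2 (one component), 4
(two, equal variances) and 5 (two, unequal); AIC $= 2k - 2\ell$. The
comparison statistic is $\Delta\mathrm{AIC} = \mathrm{AIC}_1 -
\mathrm{AIC}_2$ (positive favoring two components) with relative
likelihood $\exp(|\Delta\mathrm{AIC}|/2)$ for the favored model — the
standard Akaike-weight ratio. $\Delta$AIC is invariant under affine
transformations of the data (both model families are location–scale, so
the Jacobian terms cancel); the suite checks this numerically to
$10^{-6}$. BIC is computed and reported but never used for selection.

Laboratory inputs to the analysis are per-participant outlier force minus
family-predicted weight (final 16 test cycles); web inputs are raw
end-of-test outlier forces (final five cycles). The two-component default
for data analysis is unequal variances, with equal variances available by
argument: the reference tooling for such fits explores unconstrained
models by default, and learner/non-learner clusters have no reason to
share a variance. Parametric-bootstrap CIs (default 10,000 resamples)
refit each resample with the same settings, resolve label switching by
mean ordering, and error if more than 1% of refits fail to converge.
Classification assigns each value to the component with greater posterior
responsibility, ties to the lower-mean component.

## Power analysis

`power_for_n()` draws cohorts from a two-component, equal-variance,
equal-proportion Gaussian with a 3.5-SD mean separation and counts how
often AIC favors the two-component fit. The selection step also defaults
to unequal-variance two-component fits: paired with the equal-variance
generator this is the configuration that reproduces the expected ~85%
detection rate at $n = 36$, and it matches what an analyst running the
default unconstrained fits would have observed; equal-variance selection
is available and runs a few points higher (its smaller AIC penalty is
never paid for a variance difference that does not exist). The replicate
count defaults to 1000 and every estimate carries an exact binomial CI.

## Numerical choices and degenerate inputs

* Rejection sampling caps at $10^5$ retries; exhaustion signals an
  implementation bug, not a user error.
* `mad_exclude` on a zero-MAD cell returns no exclusions; `fit_gmm`
  floors variances rather than diverging; degenerate t-tests (all
  differences identical) return $t = 0, p = 0.5$ one-tailed rather than
  erroring.
* The Uncorr+ admissibility bound is inclusive ($|r| \le 0.3$).
* All randomness flows from explicit integer seeds through
  `withr::with_seed`; derived seeds stay within 32-bit range.

## Problem sizes in the test suite

The suite exercises cohorts of 14 (per-condition statistics) and 37
(bimodality), 1000-replicate power runs, 200-resample bootstraps inside
nested checks, and 0.5–2 s physics traces at 5 kHz — sizes chosen so the
full suite completes in about a minute while every statistic operates in
the regime it was designed for. The bootstrap default of 10,000 resamples
is intended for analyses, not tests.

## Known limitations

* The agents are deliberately minimal: no forgetting, no lapses, no
  explicit-strategy component, a single shared family (no competition
  between multiple families).
* The boundary-broadening term is one simple way to obtain
  gradual-change tolerance; other mechanisms (variance-scaled boundaries,
  change-point detection) would produce similar qualitative behavior and
  are not distinguished here.
* Pooled-trial correlation CIs treat trials as independent within the
  window; the per-participant variant is the conservative companion.
* The web physics is a qualitative stand-in (frame-rate integration,
  nominal units); nothing downstream depends on its quantitative scale.
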