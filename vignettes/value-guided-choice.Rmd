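---
title: "Modelling value-guided choice under time pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling value-guided choice under time pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgchoice)
```

`vgchoice` analyses a two-attribute risky-choice task in which the time
available for a decision is manipulated: a *short* condition with a 1 s
response deadline, a *middle* condition with free response, and a *long*
condition in which the options are viewed for 3 s before a speeded response.
Each option is a reward magnitude (displayed as a bar) paired with an
independent reward probability (displayed as a percentage); either, both or
neither option can pay out. The package couples a behavioural model of such
choices with trial-epoched analyses of region-of-interest (ROI) BOLD
signals that ask *what kind* of value signal a region carries: the sum of
the two options' values (a decision input) or their difference (a resolved
comparison).

## The choice model

Objective magnitudes and probabilities are transformed into subjective
quantities in the manner of prospect theory (gains only):

$$r_S = r_O^{\alpha}, \qquad
  p_S = \frac{p_O^{\gamma}}{\left(p_O^{\gamma} + (1-p_O)^{\gamma}\right)^{1/\gamma}},
  \qquad \mathrm{sEV} = r_S \, p_S.$$

* $\alpha > 0$ is the magnitude curvature; $\alpha < 1$ under-weights large
  rewards.
* $\gamma > 0$ distorts probabilities; $\gamma = 1$ is the identity.

Choices follow a softmax on the two options' subjective expected values.
Two parameterizations of the decision-noise parameter $\tau$ are in use in
the literature and both are implemented: the default `temperature_divide`
form, $P(\mathrm{left}) \propto \exp(\mathrm{sEV}_L/\tau)$, in which larger
$\tau$ means noisier choice (the usual temperature reading), and the
`inverse_temperature_multiply` form with $\exp(\mathrm{sEV}_L\cdot\tau)$.
The two are related by $\tau \mapsto 1/\tau$; every routine carries the form
through explicitly because the field's verbal convention ("higher
temperature, noisier behaviour") and the multiplicative formula are mutually
inconsistent, and we prefer to make the choice visible rather than silently
pick one.

### Grid-based Bayesian estimation

`fit_prospect()` evaluates the choice log-likelihood on a three-dimensional
grid over $(\alpha, \gamma, \tau)$, equally spaced in log space (150 points
per axis at full resolution; the test suite uses 40--60, which is accurate
to within the corresponding grid resolution and far faster). Under a
uniform-over-cells prior the joint posterior is the normalized likelihood;
marginals are obtained by summation and point estimates are the marginal
means on the linear parameter scale. All likelihood math is done in the log
domain with shift-by-max normalization, so near-deterministic datasets do
not underflow.

Default grid bounds are $\alpha, \gamma \in [0.2, 3]$ and
$\tau \in [0.001, 1]$ for the divide form. Task values live in $(0, 1]$, so
$\tau$ near 1 is already almost random choice and $\tau$ near $10^{-3}$ is
essentially deterministic; the bounds therefore bracket every plausible
behavioural regime for this task. (For the multiply form, mirrored bounds
such as $[1, 1000]$ are appropriate.) Posterior means are reported on the
linear scale; with a log-spaced grid the implied prior is log-uniform, which
is the natural uninformative choice for strictly positive scale-like
parameters.

Fits are per condition by default: the scientific questions concern
condition differences in $\alpha$ and $\tau$, which presupposes separate
fits. A joint fit over all trials is available (`per_condition = FALSE`) and
is what the parameter-recovery harness uses.

### What makes the parameters identifiable

Parameter recovery from ~200 binary choices is only as good as the
schedule is informative. Pilot identifiability analysis showed that with
options drawn independently and uniformly, the Spearman correlation between
true and recovered $\alpha$ plateaus near 0.8 regardless of $\tau$: almost
all trials are then easy, and easy trials constrain only the sign of the
value difference. The schedule generator therefore mixes in a
configurable fraction (default 40%) of *trade-off* trials whose objective
expected values are matched within about 10% but whose magnitude and
probability compositions differ -- exactly the difficult,
low-value-difference trials such experiments are designed around. These
trials probe the curvature of the value transforms directly and lift
$\alpha$/$\gamma$ recovery to $\rho \approx 0.87$--$0.93$ at 210 trials,
while bringing the simulated agent's accuracy (~85%) into the range typical
of human performance on this task.

The recovery harness runs the agent at $\tau = 0.01$ (divide form), a noise
level chosen from the same pilot analysis: informative enough to identify
the transforms, stochastic enough that accuracy stays off ceiling. $\tau$
itself is reported as unbiased within one log-grid step; its per-subject
error at 210 trials is ~15--20% and is a property of the data, not the
estimator.

## The synthetic task and cohort generator

`generate_schedule()` reproduces the design's structure: three timing
conditions in alternating 10-trial blocks, 70 trials per condition by
default, magnitudes uniform on $[0.1, 1]$, probabilities in whole percent
on $[0.10, 0.90]$, a configurable fraction of dominated ("no-brainer")
trials, and jittered delays (response-to-outcome and inter-trial intervals
uniform on 3.5--6 s). Stimulus onsets are planned from the condition's
canonical response time, so the run's event timing is deterministic given
the seed.

Value-based fMRI designs require the chosen and unchosen values to be
decorrelated across trials so their effects are separable; the generator
enforces a greedy-chooser chosen/unchosen correlation of $|r| \le 0.2$
(the design target in this literature) by iteratively resampling single
trials and keeping proposals that reduce the correlation. Whole-schedule
rejection sampling cannot work here -- the correlation of an unconstrained
schedule concentrates near 0.49 and essentially never falls below 0.2 --
so the generator optimises rather than rejects. Keeping trade-off trials'
value levels in a narrow band ($[0.15, 0.45]$) stops them from re-inflating
the correlation: matched trials contribute almost no value-level variance.

`simulate_agent()` samples choices from the softmax, draws reaction times
from per-condition log-normal distributions calibrated so the condition
medians are ~793, 1180 and 3366 ms (the long condition is 3 s viewing plus
a latency truncated at the 1 s response window), and resolves both options'
outcomes independently. `simulate_linear_agent()` instead plants known
linear decision weights (probability, magnitude, history terms, and
reaction-time interactions) for validating the choice regression.

`simulate_bold()` is the forward model for an ROI: each trial contributes a
0.1 s neural event at stimulus onset with amplitude
$w_c\,z(\mathrm{chosen}) + w_u\,z(\mathrm{unchosen})$ (values z-scored
within condition, matching the per-condition analyses), convolved with a
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6),
sampled at TR = 3 s, plus AR(1) noise (default $\phi = 0.3$, marginal SD 1).
Coding regimes: a *sum coder* has $w_c = w_u > 0$, a *difference coder*
$w_c = -w_u > 0$, a *null* region no value weights; regimes may differ by
condition, which is how the time-pressure double dissociation is planted
(`dissociation_truths()`). The default weight of 1 (in noise-SD units per
SD of value) gives a strong, clearly detectable per-subject effect; the
validation harness asks whether the pipeline recovers the *pattern*, so the
regime is placed well inside the detectable range rather than at the edge
of it.

The display is simplified to trial-level scalars: the sustained option
display and outcome phase are not modelled as separate convolved boxcars,
because the epoched analysis regresses trial scalars at each timepoint
rather than fitting a volume-wise convolved GLM. Motion, physiological
noise and preprocessing are out of scope; the input to the ROI analyses is
assumed already preprocessed.

## The trial-epoched ROI analysis

`epoch_timeseries()` fits one cubic spline through the whole scan series
(the interpolant passes exactly through every sample) and evaluates it on
each trial's epoch grid: 54 points covering $[0, 16)$ s from stimulus onset
at 0.3 s resolution. Epochs are cut from the global spline, not splined
per epoch, so a trial's samples are exactly the scan samples wherever the
two grids coincide.

`build_trial_design()` assembles the trial-level design in either of two
spans of the same column space: `sum_diff` (value difference, value sum) or
`chosen_unchosen` (the constituent values), plus outcome value (chosen
option rewarded, $\pm 1$), response side, a reaction-time covariate and an
intercept. Parametric columns are z-scored within condition so amplitudes
are comparable across ROIs and conditions; there is no epoch baseline
subtraction -- the per-timepoint intercept absorbs mean signal. The
volume-wise nuisance regressors of a whole-brain GLM (motion, boxcar main
effects) have no trial-level analogue and are represented by the intercept,
response-side and reaction-time columns.

`fit_timepoint_glm()` runs ordinary least squares across trials at each of
the 54 timepoints, yielding an effect-size timecourse per regressor.
`hrf_amplitude()` reduces each timecourse to a single number by a
least-squares scalar fit of a reference HRF shape, optionally over a
$\pm 3$ s lag grid. The reference shape used by the high-level wrappers is
`effective_hrf_kernel()`: the canonical double-gamma *as it appears after*
TR sampling and spline resampling, which is the shape a true
stimulus-locked response takes in these effect timecourses. The HRF family
and the amplitude-only (no free latency by default) fit are documented
choices; both are configurable.

Group statistics are one-sample t-tests per regressor × ROI × condition
(one-tailed where a signed hypothesis is stated, and every reported p is
labelled with its tail), paired between-condition contrasts of the
unchosen-value effect, and a 2 × 3 fully within-subject ANOVA (brain area ×
condition) in which each effect is tested against its own effect-by-subject
interaction -- df $(1, n-1)$ for area and $(2, 2(n-1))$ for condition and
the interaction.

`fit_brain_behaviour()` regresses per-subject choice accuracy (percent
higher-EV choices) on the four z-scored value amplitudes (chosen/unchosen ×
two ROIs) in a single OLS model per condition, as a simultaneous
four-regressor model, with contrast t-tests for each region's chosen-value
effect and their difference.

## Numerical choices and edge cases

* Probability weighting passes the endpoints 0 and 1 through exactly;
  softmax probabilities are computed shift-by-max.
* Degenerate inputs are reported, not propagated as errors where a value is
  defined: a constant vector tested against its own value gives $t = 0$,
  $p = 1$; an ANOVA with no between-cell variation reports $F = 0$;
  zero-variance accuracy marks the brain-behaviour contrasts degenerate.
* Constant design columns (e.g. outcome value when every trial rewarded)
  are dropped with a warning; rank deficiency is an error naming the
  offending column.
* Logistic choice regressions falling into separation are refitted with a
  small ridge and flagged, rather than returning divergent estimates.
* Missed responses are excluded from the likelihood, the epochs and the
  designs, and are written to events files as `n/a`.
* All simulators take explicit integer seeds; cohort-level seeds are drawn
  once from the master seed, so any subject can be regenerated in
  isolation.

## What the synthetic validation does and does not show

The generator emulates the *structure* of the experiment: trial counts,
block layout, timing, value statistics, condition-specific response times,
and value-coding regimes convolved with a canonical HRF plus AR(1) noise.
Passing the validation suite therefore shows that the estimator and the
epoch pipeline recover what was planted under these assumptions. Real
BOLD data differ in ways the generator deliberately omits: non-canonical
and regionally varying HRFs, motion and physiological artefacts, slow
drifts, display-locked sustained responses, and behaviour that follows no
parametric choice model exactly. Conclusions about the method's behaviour
on real data are limited accordingly; the file formats accept real
(externally preprocessed) ROI series in exactly the same layout.

Problem sizes used by the validation suite were chosen to match the study
design where the property depends on it (28 subjects, 70 trials per
condition, 210-trial fits; 50 subjects for parameter recovery; 20 seeded
cohorts for detection-rate checks) and reduced grids (40--60 points per
axis, 12 for the smoke-scale pipeline run) where only numerical agreement
with the full grid is at stake.

## A worked example

```{r example, eval = FALSE}
library(vgchoice)

# one subject: schedule, agent, two synthetic ROIs
sched <- generate_schedule(n_per_condition = 70, seed = 1)
agent <- prospect_params(alpha = 0.9, gamma = 0.8, tau = 0.01)
ds <- simulate_agent(sched, agent, seed = 2)

fit <- fit_prospect(ds, n_points = 60)
fit$estimates

truths <- dissociation_truths()
bold <- lapply(truths, function(tr) simulate_bold(ds, tr, seed = 3))
res <- analyze_roi_cohort(list(ds), list(bold), variant = "chosen_unchosen")
subset(res$amplitudes, regressor == "unchosen_value")

# the full seeded pipeline at reduced scale
cfg <- default_run_config(n_subjects = 8, n_per_condition = 20,
                          grid_points = 20, seed = 1)
out <- run_pipeline(cfg, out_dir = tempfile())
out$anova
```
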