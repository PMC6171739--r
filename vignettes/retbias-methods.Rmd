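---
title: "Retinotopic biases in face identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinotopic biases in face identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retbias)
```

## The phenomenon and the pipeline

Observers judging the identity of a morphed face are not uniform across the
visual field: the same morph can look more like one identity at one
retinal location and more like the other identity elsewhere. These
location-specific biases are *stable* within an observer across sessions
weeks apart, *idiosyncratic* across observers, and *weaker for more
familiar identities*. `retbias` implements the full analysis chain for this
phenomenon — behavioral simulation, psychometric modeling, reliability
statistics, familiarity regressions — together with a neural-population
simulation that offers a mechanistic account: identity-selective neural
units sample a limited part of the visual field, and familiarity plausibly
recruits more units, widening coverage and flattening the bias.

Everything runs on synthetic data; the generators are first-class, tested
code. This vignette records the models, the defaults and why they were
chosen, and what the synthetic results do and do not establish about real
data.

## Behavioral generative model

A simulated observer is a map from (morph pair, angular location) to a true
point of subjective equality (PSE):

* `true_pse = 50 + delta`, with `delta ~ N(0, sd)` drawn independently per
  subject and location. Gaussian, zero-mean, independent across locations
  is the simplest structure consistent with idiosyncratic spatial
  heterogeneity; nothing in the analyses depends on its finer shape, and
  the SD is configurable per morph pair or per subject x pair.
* Responses are Bernoulli with
  `P(second identity) = plogis(slope * (morph_pct - true_pse))`. The morph
  axis is kept in raw percent (0-100) everywhere, so slopes are per
  morph-% and PSEs are in percent toward the second identity.
* The default slope 0.1 per morph-% puts the 17-point spacing between
  adjacent morph levels at about 1.7 logits near the PSE — a task that is
  reliable but not trivial at 10 trials per cell, matching the flavor of
  the behavioral regime the designs imply.
* The default deviation SD of 5 morph-% makes the per-subject bias
  (sum of squared deviations over 4 locations, expectation `4 * 25 = 100`)
  clearly detectable at study scale without saturating the morph range.
* In the three-identity design, a trial is replaced with the uninvolved
  third identity with probability `lapse_third` (default 0.02). Lapse rates
  are not reported for the original task, only that such trials were
  removed, so this is a calibration choice, not a reproduction.
* Profiles are constant across sessions: stability is the generative
  assumption, and any observed test-retest correlation below 1 reflects
  estimation noise, not drift.

The two trial designs are factorial and exact by construction: the
two-identity experiment presents 8 locations x 7 morph levels x 2
repetitions per block for 5 blocks (560 trials, 70 per location); the
three-identity experiment presents 4 locations x 3 morph pairs x 7 levels
per block for 10 blocks (840 trials, 10 per cell). Only the trial *order*
is random.

An `orthogonal` option Gram-Schmidt-orthogonalizes the subjects' deviation
patterns (also against the constant vector), giving exactly uncorrelated
idiosyncratic patterns at the target SD. It exists for power analyses of
the within- versus between-subject contrast, where "different patterns per
subject" is the hypothesis being instantiated.

## Psychometric model and PSE decomposition

`fit_psychometric()` fits, per session and morph pair,

    logit P(second identity) = beta0 * morph_pct + beta_i + z_ik

with a shared slope `beta0`, a fixed effect `beta_i` per angular location
`i` (no global intercept), and a random intercept `z_ik` per subject `k` x
location with one shared variance. Sessions are fit separately so that
across-session correlations compare genuinely independent estimates.

The subject-level PSE at location `i` is the morph percent where the
fitted curve crosses 0.5:

    PSE_ik = -(beta_i + z_ik) / beta0 = PSE_pop_i + delta_PSE_ik

an exact algebraic identity that `pse_table()` preserves row by row. The
bias statistic is `sum_i delta_PSE_ik^2` per subject and morph pair
(`bias_variance()`, `bias_scores()`).

Two estimators share this contract:

* `estimator = "mixed"` — `lme4::glmer`, Laplace approximation, bobyqa
  optimizer (the standard robust choice for binomial mixed models; the
  default optimizer trips lme4's gradient check on perfectly healthy fits).
  Non-convergence is an error carrying the optimizer messages, never a
  silent fallback.
* `estimator = "fixed"` — ordinary logistic regression with subject x
  location fixed intercepts and the same shared slope; deviations are the
  intercepts centered across subjects within location. For a single
  subject the random effect is degenerate and this *is* the model (`z` is
  fixed at zero), so the mixed estimator auto-switches. On multi-subject
  synthetic data the two estimators' deviations correlate above 0.99; the
  fixed path is used for the large Monte Carlo suites where hundreds of
  refits are needed. The mixed path shrinks deviations toward zero
  (that is what a random effect does), which slightly attenuates — never
  inflates — idiosyncrasy statistics.

Third-identity responses are removed by `filter_third_identity()` before
fitting, mirroring how such trials are treated in the behavioral task.

## Reliability statistics

* `pearson_with_test()` is a plain Pearson correlation with `df = n - 2`.
  The degrees of freedom printed by the pipeline are purely combinatorial:
  4 subjects x 8 locations of deviations give df 30; 10 x 4 x 3 give 118;
  8 population PSEs give 6.
* `bca_ci()` implements the bias-corrected and accelerated bootstrap
  (10,000 replicates by default): bias constant `z0` from the fraction of
  bootstrap statistics below the estimate, acceleration from the jackknife
  skewness. It is written in the package (rather than wrapping an existing
  implementation) so that resampling is seed-deterministic and `z0`/`a`
  are exposed; it is cross-checked against `boot::boot.ci` in the tests,
  and reduces to the percentile interval when both corrections vanish.
  With very few subjects (the across-subject resampling unit can be as
  small as 4) BCa intervals are noisy; that is a property of the design,
  not of the implementation.
* `within_between_difference()` quantifies idiosyncrasy: each subject's
  session-1 deviation profile is correlated with their own session-2
  profile (within) and with every other subject's session-2 profile
  (between, all ordered cross pairs). Correlations are pooled on the
  Fisher-z scale by default (`pooling = "raw"` averages them directly);
  the exact construction of a between-subject correlation is a convention,
  so it is declared rather than guessed. The CI for the difference
  resamples *subjects*, because the scientific claim is about
  subject-level idiosyncrasy.
* `interaction_anova()` is `stats::aov` on a balanced subject x location
  table with replicates; only the interaction row is reported. With 10
  subjects, 4 locations and 4 replicates per cell (2 morphs x 2 sessions
  after identity alignment) the interaction has (27, 120) degrees of
  freedom. `align_pse_identity()` re-expresses PSEs toward a common
  identity (`100 - pse` for pairs where that identity comes first) and
  drops pairs that do not contain it.

## Familiarity scores and regressions

Per subject and identity, SCI is the mean of its two items, the
familiarity score is the mean of IOS, SCI and the We-scale (all 1-7), and
the contact score is the count of six binary contact items. Morph-level
scores are the means over the pair's two identities. The SCI item
aggregation (mean before the three-scale average) is a declared choice;
the source only lists the two questions.

`bias_regressions()` fits `bias ~ familiarity` and
`bias ~ familiarity + contact` by OLS, and reports R-squared, adjusted
R-squared, model F, per-coefficient t and partial eta-squared, the
chi-square(1) likelihood-ratio statistic between the nested models, and
zero-order plus partial correlations (residual-on-residual) with BCa CIs.
Bias values are averaged across sessions at the *deviation* level first
(average `delta_pse` across sessions, then square and sum) — the
alternative, averaging per-session bias scores, is available via
`session_average = "bias"`. Coefficients are reported on raw scales, no
standardization; bias is in squared morph-%.

The questionnaire generator drives all three rating scales from one latent
closeness per subject x identity (`sqrt(r) * Z + sqrt(1 - r) * e`, then
discretized to 1-7), so every pair of raw scales correlates at
`inter_scale_r` (default 0.9, giving the "highly intercorrelated scales"
regime); contact item probabilities increase with the same latent. In the
end-to-end replica the generative deviation SD is tied to the subject's
morph-level familiarity (`sd = 9 - 1.2 * familiarity`, clamped at 0.5),
which encodes the headline effect — more familiarity, less retinotopic
bias — at roughly r = -0.5 observable strength at study scale.

## Neural-population simulation

Each unit has a compressive spatial summation (CSS) receptive field:
response `r = g * a^n` with `a` the stimulus contrast map integrated under
a *unit-volume* 2-D Gaussian at the unit's center, and `n = 0.2`. Unit
volume makes the full-field response exactly `g`, which anchors the
normalization analytically (the convention is not restated in the source
model's text, so the package picks the one with an exact invariant).
Integration is a midpoint Riemann sum on a +/-10.5 degree window at 10
px/degree by default; refining the grid changes decodable activations by
well under 1%, and the high-resolution oracle in the tests is adaptive
quadrature. Stimuli are binary discs of diameter 4 degrees at 7 degrees
eccentricity, at polar angles 45/135/225/315.

Unit pools emulate three face-responsive regions via the printed median
receptive-field sizes (size = sigma / sqrt(n); 2.98, 3.87, 3.55 degrees
for IOG, pFus, mFus): sigma is lognormal with median `size * sqrt(n)` and
`sdlog = 0.35` (a realistic within-region spread), eccentricity is
half-normal with scale 5 degrees (perifoveal concentration), polar angle
uniform across both hemifields — the simulation pools units, so
contralaterality is not needed for the mechanism. Coverage (a unit covers
a stimulus when the disc intersects the circle of radius 2 sigma) is lower
in the IOG-like pool than in pFus/mFus, reproducing the ordering that
drives the region differences; the absolute coverage percentages depend on
the center distribution, which the printed medians do not pin down.

A simulated experiment draws `ratio` a-preferring units plus one
b-preferring unit from the pool (without replacement), trains a linear SVM
(cost 1) on 10 noisy responses per identity and location, then decodes 10
test trials per location and morph level. A morph m% toward b drives each
unit at `(1 - m/100)` or `m/100` of its full response (linear
morph-response assumption; mixing applies to noiseless responses, with
noise added per trial). Per-location PSEs come from plain logistic fits of
the decoded labels, and the experiment's bias is `sum (PSE_i - 50)^2`.

Two modeling choices deserve emphasis:

* **Gain scales the whole noisy activation.** Each unit's trial noise SD
  is `0.1 * gain`. A response-gain change amplifies the unit's output —
  stimulus-driven signal and intrinsic variability alike — so it cannot
  create spatial information the receptive fields do not sample. With the
  decoder's standard feature scaling the decision law is then invariant to
  gain by construction, and the gain sweep is flat up to Monte Carlo
  noise. Under the alternative reading (fixed noise added after the gain),
  gain would trivially rescue weak responses from the noise floor and
  reduce the bias, which is neither the biologically standard picture of
  response gain nor the observed behavior of attentional gain in this
  paradigm. Number of units and receptive-field size, by contrast, change
  what is sampled, and do reduce the bias.
* **Unidentifiable experiments keep an unbounded bias.** A sampled
  population may be structurally unable to produce both response classes
  at some location (nothing covers it); no amount of noise resampling
  fixes that. Such experiments carry `pse_variance = Inf` rather than
  being redrawn — a population that cannot identify the stimulus at a
  location has maximal bias, not a missing value, and redrawing units
  would condition each sweep cell on decodability (which varies across
  conditions and would distort the trends). Medians and bootstrap CIs
  across experiments absorb infinities as long as they are a minority,
  which they are at the default noise level (a few percent at ratio 1,
  none at higher ratios).

Failed per-location fits (degenerate labels or non-convergence) first get
fresh noise, learning phase included, up to `max_resample = 20` times;
separation warnings with finite estimates are kept, since wild
per-location PSEs are exactly what an undersampled population produces and
the condition summaries are medians. Decision values that are zero to
numerical precision are tie-broken alternately, which preserves the
analytic anchor: a noise-free, fully symmetric configuration yields PSE =
50 at every location and exactly zero bias.

Sweeps (`sweep_bias()`) rerun 500 experiments per condition by default
(the acceptance suite uses 100 per condition to fit a single-CPU budget;
the trends are identical in kind) along one axis: ratio 1-9, a-unit gain
1-4 in 0.5 steps, or a-unit receptive-field inflation 0-50% in 10% steps.
`sweep_trend()` summarizes a sweep by the slope of the median-variance
curve with a bootstrap CI.

## Numerical and procedural details

* All generators and analyses take explicit integer seeds; one master seed
  fans out to per-stage child seeds (`full_replica()` records them), so
  identical configurations reproduce byte-identically.
* The mixed logit uses `maxfun = 50,000` optimizer evaluations; the fixed
  logit inherits `glm`'s IRLS with `maxit = 500`.
* `fit_simple_logit()` flags: `degenerate` (one response class — no fit),
  `separated` (fitted probabilities numerically 0/1), `indeterminate`
  (slope not distinguishable from zero at |z| < 2, so the PSE ratio is
  unstable). Degeneracy and non-convergence count as failures for the
  simulation harness; the other flags are informational.
* BCa quantiles use `type = 6` interpolation; degenerate bootstrap
  distributions collapse the interval to a point with a warning.
* PSE values are not clamped to [0, 100]: estimates outside the morph
  range are meaningful evidence of a strong or unmeasurable bias and are
  handled by the robust summaries downstream.

## Problem sizes

The test and acceptance suites run the behavioral studies at their design
scale (4 subjects for the two-identity experiment, 10 for the
three-identity one; two sessions each), 200-study Monte Carlo for the
power properties using the fixed estimator, 100 simulated neural
experiments per sweep condition, and bootstrap sizes of 999-2,000 inside
Monte Carlo loops versus 10,000 for single reported intervals. These sizes
were chosen so the full suite runs comfortably on one CPU while leaving
the Monte Carlo margins far from the pass thresholds.

## What the synthetic results do and do not show

Passing tests establish that the pipeline recovers what the generators put
in: stable idiosyncratic patterns are detected as such, familiarity-linked
shrinkage of the deviation spread produces negative regression
coefficients, and the neural simulation reproduces the mechanism ordering
(units and receptive-field size matter, gain does not). They do not
validate the substantive empirical claims about human observers — the
generator's Gaussian, independent deviations, its uniform lapse rate, and
its lognormal receptive-field sizes are idealizations, and real
questionnaire data have item-level structure the single-latent model
ignores. Reported correlations from real data (e.g. the published
stability and familiarity correlations) are properties of those datasets
and are not targets of the synthetic pipeline.

## Known limitations

* The random-effect structure is a single subject x location intercept
  with one variance; random slopes and crossed structures are out of
  scope.
* The between-subject correlation construction (all ordered pairs,
  Fisher-z pooling) is one of several defensible conventions.
* The CSS simulation models static populations; attention dynamics, eye
  movements and hemodynamics are out of scope.
* BCa intervals on 4 subjects are honest but fragile; the power
  properties quote detection rates rather than pretending the intervals
  are well calibrated at that n.
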