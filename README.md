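# retbias

Tools for studying **idiosyncratic retinotopic biases in face
identification**: the same morphed face can be judged as one identity at
one retinal location and as the other identity elsewhere, in a pattern
that is stable within an observer across sessions, differs between
observers, and weakens with familiarity. The package is aimed at visual
psychophysicists and computational neuroscientists who want a tested,
fully synthetic replica of this analysis chain — from trial generation to
the neural-population account — with every stage seeded and reproducible.

## The models

**Psychometrics.** For each session and morph pair, responses are modeled
with a mixed-effects logit psychometric function

```
logit P(second identity) = β₀·m + βᵢ + z_ik
```

with shared morph slope β₀ (m = morph % toward the second identity),
location fixed effects βᵢ, and subject×location random intercepts z_ik.
Each subject's point of subjective equality decomposes exactly as

```
PSE_ik = −(βᵢ + z_ik)/β₀ = PSEᵖᵢ + ΔPSE_ik
```

into a population PSE and a subject deviation. The retinotopic **bias**
of a subject for a morph pair is `Σᵢ ΔPSE_ik²`. Stability is the
across-session Pearson correlation of these estimates (BCa bootstrap CIs);
idiosyncrasy is the within- minus between-subject correlation of the
deviation profiles; familiarity effects are nested OLS regressions of the
bias on composite familiarity and contact scores.

**Neural simulation.** Identity-tuned units with compressive spatial
summation receptive fields (`r = g·aⁿ`, `a` the unit-volume Gaussian
integral of the stimulus contrast map, `n = 0.2`) respond to morphed
stimuli at four peripheral locations; a linear SVM decodes identity from
the noisy population pattern, and per-location logistic fits of the
decoded labels yield PSEs. Sweeping the ratio of units tuned to the two
identities, their gain, and their receptive-field size shows that **more
units** and **larger receptive fields** shrink the PSE variance around
50%, while **gain does not** — the mechanistic account of why familiarity
(more recruited units) flattens the bias.

## Worked example

```r
library(retbias)

# a 4-subject, two-session study at full design scale (560 trials/session)
sim   <- simulate_behavior(1, n_subjects = 4, seed = 42)
stage <- fit_psychometrics_stage(sim$trials, estimator = "fixed")
stage$fits$ab_s1
#> Logit psychometric fit (fixed) for morph 'ab'
#>   4 subject(s), 8 locations, 2240 trials
#>   slope beta0 = 0.1095 per morph-%;  random-intercept variance = 0.6692
#>   population PSE by location:
#>     0    45    90   135   180   225   270   315
#> 48.74 52.53 51.26 47.47 52.95 48.74 49.58 46.63

rel <- reliability_report(stage$pse, n_boot = 2000, seed = 43)
rel$per_pair$ab$delta_pse
#> r = 0.626 [0.365, 0.787], t(30) = 4.40, p = 0.000126
rel$per_pair$ab$within_between
#> within r = 0.666, between r = -0.235, difference = 0.901 [0.852, 0.943]

bias_scores(stage$pse[stage$pse$session == 1, ])
#>   subject_id morph_pair     bias
#> 1        s01         ab 298.7489
#> 2        s02         ab 185.2473
#> 3        s03         ab 341.3371
#> 4        s04         ab 512.9392
```

Reading the output: the fitted slope recovers the generating value (0.1
per morph-%), the population PSEs sit near 50% with location-specific
wobble, and the subject deviations are **stable** (ΔPSE correlates 0.63
across sessions, df = 30) and **idiosyncratic** (each subject's own
session-2 profile matches their session-1 profile far better than other
subjects' do; the within−between difference of 0.90 has a bootstrap CI
well above zero). The bias column is each subject's summed squared
deviation in squared morph-%.

The end-to-end replica — both experiments, reliability and familiarity
reports, and a reduced neural sweep — is one call:

```r
bundle <- full_replica(seed = 1)
print(bundle$exp2$familiarity$regressions)
```

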