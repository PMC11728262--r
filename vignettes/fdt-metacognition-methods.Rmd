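---
title: "Models and methods: breathing interoception and metacognition from the Filter Detection Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: breathing interoception and metacognition from the Filter Detection Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what the validation suite does
and does not demonstrate.

## The task and the four measures

In the Filter Detection Task (FDT) a participant breathes through a
circuit to which, on each trial, the experimenter either adds a small
stack of filters (a barely perceptible inspiratory resistance) or a sham
filter. The participant reports "yes" (resistance present) or "no", and
rates confidence on a 1--10 scale or on a 0--100 scale depending on study
site; 0--100 ratings are down-sampled into ten bins
(`bin_confidence()`), so all analyses share one 10-point scale. An
adaptive staircase brings each participant to a filter number where
accuracy sits in a 60--85% band, and 60 trials are completed there.

From one subject's threshold block the package computes:

* **sensitivity** — the threshold filter count itself
  (`estimate_threshold()`, the modal filter number, ties broken toward
  more filters);
* **decision bias** — the equal-variance Gaussian SDT criterion
  \(c = -(z(HR) + z(FAR))/2\), negative values meaning a tendency to
  report "yes" (`estimate_type1()`; hit and false-alarm rates are clamped
  into \([1/2N, 1-1/2N]\) so the quantiles stay finite);
* **metacognitive bias** — mean binned confidence over threshold trials
  (`metacognitive_bias()`);
* **metacognitive insight** — \(\log(\text{meta-}d'/d')\) (logMratio),
  estimated per subject by maximum likelihood (`fit_metad_mle()`) or for
  a whole cohort by the hierarchical Bayesian model (`fit_metad_hier()`).

## The meta-d' observer

Meta-d' asks: what type-1 sensitivity would an ideal observer need so
that, run through the same SDT geometry, it reproduces the observed
coupling between confidence and accuracy? The model evaluates, for each
(stimulus, response) pair, the multinomial probability of the confidence
counts. Evidence is drawn from \(N(\pm\text{meta-}d'/2, 1)\); the type-1
decision point is held at the *scaled* criterion
\(c' = c \cdot \text{meta-}d'/d'\) so the meta-level observer would match
the type-1 response rates; type-2 criteria partition each response side;
and each cell probability is the normal area between adjacent criteria,
normalized by the response probability given the stimulus. Mratio =
meta-d'/d' cancels raw task performance; its log is used for Gaussian
modelling.

The single-subject MLE maximizes this likelihood over meta-d' and the 18
criteria (parameterized as log-spaced increments so ordering is
automatic), from three fixed starting points, which makes it
deterministic. Zero cells are padded by \(1/2K\) per cell. The test
suite checks the MLE against an exhaustive grid search over meta-d' in
\([0.05, 5]\) at step 0.005 with nested criteria optimization, written
independently of the package's likelihood code.

## The hierarchical model and its regression

`fit_metad_hier()` estimates, for \(N\) subjects,

\[
\log M_s \sim \mathcal N(\mu + x_s^\top\beta,\ \sigma),
\]

with the confidence counts entering through the meta-d' likelihood above
and the design matrix \(x_s\) optional (absent, the model is the plain
group estimator). Priors: \(\mu \sim \mathcal N(0,1)\), \(\beta_j \sim
\mathcal N(0,1)\) on z-scored covariates (a unit-information default),
\(\sigma \sim \text{Half-}\mathcal N(1)\). Significance of any
hierarchical parameter is read from whether its 95% highest-density
interval (HDI; shortest interval holding 95% of the draws, `hdi()`)
excludes zero. For the gender-interaction design the summary also
reports the women-specific slope (slope + interaction) computed draw by
draw; for the gender-specific-slope design, the women-minus-men
difference.

Three structural choices deserve explanation, because each was made
after quantifying the alternative on synthetic cohorts at the study's
scale (60-trial subjects, 10 confidence bins):

**Latent type-1 parameters.** Each subject's \((\log d', c)\) is latent,
with a binomial likelihood from the yes/no counts per stimulus and
hierarchical shrinkage priors whose population location and scale are
learned from the cohort. The common alternative — plugging in the
point estimates — injects their sampling error into the meta level:
an error in \(c\) rigidly displaces the whole type-2 criterion grid, an
error in \(d'\) rescales meta-d', and either can only *dilute* the
apparent confidence-accuracy coupling. At 60 trials/subject this
one-sided dilution biases the population logMratio mean by roughly
\(-0.1\) to \(-0.2\); estimating type-1 inside the model removes it.
The reported per-subject \(d'\) and \(c\) in `fdt_measures()` remain the
standard point estimates.

**Structured type-2 criteria.** Criteria are modelled as an even
partition of the evidence span from \(c'\) to \(\pm 3\), multiplied by a
criterion-spacing shape learned from the whole group (nine cumulative
log-increments) and stretched by one tightly shrunk log-scale per
subject and response side (\(h \sim \mathcal N(0, \tau_h)\), \(\tau_h
\sim \text{Half-}\mathcal N(0.1)\)). Fully free per-subject criteria —
18 incidental parameters per 60-trial subject — are avoided
deliberately: misplaced criteria can only dilute the coupling, and
every free-criteria prior we evaluated during development (wide ordered
truncated normals, sorted i.i.d. draws with learned location/scale,
per-rank locations, free log-normal increments) attenuated the
population mean well past the recovery tolerance. The structured
parameterization is the configuration under which the acceptance
suite's recovery experiment at 60 subjects x 60 trials passes its bias
and HDI-coverage checks.

**A purpose-built sampler.** The posterior has a funnel: \(\sigma\) is
small, subject likelihoods are weak, and generic one-variable-at-a-time
samplers traverse it very slowly. The package ships an adaptive
Metropolis-within-Gibbs sampler (C++, `src/hmetad_sampler.cpp`):
conjugate Gibbs updates for \(\mu\) and \(\beta\), random-walk updates
for the remaining blocks with Robbins-Monro scale adaptation during
warm-up, and an interweaving (ancillarity-sufficiency) step that
re-updates \(\mu\) and \(\sigma\) in the non-centered parameterization
with the standardized subject effects held fixed. The sampler is
validated three ways in the test suite: exact recovery of all prior
marginals when the likelihood is flat; agreement with an independent
JAGS implementation of the identical model on shared data; and
agreement with exact two-dimensional quadrature when the criteria and
type-1 parameters are pinned. Convergence is monitored by split-R-hat
(< 1.05 for all reported parameters, else the fit is flagged).
Defaults are 3 chains x (1000 adaptation + 1000 burn-in) warm-up and
3000 retained draws per chain; chain \(c\) is seeded with
\(\text{seed}+c-1\), so results are bit-reproducible.

## The OLS analyses

Sensitivity, decision bias and metacognitive bias are analysed by
ordinary least squares (`fit_ols()`, a thin wrapper over `lm()`), with
two-tailed t-test p-values and p < 0.05 as the significance rule. For
each measure and score, `run_measure_suite()` fits five models: the base
model (z-scored score + study-site dummies, largest site as reference),
the gender-interaction model, the mathematically equivalent
gender-specific-slope model (identical fitted values; the women slope
equals slope + interaction to numerical precision), and the two
site-collapsed sensitivity variants. Z-scoring is computed over the
analysed (complete-case) sample before any gender split, so both
genders share one scale; missing scores are handled by listwise
deletion per analysis. Gender is coded 0 = man, 1 = woman.

## The staircase algorithm

`staircase_step()` implements the risk-controlled difficulty rule: after
each trial, cumulative accuracy k of n at the current filter number is
transformed through a uniform-prior beta posterior, Beta(1+k, 1+n-k),
and if the probability of lying inside the 60--85% band falls below the
20% risk threshold, a filter is added (dominant lower tail) or removed
(dominant upper tail), with counts resetting at the new filter number.
The trigger implements the rule text literally — change when P(in band)
< 0.20; the alternative reading (change when P(outside band) > 0.20,
i.e. P(in band) < 0.80) is available through `risk_threshold = 0.80`.
The automatic controller runs for the first 30 trials at a filter
number; afterwards the every-10-trials experimenter review is simulated
as applying the same decision rule, logged as a manual adjustment.
Modelling the review as action rather than as a passive flag matters:
sessions that reach trial 30 on a lucky run at a chance-level filter
would otherwise complete all 60 trials at chance, and under a flag-only
reading too many simulated sessions end below the accuracy band.
Calibration presents ascending filter numbers until two consecutive
loads are reported, then one final trial with one filter fewer decides
the starting value (the lower value if detected there). Sessions are
driven by logistic observers (`sim_observer()`): accuracy \(0.5 +
(0.5-\text{lapse})\cdot\text{logistic}(\text{slope}(f - \text{midpoint}))\).
In validation we use midpoints 2--8, slopes 0.8--2 per filter and lapse
up to 0.05; the modest slopes reflect that stacked identical filters
change the load gradually, so accuracy cannot jump from chance to
ceiling across one filter.

## The synthetic cohort generator

`simulate_cohort()` emulates the pooled multicentre study conditions:
175 subjects over four sites (78/30/30/37), 51% women, 60 threshold
trials per subject at a per-subject threshold filter number, one site
collecting confidence on the 0--100 dialect. State anxiety is a
truncated-normal integer on the STAI range (20--80, mean 35, SD 10);
trait anxiety and depression are generated correlated with it and
truncated to their instrument ranges. Generative type-1 parameters:
\(d' \sim N(1.2, 0.3)\) truncated at 0.2 (mid-band accuracy), \(c \sim
N(0, 0.2)\). Subject logMratio is \(\mu_{\log M} + \beta_{g}\,z +
N(0, \sigma_{\log M})\) with gender-specific slopes; defaults plant the
magnitudes the pooled analysis reports (women \(-0.18\), men \(0.02\),
population mean \(-0.1\), \(\sigma_{\log M} = 0.25\)). Confidence comes
from a second metacognitive evidence sample with sensitivity meta-d'
(redrawn until it falls on the response side of the scaled criterion),
binned through criteria spaced evenly between \(c'\) and \(\pm 3\), and
then shifted by a per-subject offset (baseline 3 bins, which puts mean
confidence near the observed 6.4; slope \(-0.28\) bins per anxiety SD;
subject-level residual SD 0.75) and clamped to 1--10. The stimulus
schedule is i.i.d. Bernoulli(0.5); the per-trial presence probability is
a free configuration parameter since a fixed experimenter sequence is
equally plausible.

What the generator does **not** emulate: physiological noise, breathing
dynamics, learning or fatigue across trials, site differences beyond the
confidence dialect, and any dependence between consecutive trials.
Passing recovery tests on these cohorts therefore demonstrates that the
estimation pipeline inverts its own generative assumptions at realistic
sizes — not that real FDT data satisfy those assumptions.

The subject confidence *offset* exists to plant metacognitive-bias
effects for the OLS analyses. Recovery experiments for the hierarchical
insight model set the offset machinery to zero (baseline, slope and
noise), because the shift-and-clamp relabeling merges top confidence
bins and would measure scale relabeling rather than estimator recovery;
the offset is left on wherever the planted confidence slope itself is
the target.

## Interpreting the recovery experiments

The information floor matters when reading the recovery tests. At
60 subjects x 60 trials the posterior spread of \(\mu_{\log M}\) is
comparable to the 0.1 recovery tolerance itself (the fitted HDIs in the
recovery runs are roughly \(\pm 0.15\) wide), so even a perfectly
calibrated estimator misses a \(\pm 0.1\) window in an appreciable
fraction of single replicates. The acceptance test
therefore checks the replicate-*averaged* posterior means against the
truth (bias bounded by 0.1) together with per-replicate HDI coverage
(truth inside the 95% interval in at least 9 of 10 runs), which are the
claims a recovery experiment can meaningfully test at this size. For
the effect-magnitude cohorts at N = 175 the checks are sign and
ordering: the confidence slope and the women's insight slope negative,
and the women's slope below the men's — the men's planted slope (+0.02)
is smaller than its posterior spread, so its sign is not a meaningful
target.

Problem sizes used by the validation suite (chosen to exercise each
property at the smallest informative scale): 50 random tables for the
closed-form SDT check; 20 random 60-trial tables for the MLE/grid
equivalence; 11 subjects x 10000 trials for Mratio self-consistency;
10 replicates of 60 x 60 for hierarchical recovery (2 chains, 3000
warm-up + 5000 retained); 50 null cohorts of 20 subjects plus 200 null
OLS cohorts for calibration; 200 staircase sessions; 10 replicates at
N = 175 with single-chain scaled-down draws for the effect-magnitude
check.

## Known limitations

* The criteria model trades per-subject flexibility for estimability.
  Real raters with idiosyncratic, strongly unequal criterion spacing are
  represented only through the global shape and the per-side scale;
  residual misfit attenuates meta-d' toward zero rather than inflating
  it, so the direction of the resulting error is conservative.
* Type-1 estimation assumes the equal-variance Gaussian observer; no
  unequal-variance variant is provided.
* Meta-d' is fitted jointly over both response sides; response-specific
  meta-d' is out of scope.
* The hierarchical model treats trials as exchangeable within subject;
  staircase-induced nonstationarity in the threshold block is ignored,
  as in the standard analysis.
* HDI-based significance inherits the usual caveat that it is a
  decision rule on the posterior, not a frequentist error guarantee;
  the calibration simulations bound its null exclusion rate at the
  study's scale.
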