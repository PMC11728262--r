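# respmeta

Breathing-related interoception and metacognition from the Filter
Detection Task (FDT).

In the FDT, a participant decides on every trial whether a very small
inspiratory resistance (a stack of breathing-circuit filters) was added
to their breathing circuit, and rates confidence in that decision. From
~60 trials at the participant's perceptual threshold, four interoceptive
dimensions are quantified:

| measure | definition |
|---|---|
| sensitivity | perceptual threshold: the filter count giving 60–85% accuracy |
| decision bias | SDT criterion c = −(z(HR) + z(FAR))/2; negative = "yes"-prone |
| metacognitive bias | mean confidence over threshold trials (1–10 scale) |
| metacognitive insight | logMratio = log(meta-d′/d′), confidence–accuracy efficiency |

The package is aimed at interoception / computational-psychiatry
researchers who want to analyse FDT-style data or study the estimators
themselves. It implements:

* per-subject measures from trial-level data (`fdt_measures()`),
  including the 10-bin down-sampling of 0–100 confidence scales;
* single-subject **maximum-likelihood meta-d′** (`fit_metad_mle()`), with
  the type-1 point fixed at the scaled criterion c′ = c·meta-d′/d′ and
  the multinomial confidence likelihood conditional on stimulus and
  response;
* a **hierarchical Bayesian group model** with an embedded covariate
  regression on subject logMratio (`fit_metad_hier()`):
  logM_s ~ N(μ + xₛᵀβ, σ), latent per-subject type-1 parameters,
  group-structured type-2 criteria, β ~ N(0,1) on z-scored covariates,
  sampled by a purpose-built adaptive MCMC (C++) with split-R̂
  diagnostics; significance via the 95% highest-density interval
  excluding zero;
* the **OLS analysis suite** for the other three measures
  (`run_measure_suite()`): base, gender-interaction,
  gender-specific-slope (mathematically equivalent) and site-collapsed
  sensitivity models;
* the **risk-controlled staircase** that sets task difficulty
  (`simulate_session()`): cumulative accuracy is transformed through a
  Beta(1+k, 1+n−k) posterior and a filter change is prompted when the
  probability of being inside the 60–85% band drops below 20%;
* a **synthetic cohort generator** (`simulate_cohort()`) emulating the
  pooled four-site study (N = 175, 51% women, 60 trials/subject) with
  planted anxiety effects, so every stage is testable without
  participant data.

## Worked example

```r
library(respmeta)

cohort   <- simulate_cohort(synth_config(), seed = 1)
measures <- fdt_measures(cohort$trials)
print(measures)
#> FDT interoceptive measures for 175 subjects
#>  subject_id threshold_filters   d_prime decision_bias metacog_bias log_m_ratio
#>        S001                 2 1.5160522    0.32729880     6.816667          NA
#>        S002                 5 1.3423706   -0.10523647     6.550000          NA
#>        S003                 4 1.4244627    0.12938986     6.333333          NA
#>        S004                 5 1.1728566   -0.05423858     6.216667          NA
#>        S005                 5 0.3226422   -0.19713771     4.300000          NA
#>        S006                 5 2.0781932    0.07167503     6.800000          NA
#>   ... 169 more subjects

## metacognitive bias vs state anxiety (OLS)
suite <- run_measure_suite(measures, cohort$covariates,
                           "metacog_bias", "stai_state")
print(suite$base)
#> OLS model [base]: n = 175, residual df = 170
#>       term estimate     se       t      p
#>  intercept   6.4062 0.0875 73.2539 0.0000
#>    score_z  -0.2441 0.0588 -4.1547 0.0001
#>      site2   0.0730 0.1659  0.4397 0.6607
#>      site3   0.2276 0.1663  1.3688 0.1729
#>      site4   0.1705 0.1542  1.1055 0.2705

## metacognitive insight: hierarchical regression with gender interaction
des <- build_design(cohort$covariates, "stai_state", type = "gender")
fit <- fit_metad_hier(measures, des,
                      mcmc = mcmc_control(n_chains = 2, n_iter = 3000,
                                          seed = 1))
print(fit)
#> Hierarchical meta-d' model: 174 subjects, 2 chain(s) x 3000 draws
#>                  param   mean hdi_low hdi_high excludes_zero  rhat
#>                mu_logM -0.200  -0.361   -0.042          TRUE 1.026
#>             sigma_logM  0.184   0.015    0.303          TRUE 1.049
#>           beta_score_z -0.065  -0.160    0.032         FALSE 1.016
#>            beta_gender -0.037  -0.185    0.104         FALSE 1.020
#>  beta_score_z_x_gender -0.048  -0.188    0.100         FALSE 1.002
#>             beta_site2  0.130  -0.078    0.368         FALSE 1.027
#>             beta_site3  0.107  -0.121    0.325         FALSE 1.028
#>             beta_site4  0.070  -0.117    0.282         FALSE 1.016
#>              slope_men -0.065  -0.160    0.032         FALSE    NA
#>            slope_women -0.113  -0.231   -0.008          TRUE    NA
```

Read: mean confidence sits at 6.41 bins and drops by 0.24 bins per SD
of state anxiety (p < 0.001) — the planted confidence effect. The
population logMratio mean is −0.20 with subject SD 0.18. The anxiety
slope on insight is −0.11 in women (95% HDI excluding zero) versus
−0.07 in men (HDI spanning zero): the gender-specific pattern the
generator plants, significant only in women, while one subject was
excluded for carrying no type-2 information.

The staircase and the whole pipeline are also scriptable from the
shell via `exec/respmeta` (verbs `simulate`, `staircase`, `measures`,
`all`), with YAML configuration.

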