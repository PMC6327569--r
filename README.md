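# pmmi — pattern-mixture multiple imputation for longitudinal trials

`pmmi` is an R package for sensitivity analysis of longitudinal
clinical trials with missing outcome data. It targets the common
situation where patients deviate from protocol (drop out, miss visits)
and the primary analysis assumes the missing outcomes are *missing at
random* (MAR). Whether that conclusion is trustworthy depends on how it
holds up under explicit *missing not at random* alternatives, and the
pattern-mixture-with-multiple-imputation approach makes those
alternatives concrete: each deviating patient's unobserved
post-deviation distribution is built by "borrowing" from a reference
group of patients in the same trial.

The package is for trial statisticians and methods researchers who want
the whole workflow in one place: pattern bookkeeping, a Bayesian
imputation engine, the reference-based assumptions, pooled mixed-model
inference, and a simulation driver to verify operating characteristics.

## The model

Within each arm, the vector of \(J\) scheduled outcomes is modelled as
multivariate normal around per-visit regressions on baseline
covariates, `Y_i | x_i ~ N(B'x_i, Sigma)`. Gibbs data augmentation
under the Jeffreys prior yields posterior draws of `(B, Sigma)` per
arm. For a patient who deviates after visit `n_i`, the joint
distribution of pre- and post-deviation data is assembled under one of
five assumptions:

- **MAR** — the randomized arm's own distribution throughout
  (*de jure*);
- **J2R** (jump to reference) — post-deviation means jump to the
  reference arm's;
- **CDR** (copy difference in reference) — post-deviation mean
  *increments* copy the reference arm's, starting from the benefit
  already attained;
- **CR** (copy reference) — the whole profile is the reference arm's;
- **LMCF** (last mean carried forward) — means flatten at the
  randomized arm's mean at deviation.

For J2R/CR the composite covariance takes the pre-deviation block from
the arm governing the pre-deviation data and the post-given-pre
conditionals from the reference arm (the Carpenter–Roger–Kenward
construction). Missing values are drawn from the conditional normal
given each patient's observed values; `K` completed datasets are each
analysed with a random-intercept linear mixed model

```
sqrt(CD4)_ij = b0 + b1 trt + b2 month + b3 trt:month
             + b4 ART + b5 trt:ART + b6 age + b_i + e_ij
```

(REML, via lme4), and estimates are pooled with Rubin's rules:
`T = W + (1 + 1/K) B`, `df = (K-1)(1 + W/((1+1/K)B))^2`.

## Worked example

```r
library(pmmi)

# a two-arm synthetic cohort with 31% / 37% of patients deviating
trial <- generate_impi_like(seed = 7, n_per_arm = 100,
  deviation_mix = list(c("2" = 0.11, "3" = 0.06, "4" = 0.14),
                       c("2" = 0.14, "3" = 0.16, "4" = 0.07)))

classify_patterns(trial)
#> pattern_table: 4 patterns x 2 arms
#>  pattern arm0 arm1
#>    11111   69   63
#>    11110   14    7
#>    11100    6   16
#>    11000   11   14

cs <- pattern_arm_chisq(classify_patterns(trial))
#> chi-squared = 7.51 on 3 df (p = 0.057)

res <- sensitivity_analysis(trial, methods = c("MAR", "LMCF", "J2R", "CR"),
                            reference = "both", K = 10, seed = 42,
                            gibbs = gibbs_config(100, 25))
res[res$coefficient == "trt", c("analysis", "estimate", "se", "p")]
#>  analysis estimate    se      p
#>       MAR    -1.52 0.993 0.1261
#>      LMCF    -1.79 0.995 0.0729
#>  J2R (P-)    -1.42 1.017 0.1616
#>  J2R (P+)    -1.70 0.981 0.0832
#>   CR (P-)    -1.42 1.031 0.1691
#>   CR (P+)    -1.39 1.005 0.1680
```

The pattern table shows four monotone dropout patterns; the
chi-squared test does not reject homogeneity of patterns across arms
at the 5% level. In the sensitivity table, each row is one analysis of
the treatment main effect: the MAR (de jure) estimate of −1.52 moves
at most ~0.3 of a pooled standard error under any of the de facto
assumptions — `(P-)` rows borrow the control arm's distribution for
deviating active-arm patients, `(P+)` rows the reverse — so the
MAR-based inference is robust to these departures.

Simulation-based operating characteristics come from `run_study()`:

```r
mt <- run_study(sim_config(n_reps = 250, mechanisms = "MCAR", rates = 0.2,
                           methods = c("ML", "MAR", "J2R"), K = 10,
                           master_seed = 1))
```

which reports bias, RMSE and coverage (with Monte-Carlo standard
errors) of the treatment, time and treatment-by-time coefficients for
direct maximum likelihood and each imputation method.

## Layout

- `R/` — implementation: trial containers and pattern tables
  (`trial_data.R`), the Gibbs engine (`mvn_engine.R`), the
  reference-based joints (`reference_based.R`), imputation/pooling
  (`mi_pipeline.R`), the simulator (`synthetic_data.R`) and the study
  driver (`simulation_study.R`).
- `vignettes/reference-based-imputation.Rmd` — the methods vignette:
  model, assumptions, parameter defaults and design decisions.
- `inst/cli/` — thin command-line wrappers (`simulate-data.R`,
  `analyze.R`) over the same functions.
- `tests/testthat/` — unit, property and end-to-end tests.
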