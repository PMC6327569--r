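---
title: "Reference-based multiple imputation for longitudinal trials with dropout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based multiple imputation for longitudinal trials with dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmi)
```

## The problem

In a longitudinal randomized trial, patients deviate from the protocol —
they drop out, miss visits, or stop treatment — and their scheduled
outcome measurements after the deviation are missing. A primary analysis
under *missing at random* (MAR) answers the *de jure* question: what
would the treatment effect have been had everyone adhered? That answer
is only credible if the conclusions survive plausible *missing not at
random* (MNAR) alternatives. `pmmi` implements the pattern-mixture
route to such sensitivity analyses: the distribution of a deviating
patient's unobserved post-deviation data is specified explicitly, by
reference to other groups of patients in the same trial, the missing
data are multiply imputed under each assumption, and every completed
dataset is analysed with the same substantive model.

The motivating setting is a two-arm trial (placebo vs. active) with an
immunological outcome analysed on the square-root scale (e.g. √CD4
count) at five scheduled visits (months 0, 0.5, 1, 3, 6), a
time-varying treatment-status covariate (ART) and baseline age.

## Pattern bookkeeping

Write \(Y_{ij}\) for patient \(i\)'s outcome at visit \(j = 1,\dots,J\)
and \(R_{ij} \in \{0,1\}\) for the observed-data indicator. The
pattern-mixture factorisation models the outcome *jointly with* the
missingness pattern: the observed data are a mixture over patterns
\(u\) with weights \(\pi_u\), and a separate outcome model may hold in
each pattern. `classify_patterns()` tabulates the patterns with per-arm
counts, proportions and per-visit means; `pattern_arm_chisq()` tests
homogeneity of the pattern distribution across arms by the Pearson
chi-squared statistic (patterns with zero total count are dropped —
their expected counts are undefined — and the degrees of freedom count
kept patterns only); `deviation_time()` records each patient's last
observed visit \(n_i\) and any intermittent gaps before it. A trial is
*monotone* when every pattern is a block of observed visits followed
only by missing ones.

## The imputation engine

**Step A — model.** Within each arm, the \(J\) visit outcomes are
multivariate normal around per-visit regressions on baseline
covariates: \(Y_i \mid x_i \sim N(B^\top x_i, \Sigma)\) with \(B\) a
\(p \times J\) coefficient matrix and \(\Sigma\) unstructured. The
default covariates are an intercept, baseline age and baseline ART
status; columns constant across the trial are dropped. An unstructured
\(\Sigma\) makes the imputation model at least as rich as the
random-intercept analysis model, which keeps Rubin's variance estimate
on the conservative side rather than the anticonservative one.

**Steps B–C — posterior draws.** `gibbs_posterior()` draws \((B,
\Sigma)\) from their joint posterior by data augmentation under the
improper Jeffreys prior \(p(B, \Sigma) \propto
|\Sigma|^{-(J+1)/2}\). Each iteration alternates an I-step (draw every
missing cell from its conditional normal given the patient's observed
cells and the current parameters, vectorised over patients sharing a
pattern) and a P-step (draw \(\Sigma\) from its inverse-Wishart full
conditional with \(n - p\) degrees of freedom, then \(B\) from its
matrix-normal full conditional). The prior is a design choice — it is
the standard noninformative choice in multivariate-normal multiple
imputation and matches widely used implementations; nothing in the
procedure depends on proper-prior elicitation. Engine defaults are a
burn-in of 200 iterations and thinning of 100 between retained draws;
with complete data the draws are exactly independent, and with the
monotone patterns typical here the chain decorrelates in far fewer
iterations, so the simulation driver uses burn-in 100 / thinning 25
(see below). One chain per arm is run per imputation round, with chain
seeds derived from the master seed by a fixed counter scheme so any
chain is reproducible in isolation.

**Steps D–E — the post-deviation joint.** For a patient deviating
after visit \(n_i\), the marginal mean of the joint pre/post-deviation
distribution is assembled by `build_marginal_mean()` from the
covariate-predicted mean profiles \(\mu^{rand}\) and \(\mu^{ref}\) of
the randomized and reference arms:

| method | pre-deviation mean | post-deviation mean \(j > n_i\) |
|---|---|---|
| MAR  | \(\mu^{rand}_j\) | \(\mu^{rand}_j\) |
| J2R  | \(\mu^{rand}_j\) | \(\mu^{ref}_j\) |
| CDR  | \(\mu^{rand}_j\) | \(\mu^{rand}_{n_i} + (\mu^{ref}_j - \mu^{ref}_{n_i})\) |
| CR   | \(\mu^{ref}_j\)  | \(\mu^{ref}_j\) |
| LMCF | \(\mu^{rand}_j\) | \(\mu^{rand}_{n_i}\) |

`build_joint_covariance()` supplies the covariance. MAR, LMCF and CDR
keep the randomized arm's \(\Sigma\). For J2R and CR the composite
matrix takes the pre-deviation block from the arm that governs the
pre-deviation distribution and the post-given-pre regression
coefficients and conditional covariance from the reference arm — the
construction of Carpenter, Roger and Kenward. The verbal definitions
of these options do not pin the covariance down; this construction is
the standard one in the literature and is isolated in a single
function so it can be audited or replaced. For CR it collapses to the
reference arm's \(\Sigma\) unchanged.

`impute_patient()` then draws the missing values from the conditional
normal given the observed ones. Non-monotone patients are handled in
two stages within the same parameter draw: intermittent gaps (before
\(n_i\)) are first imputed under the randomized arm's MAR conditional
given all observed values, then post-deviation values are drawn under
the chosen method's joint given the completed history — the
post-deviation assumptions are statements about what happens *after*
deviation, while an isolated missed visit is an administrative gap.
Patients in the reference arm itself, and everyone under MAR, are
imputed under randomized-arm MAR; LMCF uses each patient's own arm.

**Step F — analysis and pooling.** `impute_k()` creates \(K\)
completed datasets (default \(K = 50\); the source material does not
state its \(K\), and 50 keeps the Monte-Carlo contribution to the
pooled variance below a few percent). Each is analysed by
`fit_lmm()`, a REML random-intercept linear mixed model

\[
\sqrt{CD4}_{ij} = \beta_0 + \beta_1\,\text{trt}_i + \beta_2\,t_j +
\beta_3\,\text{trt}_i t_j + \beta_4\,\text{ART}_{ij} +
\beta_5\,\text{trt}_i\text{ART}_{ij} + \beta_6\,\text{age}_i + b_i +
\epsilon_{ij},
\]

with \(b_i \sim N(0, \sigma_b^2)\), \(\epsilon_{ij} \sim N(0,
\sigma_\epsilon^2)\), and `pool_rubin()` combines the \(K\) estimates:
\(\bar q\) the mean, \(W\) the mean within-imputation variance, \(B\)
the between-imputation variance, total variance \(T = W + (1 +
1/K)B\), classic Rubin degrees of freedom \((K-1)(1 + W/((1+1/K)B))^2\)
and a two-sided Wald p-value on \(t_{df}\). The small-sample
Barnard–Rubin degrees of freedom are available through the
`df_complete` argument; the classic rule is the default because it is
the rule the pooled analyses here are built around, and no multiplicity
adjustment is applied. `sensitivity_analysis()` wraps the whole loop
and reports one block of coefficients per analysis, running each
reference-based method under the control-arm reference ("P-") and the
active-arm reference ("P+") when `reference = "both"` — the labels
follow the convention that the sign names the arm patients jump *to*.

## The synthetic trial and the simulation study

`generate_trial()` draws complete cohorts from
\[
Y_{ij} = \beta_0 + \beta_1\,\text{trt}_i + \beta_2 t_j + \beta_3\,
\text{trt}_i t_j + b_i + \epsilon_{ij},
\]
with defaults \(\beta = (13, 0.75, 0.11, -0.19)\) on the square-root
CD4 scale, \(\sigma_b = 4.57\), \(\sigma_\epsilon = 0.20\), five visits
at months 0, 0.5, 1, 3, 6 and deterministic 1:1 alternating allocation
(exactly balanced arms, no allocation noise in small replicates). These
defaults are the stated study conditions; the reading of the published
parameter list assigns its fifth value (0.20) to the residual standard
deviation, and every value is independently configurable because that
reading is not unambiguous. A consequence worth noting: with
\(\sigma_b \gg \sigma_\epsilon\) the between-patient spread dominates,
so the *scale* of bias and RMSE for the treatment effect is governed by
\(\sigma_b/\sqrt{n}\); coverage probabilities, which are
scale-invariant, are the quantities this configuration reproduces
stably.

`impose_dropout()` applies a logistic dropout model scanning visits in
order: a patient still in the study drops at visit \(j\) with
probability \(\text{expit}(\alpha + \lambda(Y_{i,j-1} - Y_{i1}))\),
with \(\lambda = 0\) under MCAR and \(\lambda = 0.5\) logits per unit
change-from-baseline under MAR (the dropout model's slope is a design
default — only the intercept is ever calibrated). Dropout is monotone
by default and the baseline visit is never removed.
`calibrate_rate()` finds \(\alpha\) for a target overall
non-completion fraction by bisection over Monte-Carlo estimates
(20,000 simulated patients per evaluation, common random numbers,
tolerance half a percentage point).

`run_study()` ties it together: per mechanism × rate cell it
calibrates the intercept once, then per replicate generates a cohort
of 200 patients, imposes dropout, and analyses it with maximum
likelihood (the direct random-intercept fit on the observed rows —
valid under MAR) and with each requested imputation method, sharing
one set of posterior draws per replicate across methods. Reference-
based methods use the control arm as reference, the conservative
choice for an active-vs-control comparison. Bias, RMSE and coverage of
the nominal 95% interval are reported for the treatment, time and
treatment-by-time coefficients with Monte-Carlo standard errors
(intervals use \(t_{df}\) with the pooled df for MI and the normal
quantile for ML). Replicate seeds derive deterministically from the
master seed, so any cell can be re-run in isolation.

The default problem sizes are those used throughout the package's own
checks: 1000 replicates for ML-only cells and 250 replicates with
\(K = 10\) for MI cells at 200 patients per replicate, with Gibbs
burn-in 100 and thinning 25. These are deliberate desk-scale choices:
ML coverage stabilises quickly, while each MI cell costs
\(n_{reps} \times K\) mixed-model fits, and at these sizes the
Monte-Carlo standard error of a coverage estimate (about 1.3
percentage points at 250 replicates) is already well below the
differences of interest. The full published-scale experiment (1000
replicates, \(K = 50\), all mechanisms and rates) is a configuration
change, not a code change.

## What the generator does and does not emulate

The simulator reproduces the features the methods are sensitive to:
Gaussian random-intercept trajectories, balanced two-arm allocation,
the five-visit schedule, monotone (optionally non-monotone) dropout
with an outcome-dependent MAR mechanism, and calibrated overall
deviation rates in the 5–50% band. It does not emulate death or other
terminal events correlated with the outcome (which would require joint
modelling), measurement-scale floors (√CD4 is treated as unbounded
Gaussian), visit-time jitter, or covariate effects on the outcome
(age and ART enter the generator as inert covariates). Passing
simulation checks therefore demonstrates correctness of the machinery
under the stated conditions, not robustness of any particular trial's
conclusions.

## Numerical choices and degenerate inputs

- Gaussian conditioning uses the Cholesky factor of the observed
  block; a singular observed block raises an error naming the visits
  involved. Conditional covariances are symmetrised and, where
  numerically semi-definite, square-rooted through an eigenvalue
  clip rather than aborting an imputation.
- Inverse-Wishart draws that fail Cholesky are jittered once by
  `1e-8 * I`; a second failure aborts the chain with diagnostics.
- `pool_rubin()` returns infinite degrees of freedom when the
  between-imputation variance is exactly zero (all imputations agree).
- Completers have nothing to impute: the deviation index is the last
  observed visit even when the trailing missing block is empty.
- Patients with fewer than two observed outcomes are excluded at load
  time with a logged count; zero-count patterns are dropped from the
  chi-squared table.
- The largest-remainder rule in `generate_impi_like()` makes requested
  pattern proportions exact whenever they divide the arm size.

One operating characteristic deserves emphasis. For the
reference-based methods, the point estimator borrows information from
the reference arm, so its true repeated-sampling variance can fall
*below* the mean within-imputation variance \(W\); Rubin's total
variance \(T = W + (1+1/K)B\) then overstates it and the nominal 95%
intervals overcover — in this package's own simulations, J2R time-slope
coverage at 50% dropout runs near 98–99% rather than 95%. This is a
well-documented property of Rubin's rules under reference-based
imputation, not an implementation artefact: the pooled estimate is
unbiased, and the conservatism grows with the dropout rate and with
the share of variance attributable to imputation-model uncertainty.

## Known limitations

Only the five listed post-deviation assumptions are provided — no
delta-adjustment or tipping-point analyses. The imputation model is
Gaussian per arm; heavy-tailed or bounded outcomes should be
transformed upstream. The chi-squared homogeneity test is asymptotic
and the usual expected-count caveats apply to sparse pattern tables.
ML here means the direct-likelihood random-intercept fit; no
unstructured-covariance MMRM alternative is included.
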