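---
title: "Methods: mediation analysis for longitudinal microbiome data"
author: "medilmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation analysis for longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medilmm)
```

## The problem

Repeated sputum (or stool, airway, ...) samples from the same patients over
years produce microbiome data that are simultaneously *clustered* (samples
within a patient are correlated), *compositional* (sequencing counts carry
only relative information), and *high-dimensional* (tens to hundreds of
genera against a few hundred samples). The scientific question this package
addresses is a mediation question: when a clinical exposure — a disease state
such as exacerbation versus baseline, or a patient-level phenotype such as
disease aggressiveness — is associated with a change in lung function, how
much of that change flows *through* the microbial community, and through
which genera?

medilmm implements a structural-equation mediation framework built from two
linked regression layers plus a resampling layer:

1. an **outcome model**: a high-dimensional linear mixed model of the
   clinical outcome on the exposure, covariates, and all (log-proportion
   transformed) genus abundances, with a per-patient random intercept,
   estimated by a debiased lasso;
2. **mediator models**: one low-dimensional random-intercept linear mixed
   model per genus, regressing that genus on the exposure and covariates,
   fitted by REML;
3. a **cluster bootstrap** wrapping both layers for inference.

## Models

Write $i$ for the patient (cluster) and $k$ for the repeated observation
within patient. With exposure $T$, outcome $Y$, covariates $C$ (age by
default) and $H$ mediators $M^{\log}$, the outcome model is

$$Y_{ik} = \beta_0 + \beta_T T_{ik} + \sum_{t=1}^{H}\beta_{M_t} M^{\log}_{ikt}
 + \beta_C C_{ik} + \gamma_i + \varepsilon_{ik},$$

with $\gamma_i \sim (0, \psi)$ and $\varepsilon_{ik} \sim (0, \sigma_e^2)$,
both mean-zero with no further distributional assumptions. Each mediator $t$
follows

$$M^{\log}_{ikt} = \delta_0^t + \delta_T^t T_{ik} + \delta_C^t C_{ik}
 + \varphi_i^t + \eta_{ikt}.$$

The **direct effect** of the exposure is $\beta_T$; the **indirect effect**
through genus $t$ is the product of coefficients $\delta_T^t \beta_{M_t}$;
the **total effect** is the direct effect plus the sum of indirect effects.
By construction `total - direct - sum(indirect)` is identically zero in every
fit, and the test suite asserts this to machine precision.

Both printed model equations index the exposure at the observation level.
Clinical state genuinely varies within a patient, and pairwise state
contrasts are only estimable from that within-patient variation, so the
exposure is treated as observation-level throughout; for patient-level
phenotypes it is simply constant within cluster.

### Mediator transform

Counts are converted to log proportions with a pseudo-count:
$M^{\log}_{ikt} = \log_{10}\{(M_{ikt} + 0.5)/D_{ik}\}$ where $D_{ik}$ is the
sample's read depth. Adding 0.5 to the numerator count keeps zeros finite and
leaves the useful conservation identity
$\sum_t 10^{M^{\log}_{ikt}} = 1 + 0.5\,H/D_{ik}$, which the tests check
exactly. An alternative placement (0.5 added to the proportion itself) is
available as `lognorm_transform(..., pseudo = "proportion")` for sensitivity
analysis; the numerator-count placement is the default because it is the one
that behaves like a pseudo-count.

### Estimating the outcome model: covariance proxy and debiased lasso

With $p = H + 2$ columns possibly exceeding the number of samples, the fixed
effects are estimated by a penalized quasi-likelihood scheme that never
estimates $(\psi, \sigma_e^2)$ directly. A working covariance
$\Sigma_a^i = a Z_i Z_i^\top + I_{m_i}$ (random-intercept design
$Z_i = 1_{m_i}$) stands in for the true covariance of the random components;
$a \ge 0$ is a tuning scalar playing the role of the variance ratio
$\psi/\sigma_e^2$. Observations are whitened blockwise with
$(\Sigma_a^i)^{-1/2}$ and the lasso

$$\hat\beta = \arg\min_\beta \frac{1}{2\,\mathrm{Tr}(\Sigma_a^{-1})}
 \|y_a - X_a\beta\|_2^2 + \lambda\|\beta\|_1$$

is solved by cyclic coordinate descent. $\mathrm{Tr}(\Sigma_a^{-1})$ acts as
the effective sample size. Coordinate-wise inference uses the debiased
estimator: for each coordinate $j$, a nodewise lasso of $(X_a)_{\cdot j}$ on
the remaining columns yields a correction score
$\hat w_j = (X_a)_{\cdot j} - (X_a)_{\cdot,-j}\hat\kappa_j$, and

$$\hat\beta_j^{(db)} = \hat\beta_j +
 \frac{\hat w_j^\top (y_a - X_a\hat\beta)}{\hat w_j^\top (X_a)_{\cdot j}},
 \qquad
 \hat V_j = \frac{\sum_i \{(\hat w_j^i)^\top (y_a^i - X_a^i\hat\beta)\}^2}
 {\{\hat w_j^\top (X_a)_{\cdot j}\}^2},$$

with the variance summing squared score-residual products *per cluster* so
that within-patient correlation is respected. In the low-dimensional limit
($\lambda \to 0$, $p \ll N$) the debiased estimate coincides with generalized
least squares under $\Sigma_a$ — the residual is orthogonal to the column
space, so the correction vanishes — and the tests verify this to $10^{-4}$.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `a` | CV over {0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8} | proxy variance ratio $\psi/\sigma_e^2$ (unitless) |
| `lambda` | CV over $\{2.0, 1.9, \ldots, 0.1\}\sqrt{2\log(p)/N}$ | lasso penalty |
| `nfolds` | 5 | cluster-level CV folds |
| `n_boot` | 3000 | bootstrap resamples |
| `level` | 0.95 | BCa interval level |
| `min_reads` | 1000 | sample depth floor (reads) |
| `min_count`, `min_fraction` | 3, 0.05 | prevalence rule: counts strictly above `min_count` in at least `min_fraction` of samples |

Cross-validation details, all cluster-level (a patient's samples are never
split across folds):

* The criterion for `a` is the raw-scale held-out prediction error
  $\|Y_{held} - X_{held}\hat\beta(a)\|_2^2$. That criterion needs a
  $\lambda$ for each candidate `a`; the fitted $\hat\beta(a)$ is taken at the
  grid $\lambda$ minimizing the same CV error, i.e. `a` is chosen as
  $\arg\min_a \min_\lambda \mathrm{CV}(a, \lambda)$ and $\lambda$ is then
  re-selected at the chosen `a`. This resolves the circularity of tuning two
  coupled parameters with one criterion in a single pass.
* The $\lambda$ grid's rate $\sqrt{2\log(p)/N}$ uses the full-sample $N$
  (not the per-fold training size) so that the same grid is comparable
  across folds. The multiplier step is 0.1.
* Ties prefer the smaller `a` (weaker working correlation) and the larger
  $\lambda$ (sparser model).
* Each nodewise regression selects its own $\lambda_j$ by the same
  machinery; all $p-1$ nodewise coefficients are penalized.

The design includes an unpenalized intercept, excluded from the penalty and
from debiasing: the outcome (an FEV~1~% scale, mean far from zero) and the
strongly negative-mean log proportions make an intercept statistically
necessary even though the penalty is written over all coefficients. Columns
are not standardized by default — the mediators already share the
log-proportion scale and the exposure is binary — but `standardize = TRUE`
is available.

## REML mediator models

Each mediator model is a random-intercept linear mixed model fitted by REML.
The implementation profiles the restricted likelihood down to the single
variance ratio $\theta = \psi/\sigma_e^2$ — for a random intercept all the
per-cluster matrix algebra collapses to closed-form downdates of cluster
sums — and optimizes over $\log\theta$ with an explicit boundary comparison
at $\theta = 0$, so $\hat\psi \ge 0$ by construction and $\hat\psi = 0$
recovers ordinary least squares exactly. This specialization matters because
the bootstrap refits on the order of $10^5$ mediator models in a full run;
the test suite cross-checks fixed effects, variance components, and standard
errors against lme4 on unbalanced multi-covariate designs.

One caveat discovered while validating: the textbook identity "balanced
one-way REML equals the ANOVA estimators" requires the within-cluster mean
square to be positive. On degenerate data with literally zero within-cluster
variation the restricted likelihood is unbounded as $\sigma_e^2 \to 0$ and
every optimizer (this one and lme4 alike) reports a path-dependent $\hat\psi$;
the tests therefore check the ANOVA identity on nondegenerate designs only.

## Bootstrap inference

Patients are resampled with replacement (whole clusters, preserving
within-patient correlation; duplicated clusters get fresh labels so they stay
distinct clusters). For every resample the *entire* analysis is repeated,
including the cross-validated selection of `a` and $\lambda$. Reported
estimates are means over resamples, with the original-sample fit also kept.
Intervals are BCa: bias correction $z_0 = \Phi^{-1}(\#\{\theta^* <
\hat\theta\}/B)$ and acceleration from the leave-one-cluster-out jackknife
skewness; endpoints are linearly interpolated empirical quantiles. P-values
are two-tailed bootstrap proportions, $p = 2\min(\#\{\theta^* \le 0\},
\#\{\theta^* > 0\})/B$ floored at $1/B$, and Benjamini-Hochberg adjustment is
applied across the $H$ indirect effects within one contrast (a flagged
alternative adjusts globally).

Determinism: the resample, original-fit, and jackknife substreams are all
derived from the single `seed`, so a result is a pure function of
`(data, configuration, seed)` and identical whether the bootstrap runs on 1
or many workers.

## What the synthetic generator emulates — and what it does not

`simulate_mediation_data()` produces the full data structure of a
longitudinal cohort: patients with 2–24 repeated samples, genus
log10-abundance latents with per-patient random intercepts, an exposure that
shifts a sparse subset of genera, multinomial counts drawn through a softmax
at realistic depths, and an outcome built from the *true* log proportions so
that pseudo-count estimation error is measured, never baked into the truth.
Defaults mirror a decade-long CF sputum cohort: 89 patients, 47 genera, an
outcome with grand mean 58 and residual SD 8 on an FEV~1~% scale, patient
random-intercept SD 8, ages 6–54, depths 1000–50000 reads. Mediator scales
(baseline spread SD 1 across genera; within-genus random-intercept SD 0.5
plus residual SD 0.8 on the log10 scale, i.e. roughly one order of magnitude
of within-genus variation) reflect how strongly genus proportions actually
swing in airway communities.

The generator deliberately omits several features of real data: taxonomic
misassignment, chimeras and sequencing error (counts are exact multinomial
draws unless the optional Dirichlet overdispersion layer is enabled),
temporal autocorrelation beyond the patient random intercept, exposure
assignment correlated with past outcomes, and unmeasured confounding. A
passing test suite therefore demonstrates that the estimators recover the
effects of their own generative model at realistic sizes — not that the
causal assumptions (no unmeasured confounding, mediators measured without
error, no outcome-to-mediator feedback) hold in any real cohort.

## Numerical choices

* Coordinate descent runs on the Gram (covariance-update) form with
  warm-started descending-$\lambda$ paths and active-set sweeps;
  convergence when the largest coefficient change in a sweep is below
  $10^{-8}$, hard cap $10^5$ sweeps, non-convergence is an error, never a
  silent result.
* With an unpenalized intercept the design columns are mean-centered before
  fitting and the intercept is corrected afterwards. This is an exact
  reparametrization of the same objective, and it is what makes the solver
  practical on log-proportion designs, whose column means (about $-2$) would
  otherwise dominate their variances and stall coordinate descent.
* Blockwise inverse square roots use symmetric eigendecomposition with an
  eigenvalue floor of $10^{-12}$.
* The REML profile optimizes $\log\theta$ on $[\log 10^{-10}, \log 10^7]$
  with `optimize()` at tolerance $10^{-10}$, plus the explicit $\theta = 0$
  boundary check.
* BCa: bootstrap proportions of exactly 0 or 1 are clamped to $1/(2B)$ and
  $1 - 1/(2B)$ before $\Phi^{-1}$ (logged); fewer than 3 jackknife values
  set the acceleration to 0; an all-equal bootstrap distribution returns the
  degenerate point interval (logged).
* A constant mediator column (e.g. identical observed richness everywhere)
  is dropped from the community outcome model with $\beta_M = 0$ rather than
  producing a singular design, so its indirect effect is exactly 0.
* Resample-level fit failures are dropped with a recorded count; more than
  5% failures aborts the bootstrap.

## Validation problem sizes

The acceptance suite exercises: exact closed forms (soft-thresholding,
compound-symmetry traces, balanced-ANOVA REML, BH); GLS equivalence at
$\lambda = 0$; debiased-lasso recovery on 50 replicates of a 50-patient,
100-genus design with 5 active genera of effect size $\ge 1$ (support MAE
below 0.25); community-mode recovery of $(\delta_T, \beta_M, \beta_T) =
(1, -2, -3)$ within 0.3 over 50 replicates; null rejection rate at most 0.12
and BCa coverage within [88%, 99%] over 100 replicates at $B = 500$ and
$B = 1000$ respectively; boundary-exact preprocessing; and bit-identical
serial/parallel bootstraps. End-to-end examples in this vignette and the
README use smaller $B$ than the production default of 3000 purely so they run
in seconds; the statistics do not change, only the Monte Carlo resolution of
the intervals.

## Known limitations

* Time is not modeled: random intercepts absorb patient-level correlation
  but not trends or uneven sampling intervals within a patient.
* Random effects are intercept-only; random slopes are out of scope.
* Exposure-mediator interactions are not modeled, and each contrast is a
  separate two-group fit rather than one multi-level model.
* The compositional closure means a shift in one genus's latent abundance
  perturbs all log proportions slightly; with many genera of modest
  proportion the product-of-coefficients truth used by the generator is
  accurate to first order, and the recovery tolerances absorb the remainder.
* Bootstrap p-values have resolution $1/B$; at $B = 3000$ the smallest
  reportable p-value is $3.3\times10^{-4}$.

## A worked community-level example

```{r community-example}
d <- simulate_mediation_data(n = 25, m_range = c(2, 6), H = 12, s = 3,
                             seed = 7)
fit <- medilmm(d$counts, d$metadata, ref = "baseline",
               comparison = "exacerbation", mode = "community",
               index = "shannon", n_boot = 200, seed = 7)
summary(fit)
```
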