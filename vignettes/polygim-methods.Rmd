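---
title: "Integrating external summary data into polytomous risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating external summary data into polytomous risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygim)
```

## The problem

Many diseases are collections of subtypes with partly distinct etiologies.
With individual-level data from one case-control study (the *internal*
study: controls $Y=0$ and subtypes $Y=1,\dots,K$), the natural model is the
polytomous logistic regression (PLR)

$$\log\frac{P(Y=k\mid X)}{P(Y=0\mid X)} = \omega_k + M_k(X;\theta_k),
\qquad k = 1,\dots,K,$$

with $M_k(X;\theta_k) = f(X)^\top\theta_k$ for a feature map $f$ shared
across classes (raw markers, a polygenic risk score $S(X)=\sum_i w_i X_i$,
or $\{S, S^2\}$). The scientific questions are the subtype-specific effects
$\theta_k$ and whether they differ across subtypes.

Other studies of the same disease rarely share individual records, but they
do publish coefficient estimates $\tilde\beta$ from logistic *working
models* of binary outcomes derived from $Y$:

* **CC (case-case)** models compare two subtypes directly
  ($D=0$ if $Y=c_0$, $D=1$ if $Y=c_1$);
* **GC (grouped case-control)** models compare controls with a merged case
  group whose subtype composition $q$ is known (possibly degenerate on a
  single subtype, as with per-subtype GWAS summary statistics).

This package fits the PLR model by combining the internal study with any
number of such summary estimates, within one likelihood.

## Retrospective empirical likelihood

Case-control data are outcome-stratified samples, so the likelihood is
built retrospectively. Bayes' rule turns the PLR model into density ratios

$$P(X\mid Y=k) = P(X\mid Y=0)\,\Delta_k(X;\xi), \qquad
\Delta_k = \exp\{\tau_k + M_k(X;\theta_k)\},$$

with shifted intercepts $\tau_k$. Placing nonparametric masses $p_i$ on the
observed covariate values as the model for $P(X\mid Y=0)$ and profiling
them out under $\sum_i p_i = 1$ and $\sum_i p_i \Delta_k = 1$ yields the
internal profile likelihood

$$\ell_1(\xi)=\sum_i\sum_k 1(Y_i{=}k)\log\Delta_k(X_i;\xi)
 - \sum_i\log\Bigl\{1+\sum_k\rho_k\Delta_k(X_i;\xi)\Bigr\},
\qquad \rho_k = n_k/n_0.$$

For linear feature maps its maximizer coincides with the prospective
multinomial-logit MLE after the intercept conversion
$\tau_k = \omega_k - \log\rho_k$; the test suite verifies this equivalence
against an independently coded prospective optimizer to $10^{-6}$. For
nonlinear maps we treat $\ell_1$ itself as the definition of the estimator.

## What a summary estimate knows about $\theta$

An external working model, written retrospectively as
$P(X\mid D=1) = P(X\mid D=0)\exp\{\alpha_0 + m(X;\alpha_1,\beta)\}$, is fit
by ordinary logistic regression; only $\tilde\beta$ is reported, the
intercept and $\alpha_1$ are nuisance. Its estimating equation, transported
to the internal control distribution with the $\Delta_k$ ratios, becomes a
moment condition $E_{Y=0}[g(X;\mu^*)]=0$ on the joint parameter
$\mu = (\tau,\theta,\alpha,\beta)$, with

$$g = \varphi_0\,\Delta_{c_0} + \rho\,\varphi_1\,\Delta_{c_1}
\quad\text{(CC)},\qquad
g = \varphi_0 + \rho\,\varphi_1\sum_k q_k\Delta_k \quad\text{(GC)},$$

where $\varphi_0 = -\rho\delta/(1+\rho\delta)\,\partial\log\delta$,
$\varphi_1 = \partial\log\delta/(1+\rho\delta)$ and $\rho = N_1/N_0$ in the
external design. Summary data are **regular** when $g(\cdot;\mu^*)$ is not
identically zero — GC models always, and CC models whose covariates differ
from the target model's. A CC model consistent with the target model
(identical named feature set) makes $g \equiv 0$ at
$\alpha_0 = \tau_{c_1}-\tau_{c_0}$, $\beta = \theta_{c_1}-\theta_{c_0}$:
such **irregular** summary data carry direct information on the coefficient
contrast but no usable moment condition, and need a separate route.
`classify_regularity()` implements exactly this structural comparison of
named feature sets (numerical span checks would be fragile; users can
override the classification).

## The integrated estimator

For regular blocks the constrained problem — maximize the empirical
likelihood plus the summary quasi-likelihood
$-\tfrac N2(\beta-\tilde\beta)^\top V^{-1}(\beta-\tilde\beta)$ subject to
$\sum p_i = 1$, $\sum p_i\Delta_k = 1$, $\sum p_i\,g(X_i;\mu) = 0$ — is
profiled with Lagrange multipliers $(\lambda,\nu)$ into

$$\ell_V(\eta) = -\sum_i\log\Bigl\{1+\sum_k\lambda_k(\Delta_{ki}-1)
 + \nu^\top g(X_i;\mu)\Bigr\}
 + \sum_i\sum_k 1(Y_i{=}k)\log\Delta_{ki}
 - \tfrac N2(\beta-\tilde\beta)^\top V^{-1}(\beta-\tilde\beta),$$

whose stationary point is found by Newton-Raphson on the full score with
analytic gradient and Hessian (a finite-difference cross-check of both runs
in the test suite). The stationary point is a saddle — the objective is
convex in the multipliers and concave in $\mu$ — so line-search safeguards
use feasibility of every denominator and decrease of the score norm rather
than ascent. Implied control-distribution weights are
$\hat p_i = n^{-1}\{1+\sum_k\hat\lambda_k(\Delta_{ki}-1)+
\hat\nu^\top g_i\}^{-1}$; at a solution $\sum\hat p_i = 1$,
$\sum\hat p_i\Delta_k = 1$ and $\sum\hat p_i g_i = 0$ hold to $10^{-8}$,
and as $n$ grows $\hat\lambda_k \to n_k/n$ and $\hat\nu \to 0$.

Initialization follows the natural two-step recipe: the internal MLE for
$\xi$ (intercepts shifted by $-\log\rho_k$), and for each working model a
weighted logistic regression on the internal sample in which each subject
of outcome stratum $s$ receives weight (external count in $s$)/(internal
count in $s$), so the internal sample mimics the external design; the
fitted intercept is shifted by $-\log(N_1/N_0)$. The same construction is
used for CC models with the two compared subtypes as the weighting strata —
the GC recipe is the canonical one and the CC version is its direct analog.

### Choosing $V$, and the optimal iteration

$V$ plays the role of the scaled covariance $\Sigma_0$ of $\tilde\beta$
(with $\mathrm{Cov}(\tilde\beta) = \Sigma_0/N$). Three policies are
provided, matching the method labels used in the replication tables:

* `identity` (GIM$_I$): $V = I$ per block — consistent but inefficient;
* `sigma` (GIM$_{V_\sigma}$): the penalty is
  $\sum_j(\beta_j-\tilde\beta_j)^2/(2\,\mathrm{se}_j^2)$ from the reported
  standard errors. The printed $\sigma_i^2/N$ convention is reconciled
  dimensionally so that $V$ stands in for $\Sigma_0$; since
  $\mathrm{Cov}(\tilde\beta)_{jj} = \mathrm{se}_j^2$, this is the diagonal
  approximation of the optimal choice and ignores correlation between
  summary statistics;
* `optimal` (GIM$_{opt}$): $V$ is iteratively replaced by the estimated
  covariance of the summary statistics, re-solving until
  $\max|\Delta\eta| < 10^{-6}$ (cap 20 rounds; 2–4 are typical).

Internally the penalty is kept as a single quadratic form with weight
matrix $W$ on the stacked reported coefficients ($W = N V^{-1}$ for a
supplied $V$; $W = \mathrm{Cov}(\tilde\beta)^{-1}$ for the optimal policy),
which generalizes additively over blocks and absorbs different external
sample sizes.

### Estimating $\mathrm{Cov}(\tilde\beta)$, including overlap

Each working model solves an M-estimating equation with score
$\psi = (D - h)z$, $h = \rho\delta/(1+\rho\delta)$, under
outcome-stratified sampling. We estimate

$$A_m = \sum_s \frac{n_s^{(m)}}{N_m} E_s[h(1-h)\,zz^\top], \qquad
B_{mm'} = \sum_{s\ \text{shared}} n_s\,
\mathrm{Cov}_s(\psi_m, \psi_{m'}),$$

with stratum expectations computed on the internal sample through the
change of measure $\hat p_i\,\Delta_s(X_i)$, and
$\mathrm{Cov}(\tilde\gamma)_{mm'} = A_m^{-1}B_{mm'}A_{m'}^{-1}/(N_mN_{m'})$,
from which the $\beta$ block is extracted. Within a stratum $D$ is fixed
but $z$ is random, so the $D$ term must stay inside the covariance — a
subtle point that a naive "centered $h z$" shortcut gets wrong by a factor
of about two for case-case models (the test suite pins this down against
parametric bootstrap covariances). Models sharing a `study` label share
outcome strata, which produces the non-zero cross-blocks for, e.g., several
per-subtype GWAS models fitted on one control group; models from distinct
studies get exactly zero cross-blocks. Declared stratum counts of
overlapping models must agree; inconsistencies are a configuration error.

### Irregular summary data and the restricted MLE

A consistent CC model contributes the penalty
$-\tfrac N2(\theta_{c_1}-\theta_{c_0}-\tilde\beta)^\top
V^{-1}(\theta_{c_1}-\theta_{c_0}-\tilde\beta)$ added to $\ell_1(\xi)$, again
with the optimal-$V$ iteration (`fit_irregular()`, dispatched automatically
by `fit_polygim()`). Mixed regular and irregular blocks combine additively
in a single objective. As the penalty weight tends to zero the estimator
returns to the internal MLE.

The restricted MLE (`fit_rmle()`) instead imposes
$\theta_{c_1}-\theta_{c_0} = \tilde\beta$ exactly, solved by a damped KKT
Newton iteration. Because $\tilde\beta$ is random, its covariance is
propagated through the KKT sensitivity blocks
($\mathrm{Cov}(\hat\xi) = E\,\Omega\,E^\top + F\,\mathrm{Cov}(\tilde\beta)\,F^\top$);
the unpropagated covariance is retained in the fit object
(`cov_xi_noprop`) because the contrast between the two is what produces
honest versus anti-conservative coverage.

### Variance estimation

The closed-form information matrices of the asymptotic theory are not
reproduced term by term; instead every estimator uses one M-estimation
sandwich: $\mathrm{Cov}(\hat\eta) = H^{-1}\Omega H^{-1}$ with $H$ the
analytic Hessian of the profiled objective at the solution and $\Omega$ the
sum of (i) the within-outcome-stratum empirical covariance of the
per-subject score contributions — the stratum centering is what encodes the
retrospective design — and (ii) the penalty-score variance
$W\,\mathrm{Cov}(\tilde\beta)\,W$. This one construction covers the MLE
(where the inverse observed information is used directly, valid for the
slope block under case-control sampling), all three $V$ policies, the
irregular route and the RMLE, and is validated *empirically*: the
benchmark-reproduction tests require the mean estimated standard error to
track the replicate standard deviation within 10% for every reported
coefficient, and Wald coverage near 95%.

## The heterogeneity test

For feature $j$, $\hat\theta_{j\cdot} \sim N(\theta_{j\cdot}, \hat W)$ with
$\hat W$ the corresponding block of the fit covariance. The likelihood-ratio
statistic for $H_0:\theta_{j1}=\dots=\theta_{jK}$ is

$$\Lambda = \hat\theta_{j\cdot}^\top\hat W^{-1}\hat\theta_{j\cdot}
 - \frac{(\mathbf 1^\top\hat W^{-1}\hat\theta_{j\cdot})^2}
        {\mathbf 1^\top\hat W^{-1}\mathbf 1}
 \;\sim\; \chi^2_{K-1} \text{ under } H_0,$$

with the common effect $\hat a = (\mathbf 1^\top\hat W^{-1}
\hat\theta_{j\cdot})/(\mathbf 1^\top\hat W^{-1}\mathbf 1)$. Pairwise
comparisons are the $K=2$ specialization
$\Lambda = (\hat\theta_1-\hat\theta_2)^2/(W_{11}+W_{22}-2W_{12})$. Raw
per-pair p-values are reported (a Bonferroni column is appended as a
clearly supplementary convenience); a singular $\hat W$ is a hard error
rather than a silently regularized one, since it signals a degenerate fit.

## What the synthetic-data engine emulates

`two_marker_design()` is a fully enumerable population: two correlated
binary biomarkers with joint cell probabilities $(0.28, 0.12, 0.18, 0.42)$,
three outcome classes, intercepts $(-0.2, 0.1)$ and slopes
$(1.5, -1.0, -0.5, 1.2)$; internal study $2000/500/500$, external study
$1000/600/400$, and the four canonical working models CC1/CC2/GC1/GC2.
Because the covariate space has four cells, exact Bayes enumeration
provides independent oracles for the samplers, the constraint functions and
the population working-model solutions.

`prs_design()` emulates a multi-study GWAS setting: five outcome classes,
21 independent SNPs under Hardy-Weinberg equilibrium (dosage
$\sim\mathrm{Binomial}(2, f)$ — the genotype model is the standard
convention, chosen here once), risk acting through the PRS, with a null
parameter set ($\omega = (-3.9,-4.1,-3.6,-3.8)$, $\theta = 0$) and an
alternative set ($\omega_k = -3.8$,
$\theta = (0.019, 0.092, -0.12, 0.047)$). Under these intercepts the
subtype prevalences are 1.5–2.5% — rare, though the largest sits at about
2.5% rather than under 2%, which is why the rarity assertion in the tests
uses a 3% threshold. Weight uncertainty is emulated by drawing analysis
weights $\tilde w_i \sim N(w_i, c\,se_i^2)$ per replicate, $c \in
\{0, 1, 16\}$; the true data-generating weights stay fixed, so estimates
under large $c$ display genuine attenuation-style bias while null-model
inference remains valid. Study sizes follow the packaged eight-row layout
(`nhl_study_layout()`); two external populations differ by effect-allele
frequencies 0.2 lower (floored at 0.05) on the first 10 / last 11 SNPs,
which drives the complete-versus-partial summary-data strategy comparison.
The 21-SNP weight table shipped in `inst/extdata/` is a **synthetic
stand-in** with realistic magnitudes (effects 0.15–0.45, standard errors
0.028–0.065, frequencies 0.09–0.52); absolute benchmark values that depend
on the real panel are therefore not reproduced, while all pattern-level
properties (coverage, bias signatures, efficiency monotonicity) are.

Case-control sampling is exact, not approximate: class-conditional cell
distributions are enumerated for the two-marker design, and for the PRS
design per-SNP exponential tilting proposals are thinned by rejection on
the outcome denominator, which draws exactly from $P(X\mid Y=k)$.

What the engine does *not* emulate: linkage disequilibrium between SNPs,
non-Hardy-Weinberg genotype distributions, covariate missingness, and
working models other than logistic. Passing tests therefore demonstrate
correctness of the estimator under its stated sampling assumptions, not
robustness to their violation.

## Numerical choices

* Exponent clipping at $\pm 700$ inside every $\Delta$ and $\delta$ (with a
  logged warning) prevents overflow while leaving realistic surfaces
  untouched.
* Newton convergence at $\max|\text{score}| < 10^{-8}$, cap 100 iterations,
  step-halving for feasibility/monotonicity. Score components are sums of
  $n$ terms, so for very large studies an accumulation floor of
  $2\times10^{-10}\,n$ is accepted once the iteration has stalled at
  floating-point resolution.
* The $V$ iteration declares convergence at $\max|\Delta\eta| < 10^{-6}$
  (cap 20).
* Near-singular covariance matrices receive a ridge of
  $10^{-10}\,\mathrm{tr}/\dim$ before inversion, with a logged warning —
  except the heterogeneity-test $\hat W$, where singularity is an error by
  design.
* Replicate $r$ of a replication study uses seed (base + $r$), so any
  subrange of replicates is independently reproducible.

## Problem sizes used in the shipped studies

The packaged replication studies are sized for a single CPU: the
two-biomarker benchmark runs 2000 replicates (matching the published
tables); the multi-study PRS checks run 100–300 replicates on external-study
subsets, sized so that the profiled Newton systems stay near 100 dimensions
while each claimed pattern (null coverage, measurement-error bias,
efficiency monotonicity, partial-versus-complete strategy) remains
detectable at its stated tolerance. Common random numbers (shared replicate
seeds) are used across settings that are compared against each other.

## Known limitations

* GC models require known case-mix proportions $q$; unknown mixtures are
  out of scope.
* Summary data must come from the same source population as the internal
  study (the partial-summary strategy is the supported mitigation, with its
  three checkable validity conditions in `check_partial_validity()`).
* Mixed-model (relatedness-adjusted) summary statistics are not supported.
* The parameter count grows linearly with the number of summary
  coefficients; several hundred is practical, beyond that batching by
  independent SNP groups (not implemented here) is the standard recourse.
* Cross-covariance between multiple *irregular* blocks from one study is
  not exploited (each irregular block is penalized with its own weight);
  regular blocks share a full joint covariance.
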