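# polygim

Polytomous logistic regression for disease-subtype studies that integrates
coefficient estimates ("summary data") published by external studies, using
a profiled empirical likelihood.

## Who this is for

Epidemiologists and statistical geneticists who have individual-level
case-control data on a disease with several subtypes (controls `0`,
subtypes `1..K`) and want to sharpen subtype-specific effect estimates —
and tests of etiologic heterogeneity between subtypes — using coefficients
reported by other studies that only published logistic regression results:
case-case comparisons between two subtypes (CC), or grouped case-control
models comparing controls with a merged case group of known subtype mix
(GC), such as per-subtype GWAS summary statistics for the SNPs of a
polygenic risk score (PRS).

## The model and the estimator

The target model is the polytomous logistic regression

  log{ P(Y=k|X) / P(Y=0|X) } = ω_k + f(X)ᵀθ_k,   k = 1..K,

with a feature map f shared across classes (raw covariates, a PRS S(X) =
Σ w_i X_i, or {S, S²}). Written retrospectively, P(X|Y=k) =
P(X|Y=0)·Δ_k(X;ξ) with Δ_k = exp{τ_k + f(X)ᵀθ_k}. The control distribution
is modeled nonparametrically by masses p_i on the observed covariates; each
external working model contributes (i) a moment condition
Σ p_i g(X_i; μ) = 0 derived from its estimating equation ("regular" summary
data), or (ii) — when a case-case model is consistent with the target model
("irregular") — a quadratic penalty on the contrast θ_{c1} − θ_{c0} toward
the reported β̃. Lagrange-multiplier profiling gives a joint objective
solved by Newton-Raphson; the penalty matrix V is iterated to the estimated
covariance of the summary statistics (the efficient choice), and sandwich
covariances respect the retrospective sampling of every study, including
summary statistics computed on overlapping samples. A chi-square
likelihood-ratio statistic tests H₀: θ_{j1} = … = θ_{jK}.

Main functions: `internal_data()`, `target_model()`, `working_model()` /
`summary_data()` / `summary_entry()`, `fit_plr_mle()`, `fit_polygim()`
(with `fit_irregular()` and `fit_rmle()` as explicit routes),
`heterogeneity_test()` / `pairwise_heterogeneity()`, `wald_summary()`,
`build_joint_sigma()` / `estimate_sigma0()`, and the simulation engine
`two_marker_design()` / `prs_design()` / `run_replication_study()`.
A command-line wrapper (`fit`, `het-test`, `simulate`) lives in
`inst/cli/polygim.R`.

## Worked example

Simulate the fully enumerable benchmark population (two correlated binary
biomarkers, two disease subtypes), fit an external grouped case-control
working model, and integrate its two reported coefficients:

```r
library(polygim)
set.seed(2026)
design    <- two_marker_design()
internal  <- sample_case_control(design)                       # 2000/500/500
external  <- sample_case_control(design, design$external_sizes) # 1000/600/400
summaries <- external_summary_from_data(external, design$working_models["GC2"])
fit <- fit_polygim(internal, summaries, design$target, policy = "optimal")
fit
#> polygim fit [GIM_opt]: K = 2, 6 parameters, loglik = 187.022
#>        term estimate      se       z   p_value p_bonferroni
#> 1      tau1  -0.5795 0.07096  -8.166 3.182e-16    1.273e-15
#> 2      tau2  -0.5260 0.07005  -7.509 5.941e-14    2.377e-13
#> 3 theta1.X1   1.6193 0.10603  15.272 1.168e-52    4.671e-52
#> 4 theta1.X2  -1.0745 0.09711 -11.065 1.854e-28    7.416e-28
#> 5 theta2.X1  -0.5820 0.10718  -5.430 5.636e-08    2.254e-07
#> 6 theta2.X2   1.4104 0.11513  12.251 1.668e-34    6.672e-34
heterogeneity_test(fit, "X1")
#> Subtype heterogeneity LRT: Lambda = 184.9979, df = 1, p = 3.929e-42
#>   common effect under H0: 0.5290
```

`theta1.X1 = 1.62` is the log odds ratio of marker X1 for subtype 1 versus
controls (truth 1.5); the heterogeneity test rejects because X1 truly acts
in opposite directions on the two subtypes (1.5 vs −0.5). Integrating the
external summary shrinks the standard errors relative to the
internal-data-only MLE — here by 9–17% per slope:

```r
mle <- fit_plr_mle(internal, design$target)
round(sqrt(diag(fit$cov_xi))[3:6] / sqrt(diag(mle$cov_xi))[3:6], 3)
#> theta1.X1 theta1.X2 theta2.X1 theta2.X2
#>     0.848     0.832     0.899     0.912
```

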