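---
title: "Random-regression gBLUP for longitudinal growth traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression gBLUP for longitudinal growth traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Image-based phenotyping platforms record traits such as projected shoot
area (PSA, the plant-pixel count summed over camera views, a proxy for
shoot biomass) on every plant on every day of an experiment. Genomic
prediction for such longitudinal traits can either ignore the longitudinal
structure — fit an independent "single time point" (TP) gBLUP model at each
imaging day — or model each line's whole trajectory. This package
implements the second option: a random-regression (RR) model in which every
line's additive-genetic deviation is a curve, parameterized by regression
coefficients on Legendre polynomials, with a covariance matrix over
coefficients estimated by REML against a marker-derived genomic
relationship matrix. The package also implements the TP baseline, the
derived heritability and genetic-correlation trajectories, and four
cross-validation scenarios including phenotype forecasting.

# Models

## Time standardization and the basis

Imaging days \(d\) are mapped linearly onto \(x \in [-1, 1]\) over a
declared *domain* \([d_{\min}, d_{\max}]\):
\(x = -1 + 2(d - d_{\min})/(d_{\max} - d_{\min})\). The domain is a
first-class argument rather than being implied by the observed days: a
forecasting fit uses only early days but declares a domain covering the
later evaluation days, so the fitted coefficient curves can be evaluated
there without polynomial extrapolation outside \([-1,1]\). Evaluation
outside the declared domain is an error (there is no silent
extrapolation). A degenerate single-day grid standardizes to 0.

The covariables are *normalized* Legendre polynomials
\(\phi_j(x) = \sqrt{(2j+1)/2}\, P_j(x)\), the covariance-function
convention of the animal-breeding literature; they are orthonormal under
the continuous inner product on \([-1,1]\) (the test suite verifies this by
Gauss–Legendre quadrature). Raw \(P_j\) are available behind a flag; the
TP model uses the raw order-0 basis (covariable exactly 1) so that its
coefficient variances are directly the per-day variance components.

## The random-regression model

For the record of line \(j\), experiment \(k\), day \(t\):
\[
y_{tjk} = \sum_{a=0}^{2}\phi_a(x_t)\beta_a
        + \sum_{a=0}^{n_g}\phi_a(x_t)u_{ja}
        + \sum_{a=0}^{n_s}\phi_a(x_t)s_{ka}
        + e_{tjk},
\]
with \(u \sim N(0,\, G \otimes \Omega)\), \(s \sim N(0,\, I \otimes P)\)
and \(e \sim N(0, D)\), where \(G\) is the VanRaden genomic relationship
matrix, \(\Omega\) is the \((n_g{+}1)\times(n_g{+}1)\) covariance of
genetic regression coefficients, \(P\) the experiment analogue, and \(D\)
is diagonal with either one variance per imaging day ("heterogeneous") or a
single variance. A separate overall intercept would be confounded with the
degree-0 fixed coefficient, so the mean is folded into \(\beta_0\) and
\(X\) stays full rank. Replicate plants within a line-by-experiment cell
share \(u_j\) and \(s_k\) and differ only in residuals; no
permanent-environment effect beyond experiment is modeled.

Genomic predictions at any day in the domain are
\(\widehat{g}_{jt} = \phi_t' \hat u_j\); per-day genetic variance is
\(\sigma^2_g(t) = \phi_t' \Omega\, \phi_t\) (experiment analogously), the
genetic correlation between days \(i\) and \(j\) is
\(\phi_i'\Omega\phi_j / \sqrt{(\phi_i'\Omega\phi_i)(\phi_j'\Omega\phi_j)}\),
and
\(h^2(t) = \sigma^2_g(t) / (\sigma^2_g(t)+\sigma^2_s(t)+\sigma^2_e(t))\).
The experiment variance is deliberately part of the denominator — the
experiment term is treated as an environmental effect; other heritability
definitions exclude design effects, so the choice is documented here.

## The genomic relationship matrix

\(G = Z_{cs}Z_{cs}'/m\) with per-marker centering by \(2\hat p_j\) and
scaling by \(\sqrt{2\hat p_j(1-\hat p_j)}\), \(\hat p_j\) the observed
allele frequency. "Centered and scaled" is ambiguous between this and
VanRaden's method 1 (overall scaling); per-marker scaling is the default
and method 1 is an option. Missing dosages are mean-imputed per marker
(with a reported count); monomorphic markers are dropped. Negative
eigenvalues of \(G\) (numerical noise from the centering null space) are
clamped to zero and the eigen pair is stored on the object — the solver
consumes \(G\) only through symmetric square roots, so a singular \(G\) is
handled exactly rather than being jittered into positive definiteness.

# REML estimation

Variance components maximize the restricted likelihood by
average-information (AI) REML with two safeguards:

* **Prior-whitened mixed-model equations.** With
  \(\Sigma = \mathrm{blockdiag}(G\otimes\Omega,\ I\otimes P) = LL'\)
  (symmetric square roots, Kronecker-factored), the working system is
  \(\hat C = [X,\ WL]'R^{-1}[X,\ WL] + \mathrm{diag}(0, I)\). This never
  forms \(\Sigma^{-1}\): when \(\Omega\) or \(P\) approaches the boundary
  of the PSD cone (rank-deficient optima are common in covariance-function
  models), \(\hat C\) remains well conditioned and the identity
  \(\log|\Sigma| + \log|C_{\mathrm{MME}}| = \log|\hat C|\) keeps the
  likelihood exact — a naive \(\Sigma^{-1}\)-based implementation loses the
  likelihood to catastrophic cancellation exactly where model selection
  needs it most. The restricted likelihood includes \(+\tfrac12\log|X'X|\)
  so that its value is invariant to any full-rank reparameterization of
  the fixed effects (and the TP and RR parameterizations of the same
  single-day model give the same value).
* **Monotone stepping.** An AI step that fails to increase the likelihood
  or leaves the parameter space is retried with Levenberg–Marquardt
  damping (a growing ridge bends the step toward the gradient); if all
  damped steps fail, a monotone EM step is taken. Convergence requires the
  likelihood change to fall below `tol_loglik` (default 1e-6) and either
  the relative parameter change to fall below `tol_par` (default 1e-6) or
  the likelihood to have been flat for three consecutive iterations
  (parameters can slide along a likelihood-flat ridge indefinitely without
  affecting any reported quantity). For small parameter counts a final
  polish by direct optimization over Cholesky factors follows, because
  Cholesky coordinates move smoothly *along* the PSD boundary where
  projected AI/EM steps stall.

All trace terms reduce to strided diagonal-block sums of \(\hat C^{-1}\)
and the AI matrix costs one extra multi-right-hand-side triangular solve,
so one iteration is a handful of dense factorizations of dimension
\(p + n(n_g{+}1) + n_e(n_s{+}1)\) (about 1,080 for the full 357-line
study); a full fit takes seconds to a few tens of seconds on one CPU.

Lines present in \(G\) but without phenotypes contribute nothing to the
restricted likelihood, so the solver fits on the phenotyped subset and
propagates their coefficient BLUPs through \(G\) afterwards
(\(\hat u_{\mathrm{new}} = G_{\mathrm{new},s} G_{s,s}^{-} \hat u_s\), the
standard gBLUP treatment of unphenotyped selection candidates — exact, and
much cheaper than carrying them in the equations). This is how every
cross-validation scenario predicts its test lines: their phenotypes never
enter the design, the REML iterations, or the right-hand sides (a sentinel
test asserts this).

## Model selection

Candidate structures are ranked by \(\mathrm{AIC} = -2\ell_R + 2k\) where
\(k\) counts *free covariance parameters only*
(\(\Omega\): \(q(q{+}1)/2\); \(P\) likewise; \(D\): \(t\) or 1) — the
REML-based convention; fixed effects are excluded and the count is
recorded on the fit so other conventions can be compared. The default
grid crosses genetic order \{1, 2\}, experiment order \{0, 1\} and
residual \{homogeneous, heterogeneous\} (8 models). Fits that do not
converge are ranked last and flagged rather than silently dropped.

# The synthetic-data generator

The generator emulates the design of a rice diversity-panel greenhouse
study: 357 lines (2,000 markers by default; 33,674 supported), three
experiments, 54 randomly chosen lines duplicated per experiment, 20
consecutive daily time points, and a kilopixel-scale PSA-like trait.
Genetic coefficient curves are drawn with covariance
\(G \otimes \Omega_{\mathrm{true}}\) from the marker-derived \(G\) itself
(the gBLUP equivalence the analysis relies on), not from explicit marker
effects; experiment curves from \(P_{\mathrm{true}}\); residuals are
day-specific with standard deviation proportional to the mean curve plus a
floor, giving the heteroscedasticity the heterogeneous-\(D\) model is
meant to capture.

The calibrated defaults are a frozen fixture
(`inst/extdata/sim_defaults.json`), chosen once and not re-derived at run
time:

* mean curve \(60 \to 305\) kilopixels over the 20 days, increasing and
  convex, high enough above zero that the positivity of the trait truncates
  less than 0.5% of records on any day (the additive Gaussian model is only
  faithful away from zero);
* \(\Omega_{\mathrm{true}}\) from projecting a target covariance (genetic
  sd proportional to the mean with a floor, squared-exponential
  correlation in standardized time) onto the quadratic basis — implied
  per-day \(h^2\) 0.62–0.68 and genetic correlations 0.91–1.00 with
  adjacent days closest to 1;
* an experiment-effect sd growing linearly from 4 to 25 kilopixels;
* residual sd \(= 0.169\,(\mathrm{mean}(t) + 15)\).

All three eigendirections of \(\Omega_{\mathrm{true}}\) carry variance
(4293, 52, 0.4), so the generating order-2 structure is genuinely
identifiable — a design requirement for the model-selection analysis to be
meaningful, checked at calibration time.

What the generator does **not** emulate: linkage disequilibrium and
pedigree structure (markers are independent binomial draws; an optional
two-subpopulation Balding–Nichols mode adds coarse stratification only),
image segmentation artifacts and outlier plants, missing days, seasonal
covariates, and genotype-by-experiment interaction beyond the additive
experiment curves. Passing recovery tests on this generator therefore
shows the estimation machinery is correct under the model's own
assumptions — not that the model is adequate for any particular real
data set.

# Cross-validation scenarios

Lines are halved at random; with 357 lines the leftover line joins the
training set of both folds (training 179 / test 178). Accuracy at a day is
the Pearson correlation between predicted gBLUPs and observed phenotypes
over test lines, computed within each experiment (replicates averaged
first), averaged over experiments, then over the two folds; resample
\(i\) uses seed \(\texttt{base\_seed} + i - 1\) and results are bitwise
reproducible.

* **A** — train on all days for training lines, predict all days for test
  lines; available for both RR and per-day TP models.
* **B** — a single sampled half of the lines, fitted on days 1–10,
  predicts the *same* lines on days 11–20 (no folds, matching the
  sampled-half design of this scenario).
* **C** — training lines' days 1–10 predict *test* lines' days 11–20.
* **D** — training lines' full first-study window predicts test lines in
  a second study at later days; the basis domain spans both studies'
  day ranges so evaluation stays inside \([-1,1]\].

The per-day TP model cannot forecast days without data, so scenarios B–D
are RR-only and asking for TP there is an error rather than a silent
fallback. Published descriptions of such designs vary between 10 and 20
resampling rounds; the default here is 20 and every driver sets it
explicitly.

# Numerical and design choices

* Outlier screen: per-day quartiles with linear interpolation between
  order statistics (R's default type-7 quantiles, stated because the
  1.5 IQR rule is convention-sensitive); flagging is advisory and removal
  is a separate explicit call, mirroring workflows where flagged plants
  are reviewed before exclusion.
* Phenotypic correlations between days are pairwise-complete Pearson
  correlations over plants, tolerating missing days.
* Mixed-model equation solutions are checked against their right-hand
  side (relative residual below 1e-8) and the scaled gradient at the
  optimum is recorded on every fit. The raw gradient only vanishes at
  *interior* optima; when the estimate lies on the PSD boundary
  (rank-deficient \(\Omega\)) the honest stationarity check is that a
  restart from the reported optimum gains nothing, and that is what the
  tests assert.
* Degenerate inputs: zero variance at a day, all-zero variance
  components, zero genetic variance in a correlation — all return `NA`
  with a warning rather than an error or a silent number.

# Problem sizes used in the tests

The suite validates statistical correctness at sizes chosen for a
single-CPU run: oracle equivalence on a 5-line, 3-day instance against an
independent dense-likelihood maximizer; covariance recovery on 20
replicates of a 300-line, 2,000-marker study; model-grid self-selection on
20 replicates at 110 lines; scenario orderings at 100 lines with shared
seeds. The thresholds (relative RMSE of \(\Omega\) below 25%, mean
heritability within ±0.05 per day, the generating structure winning the
AIC grid in at least 80% of replicates, and the B > C and RR ≥ TP
accuracy orderings) are the package's accuracy contracts.

# Known limitations

* Single trait; no multi-trait or genotype-by-environment covariance
  functions.
* Bayesian and marker-effect (SNP-BLUP) formulations are out of scope.
* B-splines and other covariance-function families are not implemented.
* Confidence intervals on variance trajectories are not provided.
* The AI-REML iteration count grows when a fitted structure is badly
  misspecified for the data (likelihood ridges); such fits end flagged
  rather than silently truncated.
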