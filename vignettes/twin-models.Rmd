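---
title: "Longitudinal twin variance-component models with twinpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal twin variance-component models with twinpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
library(dplyr)
```

## The scientific problem

Twin designs decompose individual differences in a phenotype — here
motivated by MRI-based *predicted brain age* (PBA) and the *predicted
brain age difference* PBAD = chronological age − PBA — into additive
genetic (A), shared environmental (C) and non-shared environmental (E)
sources, by contrasting monozygotic (MZ) and dizygotic (DZ) twin pairs.
MZ pairs share all their segregating genes, DZ pairs on average half, so
the cross-twin covariance of additive genetic effects is weighted 1.0 for
MZ and 0.5 for DZ pairs; shared environment is by assumption fully
correlated within pairs in both groups, non-shared environment (which
absorbs measurement error) is uncorrelated.

Longitudinally, the interesting question is not just *how heritable* the
phenotype is at each age, but *whether the same influences act across
ages*. Four competing covariance structures formalize the alternatives:

* **Correlated factors (Cholesky)** — the atheoretical reference: per
  component, a full lower-triangular path matrix; free variances and
  covariances among the T age-interval variables. Every other model is a
  constrained special case.
* **Autoregressive simplex** — age-specific innovations transmitted from
  occasion to occasion by regression coefficients β: influences
  *accumulate*.
* **Common pathway** — one (or two) latent phenotypic factor(s), each
  with unit total variance split into A and E (and optionally C) parts,
  loading on every occasion, plus occasion-specific A/E residuals: a
  *stable latent phenotype*.
* **Independent pathway** — separate common A and E factors loading
  directly on occasions, plus residuals.

All models are path-parameterized (variances are squares of free paths),
so every implied component matrix is positive semi-definite by
construction and no inequality constraints are needed; path signs are not
identified and reported quantities are squares or absolute values.

## Age anchoring and preprocessing

Assessment waves in midlife cohorts are irregularly timed and their age
ranges overlap (the emulated design: three waves at mean ages 56.1, 61.8
and 67.5 years, SD 2.6 each). Wave-based longitudinal modeling would
confound age with occasion, so scores are *age-anchored*: re-coded to the
chronological-age interval (51–55, 56–60, 61–65, 66–72; membership by
completed years, so 55.9 falls in 51–55) that contains the assessment
age. A subject assessed twice inside one interval contributes only the
first (earliest-wave) observation; `age_anchor()` tallies kept and
dropped records. With three waves no subject can cover four intervals —
the resulting structured missingness is deliberate and handled by FIML,
never by listwise deletion.

Before modeling, each interval variable is residualized by
individual-level OLS on scanner (1.5T at wave 1 vs 3T later), age at
assessment (centered within interval), ethnicity and birth-year cohort.
Residualization is per interval variable with both twins pooled as
individuals; family clustering is ignored at this stage because only
means are adjusted. Covariates that are constant inside an interval
(e.g. scanner in an interval reachable from a single wave) are absorbed
by the intercept and dropped; genuinely collinear terms raise an error.
Whether such residualization should pool intervals instead is not
settled; per-interval adjustment was chosen because interval membership
itself determines which scanner/age mix a variable sees. A consequence,
inherited by any analysis of residualized scores, is that interpretable
mean and variance trajectories are lost — which is why latent
growth-curve models are out of scope here.

## The FIML engine

Each twin pair is one observation of a 2T-variate normal with mean
`rep(μ, 2)` (T free means, equal across twins and zygosity — the
standard assumption the MZ/DZ contrast requires; after residualization
they are ≈0 but left free) and covariance

$$\Sigma_z \;=\; \begin{pmatrix}\Sigma_A+\Sigma_C+\Sigma_E &
r_{A,z}\,\Sigma_A+\Sigma_C\\ r_{A,z}\,\Sigma_A+\Sigma_C &
\Sigma_A+\Sigma_C+\Sigma_E\end{pmatrix},\qquad r_{A,\mathrm{MZ}}=1,\;
r_{A,\mathrm{DZ}}=0.5 .$$

The raw-data likelihood sums each pair's observed-subvector density
(rows/columns of missing entries deleted). Internally pairs are grouped
by zygosity × missingness pattern and the deviance is evaluated from each
group's count, mean and scatter, making one evaluation's cost independent
of sample size. Implied submatrices that fail a Cholesky factorization
return a large finite penalty so optimizers recover gracefully.

Optimization uses bounded quasi-Newton (`nlminb`) from multiple start
points: the first start is deterministic (path starts scaled to the
observed variance, means at observed variable means), the rest are seeded
jitters. The default is 10 starts because simplex and common-pathway
deviance surfaces can be multimodal; the simulation loops in the tests
and the acceptance script use 1–3 starts for the univariate and
common-pathway fits after verifying (by comparing 1-start against
6-start refits across 100 replicates) that those surfaces are effectively
unimodal at the sizes used. Convergence tolerance is `rel.tol = 1e-8` on
the deviance; refitting from a solution reproduces it to well below that.

## Identification choices

* **Common pathway**: the latent factor's total variance is fixed to 1 by
  deriving its E path as $\sqrt{1-f_a^2-f_c^2}$, so the squared factor
  paths *are* the standardized factor decomposition (a "74% genetic
  factor" is read directly off `fac_a1²`). The first loading of each
  factor is non-negative, and a second factor does not load on the first
  variable.
* **Independent pathway**: first loading of each common factor
  non-negative.
* **Autoregressive simplex**: with free per-occasion residual variances
  the model is locally unidentified — the first and last occasions'
  innovation and residual variances enter the likelihood only through
  their sums (the numeric Jacobian of the moment map loses rank 2). That
  overstates likelihood-ratio df against the reference model and made
  simplex-generated data reject the simplex in ~23% of replicates at a
  nominal 5% level. The default model therefore constrains the occasion
  residual variance equal across occasions (one `res_e` path), the
  standard remedy for simplex measurement models;
  `equal_residuals = FALSE` restores the free-residual variant for
  sensitivity analyses. Occasion residuals are E-only by default (they
  absorb measurement error); genetic residual chains remain expressible
  through the A innovations.
* **β coefficients** are free per transition and per chain; equality
  across chains can be imposed with `fix_parameters()`.

## Inference

Likelihood-ratio tests use a central chi-square reference with df equal
to the difference in counted free parameters — the convention of the
twin-modeling literature. For variance components tested at their
boundary (dropping C, dropping a residual A path) the central reference
is conservative; the simulations below confirm rejection at or below the
nominal level. AIC is `−2lnL + 2k` on the raw deviance, with ties broken
toward fewer parameters.

Profile-likelihood 95% CIs locate the points where the profiled deviance
rises 3.841 above its minimum, re-optimizing all other parameters:
exactly (by reparameterization) for univariate standardized components
and the common-pathway factor share, by fixing-and-refitting for named
parameters, and by a quadratic-penalty profile (weight 10⁶) for arbitrary
smooth functions of the parameters. Bounds for standardized quantities
are clipped to [0, 1] and flagged when the deviance never reaches the
critical rise before the boundary.

### Model selection

The pipeline mirrors the conventional decision sequence: fit the
correlated-factors reference, test AR / CP1 / CP2 / IP against it by LRT;
candidates that deteriorate significantly are eliminated. Among the
survivors, one further filter is applied before the AIC ranking: when one
surviving candidate is nested inside another (CP1 inside CP2, and CP1
inside IP — proportional independent-pathway loadings reproduce a common
pathway exactly) and the LRT between them is non-significant, the more
complex model leaves the race. Without this parsimony step the selection
of a true CP1 over IP is capped at $P(\chi^2_3<6)\approx0.89$ no matter
how much data is available, because IP's three extra parameters buy an
expected deviance improvement of 3 against an AIC penalty of 6 — an AIC
coin-flip in the tail. Preferring the nested model when its constraint is
not rejected is standard structural-equation practice and matches the
narrative logic of eliminating models by LRT before adjudicating the rest
by AIC. Within the winning class, whole components are dropped
(ACE → AE / CE / E) and kept if the LRT against the winner is
non-significant with the lowest AIC; finally, per-variable residual
genetic paths are dropped stepwise (largest p first) while the drop stays
non-significant.

## The synthetic cohort generator

Because the motivating study's registry data are available only on
request, the package ships a generator that emulates the *design*, not
the data: three waves at the means/SDs/ranges above (ages drawn from
truncated normals, identical within a pair — twins share a birth year),
per-wave participation probabilities (default 1 / 0.8 / 0.65, independent
across twins and waves; within-pair correlated attrition is not modeled),
a configurable number of pairs with one twin entirely absent, a scanner
shift after wave 1, an ethnicity mixture (88.3 / 5.3 / 3.4 / 3.0%) with
configurable phenotype shifts, and a birth-year gradient over 1943–1955.
Default pair counts (150 MZ + 150 DZ complete + 30 incomplete) are of the
order of a single-registry MRI twin sample. Phenotypes are the latent
interval-level twin values drawn from any chosen generating model, plus
the covariate effects; a subject whose waves land in one interval twice
produces a duplicate measurement, exercising the first-observation rule.

What passing tests on these simulations do *not* show: robustness to
non-normal phenotypes, to informative (phenotype-dependent) attrition, to
within-pair age differences, or to scanner effects that alter variances
rather than means. The generator is multivariate-normal by construction,
matching the likelihood's assumptions.

## Problem sizes used in the tests and acceptance script

Simulation sizes were chosen so that Monte-Carlo error is small relative
to the tolerance being asserted while the whole suite stays quick:
moment-recovery checks use 10,000–20,000 pairs; univariate parameter
recovery uses 50 replicates of 2,000 + 2,000 pairs in the acceptance
script (12 in the test suite); common-pathway factor recovery 25
replicates of 1,500 + 1,500 (8 in the suite); CI calibration 500 replicates of
300 + 300 (binomial SE ≈ 1 point at 95% coverage); selection consistency
100 replicates of 300 + 300 pairs against the AR / IP / CF competitor
set, and 40 simplex-generated replicates for the converse check. Stated
agreement bands are 3 Monte-Carlo SEs for recovered parameters and ±3
points for coverage.

## Known limitations

* Continuous-normal likelihood only: no ordinal-threshold FIML (the
  polyserial routine serves correlation tables, not model fitting).
* No definition-variable (continuous-age) modeling; anchoring to
  intervals is a design choice inherited from the emulated study.
* No growth-curve or hybrid simplex–common-factor models.
* LRTs on boundary parameters use the naive central reference by
  default (a chi-bar-square mixture is available via
  `lrt(..., boundary = TRUE)` but kept off so decisions remain
  comparable with the conventional practice the package reproduces).
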