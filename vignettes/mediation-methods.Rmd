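---
title: "Methods: recursive logit systems, effect decomposition, and the synthetic survey generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recursive logit systems, effect decomposition, and the synthetic survey generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsemmediate)
```

## The statistical model

`gsemmediate` fits a generalized structural equation model of a specific,
common shape: a **recursive** system of regression equations with logit
links over fully observed categorical (and one continuous) survey
variables. Each endogenous variable — the binary outcome and every
mediator — has exactly one equation:

* a Bernoulli response uses a binary logit,
  $\operatorname{logit} P(Y=1\mid X) = X\beta$;
* a polytomous response uses baseline-category multinomial logits,
  $\log\frac{P(Y=k)}{P(Y=\text{base})} = X\beta_k$, $k = 1,\dots,K-1$,
  fit jointly.

Because the predictor-to-response graph is acyclic, every variable is
observed, and the equation residuals are independently specified, the
joint likelihood factorizes into the product of per-equation
likelihoods. Equation-by-equation maximum likelihood therefore *is*
joint maximum likelihood; no joint optimizer is needed, and the system
log-likelihood is the sum over equations. This factorization is the core
estimation decision of the package, and it is also why the diagram
validator insists on acyclicity ("not recursive" errors) rather than
attempting anything more general.

Mediation chains deeper than exposure → mediator → outcome are rejected
at diagram-build time with an "unsupported chain depth" error. The
shipped application has no mediator-of-mediator edges, and silently
enumerating only part of a deeper structure would misreport totals; a
hard error is the safer contract.

### Missing data

Each equation is fit on its own complete cases (listwise deletion
*within* an equation, not across equations). In surveys where some
questions are asked only of a subsample, this makes the per-equation
sample sizes differ by design: in the shipped application the outcome
equation keeps roughly 12% of records (its predictors include two
subsample-only variables) while the mediator equations keep all of them.
The source analysis does not describe its missing-data handling
explicitly; per-equation complete-case analysis is the inference that
reproduces its two distinct printed sample sizes, and we flag it here as
an inference rather than a stated fact.

## Effect decomposition

With path coefficients on the log-odds scale:

* **Direct** effect of an exposure term: its coefficient in the outcome
  equation, with Wald standard error and normal-based 95% interval
  ($z = 1.959964$) and two-sided normal $p$.
* **Indirect** effect along exposure → mediator level → outcome: the
  product $ab$ of the exposure's coefficient in the mediator equation
  (at that mediator contrast) and the mediator-level indicator's
  coefficient in the outcome equation. The standard error is the
  first-order delta method without the covariance term,
  $\sqrt{b^2\operatorname{Var}(a) + a^2\operatorname{Var}(b)}$ — the two
  coefficients come from different equations, whose estimates are
  treated as independent. The exact product-variance formula adds
  $\operatorname{Var}(a)\operatorname{Var}(b)$; for survey-scale
  standard errors the difference is far below reporting precision, and
  the first-order form matches the behaviour of standard nonlinear-
  combination post-estimation tools, so it is what we report.
* **Total** effect: direct plus the included indirect products. Its
  delta-method variance uses the gradient of the sum of products, with
  within-equation covariances included (the direct coefficient and all
  $b$'s share the outcome equation; two paths through the same
  multinomial mediator share that equation) and cross-equation
  covariances fixed at zero. Equations fit on overlapping data are not
  exactly independent, so this is an approximation; it is stated in the
  output rather than hidden.
* **Odds ratios**: `to_odds_ratio()` exponentiates the estimate and the
  interval endpoints and carries the $p$-value over unchanged.

### Two total-effect conventions

`effect_table(..., total = "per_row")` (default) reports one total per
combination of *one contrast from each* mediator equation containing the
exposure: for an exposure mediated only by a 4-level mediator that is
three rows (one per non-baseline level); for an exposure entering two
mediator equations it is the cartesian product of their contrasts. This
is the convention of per-mediator-level reporting rows in published
tables, verified arithmetically against them. `total = "grand"` instead
adds *all* indirect paths to the direct effect, which is what a prose
definition of "total = direct + indirect" describes. Both are exposed
because the two readings give different numbers whenever a mediator has
more than one non-baseline level.

### Reporting conventions

Estimates are kept unrounded internally; display rounds path
coefficients and effects to 3 decimals and odds ratios to 2. Pipeline
artifacts are written unrounded with a `_display` variant rounded this
way. No multiple-testing adjustment is applied (none is applied in the
emulated analysis).

Reconstructing the decomposition from a *published* coefficient table
(`system_fit_from_coefficients()`) back-derives standard errors from the
printed 95% limits, $(\text{hi}-\text{lo})/(2 \times 1.959964)$, and has
no within-equation covariances (diagonal covariance); point estimates of
indirect and total effects are unaffected, and interval widths for
totals are then approximations. Two cells of the shipped published table
are internally inconsistent with the product of their own printed
factors (a schooling-by-contraception indirect, and by propagation one
schooling total); we treat these as source rounding/typos, and the test
suite checks reconstruction of every other printed value to ±0.002.

## Numerical estimation

The Newton–Raphson fitter is deliberately contract-first:

* start at $\beta = 0$; full Newton step from the observed information
  (which equals the expected information under the canonical logit
  link), with step-halving (up to 20 halvings) so the log-likelihood is
  non-decreasing across iterations;
* convergence when the score max-norm is ≤ 1e-8 *or* the relative
  log-likelihood change is ≤ 1e-10; at most 100 iterations;
* any iterate with $|\beta_j| > 15$ on the log-odds scale raises a
  separation error — 15 is far outside any plausible survey effect, so
  this catches complete/quasi-separation early without a specialized
  test;
* rank-deficient designs raise an error naming the collinear columns;
  a constant response is reported as degenerate rather than ground
  toward $\pm\infty$;
* covariance is the inverse observed information at the final iterate.

Frequency weights are accepted for aggregated (synthetic) data only; the
analysis itself is unweighted. The emulated survey analysis likewise did
not incorporate its design weights, on the argument that at its sample
size the bias of unweighted estimates is negligible; emulating the
two-stage sampling design is out of scope here.

Descriptive statistics make three documented choices: Pearson
chi-squared without continuity correction (the general R×C test),
quantiles by linear interpolation (type 7), and the rank-sum test with
mid-ranks and the tie-corrected normal approximation. Each descriptive
block uses its own pairwise complete cases, so denominators vary across
blocks exactly as they do in survey descriptive tables.

## The synthetic survey generator

`default_scenario()` emulates the structure the analysis assumes, not
the full survey:

* **Exogenous margins** are derived from the bundled published
  cross-tabulated counts; variables asked only of a subsample use the
  margins among observed respondents. Exogenous covariates are drawn
  **independently** — there is no wealth × schooling copula, a stated
  simplification: all exposure–outcome association flows through the
  declared equations. Consequently, passing recovery tests shows the
  estimator and decomposition are correct under the model, not that the
  model captures real-survey dependence among exposures.
* **Schooling** (the sole continuous variable) is a discrete mixture on
  0–17: mass 0.28 at zero, uniform weight 0.035 on 1–12, extra masses
  0.10 at 8 and at 10, and 0.02 on 13–17 — chosen once to match the
  published median 7–8 and IQR (0, 10).
* **True coefficients** default to the published point estimates, with
  unlisted terms zero. **Intercepts** are not published anywhere, so
  they are calibrated deterministically at scenario-build time: the
  expected category probabilities are computed by *exact enumeration*
  over the discrete covariate lattice (marginalizing mediators through
  their already-calibrated equations), then solved by bisection (binary
  equations) or an IPF-style fixed point on the intercept vector
  (multinomial equations) to hit the target margins — screening
  prevalence ≈ 21% and the published mediator margins. No Monte Carlo
  enters calibration, so it is seed-independent; it is memoized for the
  default scenario.
* **Missingness**: the two subsample-only variables (autonomy, sex
  partners) share a single module non-response indicator with
  probability 0.88. A shared indicator — not independent per-variable
  masking — is what reproduces an outcome-equation complete-case
  fraction of ≈ 0.118; independent masking at the observed per-variable
  rates would leave only ≈ 1.6% of rows, contradicting the emulated
  analysis's sample sizes.
* **Reproducibility**: one seeded Mersenne–Twister stream per
  generation; identical scenarios produce byte-identical CSVs, and the
  caller's RNG state is saved and restored.

The mediator-equation predictor sets are exactly those with published
coefficients (religion + schooling for contraception; wealth + religion
for children; schooling for STI awareness). Whether further covariates
entered those equations in the source analysis is ambiguous; we use
exactly the published sets and note the ambiguity here.

## Problem sizes used in the test suite

The suite exercises the stochastic claims at sizes chosen to balance
Monte-Carlo resolution against a single-CPU run of a few minutes:
parameter recovery and decomposition closure on one generated population
of n = 200,000 (every generating coefficient with magnitude ≥ 0.1
recovered within 3 standard errors; every implied product indirect
effect within 3 delta-method standard errors); Wald-interval coverage
over 100 replicates at n = 20,000 (accepted band 90–99 of 100);
realized margins at n = 500,000 (within half a percentage point of
target); delta-vs-bootstrap agreement with 10,000 parametric draws
(within 10%). Closed-form oracles (saturated 2×2 and 2×3 tables,
entropy log-likelihoods, rank-sum and chi-squared hand computations) are
exact to stated numerical tolerances.

## Known limitations

* No latent variables, ordinal/probit links, interactions, or
  mediator-of-mediator chains.
* Counterfactual (natural direct/indirect) effect definitions on the
  probability scale are out of scope; effects are products and sums of
  path coefficients on the log-odds scale.
* Cross-equation coefficient covariance is approximated as zero for
  interval construction.
* No survey weights, clustering, or robust standard errors.
* The generator's independence of exogenous covariates understates
  real-survey confounding among exposures; results on synthetic data
  validate the machinery, not the substantive survey conclusions.
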