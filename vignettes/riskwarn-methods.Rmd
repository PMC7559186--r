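---
title: "Methods: probabilistic food-quality-safety risk early warning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic food-quality-safety risk early warning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskwarn)
```

## The model

`riskwarn` estimates the overall food-quality-safety risk of a processing
enterprise as a random variable

$$\Phi = \sum_{i=1}^{n} w_i\,\mu_i,$$

where the $\mu_i$ are leaf-level risk inputs (one per indicator in a risk
index tree) and the $w_i$ are their global importance weights. Each $\mu_i$
is modelled by a parametric distribution fitted to data on a common
dimensionless 0–100 risk scale, the $w_i$ come from expert pairwise
comparisons, and the distribution of $\Phi$ is obtained by Latin hypercube
Monte Carlo. Early warning is then a tail statement: the probability that
$\Phi$ exceeds an enterprise limit (e.g. 70) or an ideal value (e.g. 40).

The default index tree has a single target node, three first-level indices
(external environmental risk, internal environmental risk, consumer-concern
risk) and twelve leaf indicators; arbitrary trees are supported.

## Expert weighting (AHP)

Each expert supplies, per internal node, a reciprocal pairwise-comparison
matrix on the Saaty nine-point scale $\{1/9,\dots,1,\dots,9\}$. Local
weights are the normalized principal right eigenvector, computed by power
iteration from the uniform vector (tolerance $10^{-10}$, at most $10^4$
iterations). Consistency is screened with
$CR = \frac{\lambda_{\max}-n}{(n-1)\,RI_n}$ using the standard random-index
table $RI = (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)$ for orders
1–9; experts with $CR > 0.1$ are excluded (both values are the universal
AHP conventions; the threshold is configurable). Orders 1–2 are consistent
by construction, so $CR = 0$ there.

Included experts are combined per component by the weighted geometric mean
$w_j' = \prod_k (w_j^{(k)})^{\lambda_k}$ with $\lambda$ uniform over the
included panel by default, then renormalized. The geometric mean (rather
than arithmetic) keeps the aggregate consistent under reciprocal
comparisons. Global leaf weights are the chain product of layer composition
matrices, $w^{(k)} = U^{(k)} U^{(k-1)} \cdots U^{(3)} w^{(2)}$, with zero
entries where a child is not dominated by a parent; leaves reached before
the deepest layer are carried through with weight preserved, so the global
vector always sums to one.

## Fuzzy scoring of detection data

Hazard measurements (drug residues, heavy metals, microbial counts, metal
fragments, …) are heterogeneous in unit and magnitude, so each hazard
carries a five-level warning ladder $q_1 < \dots < q_5$ and the level
weights $T = (10, 30, 50, 70, 90)$. A measurement $x$ is assigned triangular
partition-of-unity memberships: full membership in level 1 at or below
$q_1$, full membership in level 5 at or above $q_5$, and for
$q_j < x < q_{j+1}$

$$h_j = \frac{q_{j+1}-x}{q_{j+1}-q_j}, \qquad h_{j+1} = 1 - h_j,$$

all other components zero. The score $RV = \sum_j h_j T_j$ is then
continuous and piecewise linear in $x$, equals $T_j$ exactly at each anchor,
and is non-decreasing for any valid ladder. (The interpolation is written in
this form deliberately: it is the only reading under which the memberships
sum to one and the score is continuous; naive alternatives with the
denominator $q_j - q_{j+1}$ reverse sign mid-interval.) A per-hazard
direction flag covers indicators where lower measurements are worse.

The shipped ladders are placeholders: the real cut-offs are
jurisdiction-specific regulatory limits (veterinary-drug MRLs, pesticide
MRLs, metal-detection standards) that the user must edit into the config.

## Questionnaire elicitation

Indicators without measurement histories (policy risk, management quality,
consumer concerns, …) are elicited as probability–impact pairs: probability
of occurrence $p \in [0,1]$ and impact $E \in [0,10]$, giving
$RV = p \times E$. Raw $pE$ lives on $[0,10]$ while fuzzy scores live on
$[10,90]$; we multiply by 10 (the `questionnaire_scale_factor` option) so
that both input families share a 0–100 scale — otherwise
questionnaire-driven indicators would be structurally down-weighted by an
order of magnitude relative to detection-driven ones.

Instrument reliability is summarized by Cronbach's
$\alpha = \frac{K}{K-1}\bigl(1 - \sum_k s_k^2 / s_T^2\bigr)$. Because a
single published $\alpha$ for such an instrument could refer to the $p$
items, the $E$ items, or the derived $RV$ items, the report computes and
labels all three. Validity screening applies three toggleable rules —
missing fields, out-of-range values, straight-lining — since the criteria
that make a questionnaire "invalid" in practice are rarely published.

## Distribution fitting

Seven candidate families are fitted by maximum likelihood: BetaGeneral
(a beta rescaled to support $[\min,\max]$, parameters
$(\alpha_1, \alpha_2, \min, \max)$), Normal, Lognormal, Gamma, Weibull,
Triangular and Uniform. Closed forms are used where they exist; Gamma and
Weibull use Nelder–Mead on log parameters from moment-matched starts with
deterministic restarts (restart jitters never touch the global RNG, so a
seeded pipeline is bit-reproducible regardless of prior RNG state).

**Bounded-support families need care.** The BetaGeneral likelihood is
unbounded along the ridge where $\max \to \infty$ and $\alpha_2 \to \infty$
jointly (the rescaled beta degenerates to a gamma), and the support-bound
MLE is non-regular. The default therefore profiles the bounds over a grid of
margins around the sample range (fractions
$0.001 \dots 2$ of the range), maximizes the two shapes inside each
candidate support, and finally polishes all four parameters with the margins
box-constrained to at most twice the sample range. The cap is an explicit
regularization choice, not an optimizer artifact. Even so, users should
expect $(\alpha_2, \max)$ to carry large sampling error: in our seeded pilot
studies at $n = 5000$ from BetaGeneral(3.6, 23.1, 6.4, 126.4), the median
error was ≈8% for $\alpha_1$ and ≈0.4 units for $\min$, but ≈20–30% for
$\alpha_2$ and ≈15–35 units for $\max$ — and alternative estimators (joint
MLE, four-moment matching, maximum product of spacings) did no better. The
acceptance suite asserts the stricter 15% target for both shapes and is
deliberately left failing for $\alpha_2$ rather than silently widened; the
unit suite guards the pilot-measured levels. Functionals of the fitted
distribution on the data range (mean, cdf values, quantiles) are far more
stable than the ridge-coupled parameters themselves.

Goodness of fit uses the chi-square test with equal-probability binning
under the fitted model: 33 bins by default, expected count floor 5, and
$df = \text{bins} - 1 - \#\text{params}$, so the four-parameter BetaGeneral
gets $df = 28$ (critical value 41.3371 at $\alpha = 0.05$). Candidates are
ranked by the chi-square statistic ascending with AIC as tie-break, and
P–P/Q–Q diagnostics use plotting positions $(i - 0.5)/n$.

## Latin hypercube simulation

For each input independently, the unit interval is cut into $N$
equiprobable strata, one uniform is drawn per stratum, the strata are
permuted, and the stratified uniforms are pushed through the input's
quantile function; inputs are mutually independent (inter-input dependence
is a documented non-goal — no copulas). Stratification is exact for every
$N$ by construction, which the tests assert directly. Default
$N = 10{,}000$; the full sample path is fixed by the seed.

Interval probabilities use the $[\text{lo}, \text{hi})$ convention (the
choice has measure zero for continuous inputs). The warning trigger defaults
to $P(\Phi > t) > 0.001$ rather than comparing the simulated maximum to the
threshold: the sample maximum is an unstable, $N$-dependent statistic, but a
`trigger_mode = "max"` option reproduces the extreme-value convention.

## Sensitivity and scenario analysis

Inputs are ranked by the absolute Spearman rank correlation of their sampled
values with $\Phi$ (the convention of spreadsheet risk tools; Pearson via
`method = "linear"`). Rank correlation makes the ranking invariant to
strictly monotone transformations of any input. Scenario analysis conditions
on $\Phi \ge$ a target and flags inputs whose conditional median shifts by
more than 0.5 unconditional standard deviations (configurable; the published
analyses of this model family do not state their selection rule, so the
statistic is always reported and the cut-off is left to the user).

## What the synthetic generator does and does not emulate

`synth_bundle()` produces a complete stated world: a 25-expert panel per
node built from ground-truth weights via Saaty rounding (nearest scale value
in log space) plus step perturbations; detection records drawn from a
per-hazard contamination law (default BetaGeneral(1.5, 4) over
$[0, q_5 + 0.2(q_5 - q_1)]$: contamination concentrated in the low bands
with a thinning tail, as routine enterprise testing data typically shows);
and questionnaires from a one-factor latent model whose loading is solved
from the target Cronbach $\alpha$ (default 0.834) with the latent
correlation pre-corrected by $\rho = 2\sin(\pi r/6)$ so the correlation
survives the normal-cdf mapping onto the response scales exactly. Invalid
questionnaires (default expected fraction 4.8%, i.e. ~476 valid of 500) are
injected as missing/out-of-range/straight-lined rows.

The generator deliberately does **not** emulate: real regulatory
concentration scales per analyte, temporal trends or seasonality in
detection data, correlated hazards, multi-factor questionnaire structure, or
systematic expert bias. A green end-to-end test therefore establishes that
the pipeline recovers its own stated world (weights within Saaty rounding
error, overall mean within the sampling error budget), not that the model
describes any particular enterprise.

## Numerical choices

- Power iteration: tolerance $10^{-10}$, max $10^4$ iterations, uniform
  start; matches a dense eigen decomposition to $10^{-8}$ on all tested
  Saaty matrices of order ≤ 5.
- Weight vectors renormalized to sum 1 within $10^{-9}$ at every stage.
- Judgment matrices must be reciprocal within $10^{-9}$ in memory; matrices
  parsed from YAML/JSON configs are accepted at $10^{-6}$ and re-symmetrized
  exactly, since text serialization rounds values like 1/3.
- Equal-probability binning clamps the outer bin edges to $\pm\infty$ so
  boundary observations are never dropped.
- The chi-square p-value uniformity property is tested at 300 replicates of
  $n = 400$ (scaled down to fit the test budget) with a Kolmogorov band set
  a priori for that replicate count.

## Known limitations

- Inputs are sampled independently; correlated risks will widen or narrow
  the true $\Phi$ distribution relative to the simulated one.
- The BetaGeneral $(\alpha_2, \max)$ ridge (above) limits parameter
  interpretability at realistic sample sizes.
- The published 18-component global weight vector of the motivating case
  study cannot be mapped to named indicators (its node labelling was never
  published); it is shipped as an opaque fixture whose normalization is
  asserted, nothing more.
- Sample extremes (min/max of $\Phi$) are $N$-dependent and not comparable
  across runs with different iteration counts; use quantiles instead.
- No forecasting: the engine assesses current risk; extrapolating the risk
  trajectory over time is out of scope.
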