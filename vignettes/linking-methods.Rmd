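---
title: "Linking a performance battery to a PRO T-score metric: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking a performance battery to a PRO T-score metric: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfolink)
```

## The problem

Physical function is measured both by patient-reported outcome (PRO)
questionnaires and by performance outcome (PerfO) task batteries scored by an
administrator. When a multi-task PerfO battery and a short PRO form plausibly
measure the same broad construct, item response theory lets us place the PerfO
tasks on the PRO instrument's established reporting metric, so that group-level
results can be compared and pooled across assessment types. `perfolink`
implements that workflow end to end: assumption checks, fixed-anchor
calibration, scoring, a sum-score crosswalk, and agreement evaluation — plus a
synthetic-data generator with known ground truth so every stage is testable
without access to patient data.

## The measurement model

Each item $j$ has $m_j$ ordered categories coded $0,\dots,m_j-1$. The graded
response model (GRM) specifies cumulative category probabilities that are
logistic in the latent trait $\theta$:

$$P^*_{jk}(\theta) = P(X_j \ge k \mid \theta) = \frac{1}{1+\exp\{-a_j(\theta-b_{jk})\}},$$

with discrimination $a_j > 0$ and strictly increasing thresholds
$b_{j1} < \dots < b_{j,m_j-1}$; category probabilities are adjacent
differences. The reporting metric is a T-score, $T = 10\,\theta + 50$, so the
reference population has mean 50 and SD 10. Ordinal codes are 0-based
throughout; sum scores over $J$ five-category items therefore range
$0,\dots,4J$, which keeps crosswalk indexing free of off-by-one adjustments.

## Fixed-anchor calibration

`grm_calibrate()` maximizes the marginal likelihood by EM over a quadrature
grid (default: 61 equally spaced nodes on $[-6, 6]$ with normalized standard
normal weights — fine enough that EAP estimates agree with an 8001-node grid to
better than $10^{-6}$). Anchor items keep their supplied parameters bit for
bit; only free items are updated. Three numerical choices matter:

* **Threshold order** is enforced structurally: each free item is estimated as
  $(\log a,\; b_1,\; \log\Delta_2,\dots)$, so thresholds cannot cross and the
  EM never oscillates between permuted orderings.
* **The latent prior stays N(0,1) for every cycle.** This is what defines the
  link: the current sample is assumed to be scored on the anchors' reference
  metric, and free-item parameters land on that metric. A consequence worth
  knowing: the link is *not* exactly translation-equivariant. If every anchor
  threshold is shifted by $+1$, the free items follow by about $+0.8$ rather
  than $+1.0$ when 4 anchors face 9 free items, because the fixed prior pulls
  the trait distribution back toward zero. With a re-estimated population
  distribution the shift would be complete; re-estimation is deliberately not
  done, since it would break the anchor metric's interpretation.
* **Convergence** is declared when the largest absolute parameter change in a
  cycle falls below $10^{-4}$ (at most 500 cycles); the marginal log-likelihood
  trace is retained and must be non-decreasing, which the tests assert.

Free items with unobserved categories are collapsed to their observed
categories before estimation and the recoding map is recorded; anchors are
never collapsed because their parameters are external.

Scoring is expected a posteriori (EAP): posterior mean and SD over the grid,
then the affine T transform. An all-missing pattern returns the prior mean
($T = 50$, SE $\approx 1$).

## Crosswalk construction

`build_crosswalk()` tabulates summed-score EAPs: for each attainable sum score
$s$ over the chosen item subset, the posterior over nodes is proportional to
$P(S = s \mid \theta_q)\,w_q$, with $P(S = s \mid \theta)$ from the
Lord–Wingersky recursion. Because the GRM sum score has monotone likelihood
ratio in $\theta$, the tabulated $\theta$ values are strictly increasing in
$s$; this is asserted on every built table. Persons with incomplete subsets
are scored by pattern EAP instead (recorded per person); the reverse direction
maps a T-score to the nearest tabulated sum score, ties to the lower score.
Pattern-based and summed-score EAPs agree to about 0.15 RMS in $\theta$ on
nine-item data — a documented consistency, not an identity.

## Assumption checks

**Classical statistics.** Cronbach's alpha (with deletion deltas) and corrected
item-total correlations use complete cases over the analyzed items; the
eligibility rule (all anchors answered, at least six of nine new items) keeps
near-complete data anyway, so a more elaborate missing-data treatment would
buy little.

**Mokken scalability.** $H_{ij}$ divides the observed inter-item covariance by
the maximum attainable under the two items' marginals — the comonotone
coupling, i.e. sorting both margins against a common ordering. Item and scale
coefficients are ratio-of-sums aggregates, so $H$ always lies between the
smallest and largest $H_i$. Monotonicity uses rest-score groups (adjacent rest
scores merged until each group holds $\max(50, n/10)$ persons) and counts a
violation only when an ordered pair of groups shows a drop exceeding 0.03 (the
conventional minimum-violation size) *and* a one-sided two-proportion z-test
rejects at 0.05, without multiplicity correction. On clean GRM data a single
isolated active violation across a 13-item battery is within expectation,
which is why the pipeline criterion flags only items with more than one; a
genuinely non-monotone item produces dozens.

**Factor structure.** Polychoric correlations are estimated in two steps:
thresholds from inverse-normal cumulative marginals, then each pairwise $\rho$
by maximizing the bivariate-normal contingency likelihood (rectangle
probabilities via 32-point Gauss–Legendre quadrature of the single-integral
form of the bivariate CDF; accuracy ~$10^{-7}$ against direct integration).
Asymptotic variances come from the observed information of the pairwise
likelihood, with a $\;(1-\rho^2)^2/n$ fallback. The confirmatory fit minimizes
the diagonally weighted least-squares discrepancy with those inverse variances
as weights; CFI/TLI come from the discrepancy chi-square against the
independence baseline, RMSEA from the noncentrality, SRMSR as the root mean
squared residual correlation. These are the standard (non-robust) formulas;
mean-variance-adjusted ("robust WLSMV") corrections are a known limitation and
out of scope.

**Bifactor indices.** Exploratory bifactor analysis is Schmid–Leiman:
principal-axis extraction of the specific factors, promax rotation, a single
second-order factor on the factor correlations (again principal-axis — with
only four pseudo-variables, ML factoring is fragile), then orthogonalization
$g = P\gamma$, $\lambda_s = P_s\sqrt{1-\gamma_s^2}$. One degenerate case needs
care: when the data carry no real specific structure, rotating null factors
smears the general factor across them. First-order factors whose
reduced-matrix eigenvalue is below 5% of the first eigenvalue are therefore
dropped before rotation; with a single surviving factor the solution is pure
general (ECV = 1). ECV is $\sum g^2 / (\sum g^2 + \sum\sum \lambda_s^2)$;
omega-hierarchical uses the standard column-sum formula (the Schmid–Leiman
solution has small cross-loadings, so column sums over each specific factor
are used rather than partition-restricted sums — the difference is of the
order of squared cross-loadings). PUC is the counting formula on the
user-supplied partition; the item-to-subdomain map is a required input because
no canonical partition exists, and $\{4,3,3,3\}$-style partitions of 13 items
give PUC $\approx 0.77$–$0.81$.

**DIF.** Per item, three nested proportional-odds models (trait; + group;
+ group and interaction) are fitted by maximum likelihood (`MASS::polr`), with
the EAP score from the full fixed-anchor calibration as the conditioning trait
— a single pass, no iterative purification, with a hook for user-supplied
scores. The effect size is the Nagelkerke pseudo-$R^2$ change between the
full and the trait-only model, both computed against the intercept-only null;
uniform and non-uniform likelihood-ratio p-values are reported separately, but
the flag uses the total change against a default 3% threshold. Multi-level
groups enter as indicator sets, so the change is joint.

**Item fit.** The generalized S-X² conditions on the rest score: expected
category probabilities integrate the item's category curves against the
rest-score likelihood (Lord–Wingersky on the remaining items) and the normal
prior. Adjacent category cells with expected count below 1 are collapsed
toward the nearer tail; degrees of freedom are cells minus retained rest-score
levels minus the item's parameter count, and items ending with no degrees of
freedom are reported without a p-value. Persons missing any analyzed item are
excluded, since the statistic conditions on complete sum scores.

## Agreement evaluation

The paired standardized mean difference is $\mathrm{mean}(a-b)$ divided by the
*SD of the paired differences* — stated prominently because pooled-SD variants
of the paired SMD differ materially. The default 95% CI is the normal
approximation $\mathrm{smd} \pm 1.96\sqrt{1/n + \mathrm{smd}^2/(2n)}$; a
nonparametric bootstrap is available. Effect sizes are labeled
negligible/small/medium/large at 0.2/0.5/0.8. Bland–Altman summaries report
the mean difference, limits of agreement, and the least-squares trend of the
difference on the pair average. Ceiling and floor rates are fractions of
persons at the instruments' attainable extremes — the short anchor form
saturates sooner than the nine-task battery, which is the practical reason the
crosswalk is anchored rather than projected.

## What the synthetic generator does and does not emulate

`simulate_study()` reproduces the statistical structure the analysis assumes:
five-category graded responses from a latent trait, an optional
general-plus-specific (bifactor) propensity structure, group-specific
threshold shifts for DIF, MCAR missingness on the new items, ceiling behavior
of a short anchor form, and nuisance covariates built to correlate 0.22 and
0.28 with the standardized PRO−PerfO score difference. Defaults follow the
emulated study: 1,113 persons, 4 anchor + 9 new items, reference-population
traits N(0,1), 2% missingness on new items. The default discriminations are
drawn from $[1.2, 3.0]$ — the slope range implied by the standardized
loadings (~0.56–0.87) of a conforming pooled battery; items weaker than that
(loading $\approx 0.45$) genuinely fail the conventional item-quality criteria
and are available through `make_item_bank()`'s wider default range when
misfit, DIF or criterion failure is the thing being studied.

The generator does **not** emulate informative missingness, realistic joint
distributions of clinical covariates, administration or translation effects,
or longitudinal follow-up. Passing the pipeline on synthetic data therefore
shows the machinery is correct under the assumed model — it does not validate
any particular real battery.

The bifactor generator thresholds a standard-normal propensity (normal-ogive
formulation) rather than using the logistic GRM; the 1.7 scale constant is
irrelevant there because bifactor data feed only loading-scale analyses.

## Problem sizes

The test suite and worked examples use the sizes at which each property is
informative and stable: toy banks of 3 items for enumeration oracles,
$n = 2{,}000$ for parameter-recovery and null-calibration checks (50
replicates for the S-X² size check), $n = 5{,}000$ for correlation-recovery
and bifactor-structure checks, $n = 20{,}000$ for the EAP aggregate-
unbiasedness check, and $n = 1{,}113$ — the emulated study size — for the
end-to-end pipeline.

## Known limitations

Robust (mean-variance adjusted) fit indices, calibrated-projection linking,
iterative DIF purification, plausible-value imputation and automated Mokken
item selection are out of scope. Standard errors for calibrated item
parameters are not reported; the significance test the surrounding literature
applies to individual slopes is therefore not reproduced. The crosswalk is
built for complete response subsets; persons eligible under the 6-of-9 rule
but with missing tasks are scored by pattern EAP, which is the defensible
default but means two persons with the same sum score can receive different
T-scores if one of them skipped items.
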