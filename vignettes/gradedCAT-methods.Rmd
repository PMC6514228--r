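---
title: "Methods: graded-response CAT, bank quality control, and the Monte-Carlo evaluation"
author: "gradedCAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded-response CAT, bank quality control, and the Monte-Carlo evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedCAT)
```

## The measurement model

All items are five-category Likert responses (1 = never ... 5 = always)
modelled by Samejima's graded response model (GRM). Item $j$ carries one
discrimination $a_j > 0$ (a logit slope, unitless) and four strictly ordered
thresholds $b_{j1} < b_{j2} < b_{j3} < b_{j4}$ on the latent-trait scale.
The boundary probability of responding in category $k{+}1$ or above is

$$P^{*}_{jk}(\theta) = \frac{1}{1 + \exp\{-a_j(\theta - b_{jk})\}},$$

and category probabilities telescope, $P_{jc} = P^{*}_{j,c-1} -
P^{*}_{jc}$ with $P^{*}_{j0} = 1$, $P^{*}_{j5} = 0$. Fisher information
uses Samejima's formula $I_j(\theta) = \sum_c (P'_{jc})^2 / P_{jc}$; test
information is the sum over locally independent items. The latent trait is
standardized against a N(0, 1) population, so thresholds read as
population quantile locations: the packaged 59-item internet-addiction
bank spans $b_1 = -1.968$ to $b_4 = 4.121$, which is why its measurement
precision degrades below $\theta \approx -2$ — there simply are no easy
items there.

The bank ships at the 3-decimal precision of its published calibration;
`writeItemBank()` keeps that convention, so write-then-read round-trips
are exact for 3-dp banks and quietly truncate anything finer. Threshold
ordering is *validated*, never repaired: a transcription error should
fail loudly, not be sorted away.

## Scoring: EAP on a fixed quadrature grid

Trait estimates are expected a posteriori (EAP): the posterior mean of
$\theta$ under the N(0, 1) prior discretized on 81 equally spaced nodes on
$[-4, 4]$ with renormalized normal weights. The reported standard error is
the posterior standard deviation on the same grid — not the
information-based approximation — which matters for every SE-driven result
downstream (stopping rules, marginal reliability, the CSEE column of the
precision table). Node count and range are configurable via
`quadratureGrid()`, and the two endpoint nodes carry half weight (the
composite trapezoid rule): with full endpoint weights the O(h) boundary
bias inflates posterior-SD errors for diffuse one-item posteriors to
about $10^{-3}$, while with trapezoid endpoints the default grid agrees
with a 10,001-point reference to better than $10^{-4}$ on every pattern
(and to about $10^{-6}$ on typical multi-item patterns).

Likelihoods accumulate in log space (no underflow on long patterns), and
terms are summed in bank order regardless of administration order, so the
adaptive and non-adaptive estimates of the same responses are identical
bit for bit — a property the tests assert literally.

## The adaptive loop

`administerCAT()` implements: random initial item (uniform over the bank,
to spread exposure; a fixed start is available), then repeatedly respond
→ EAP update → stopping check → maximum-information (MIC) selection at
the current estimate. Stopping rules are `"none"` (administer the whole
bank) or a standard-error ceiling (0.2–0.5 in the evaluation sweeps). The
check runs after each update, so a test is at least one item long even
under an absurdly loose ceiling; besides bank exhaustion no implicit
length cap exists (an explicit `maxItems` is off by default). Exact
information ties — possible with duplicated parameters — resolve to the
lexicographically smallest item id, making runs reproducible.

## Calibration

`calibrateGRM()` is marginal maximum likelihood via EM. The E-step puts
posterior weight on the quadrature nodes per person; the M-step maximizes
each item's expected complete-data log-likelihood by BFGS with an
analytic gradient, parameterizing thresholds as $(b_1, \log$
increments$)$ so ordering holds by construction. Convergence is an
absolute change in $-2\mathrm{LL}$ below $10^{-4}$, capped at 500 cycles;
hitting the cap flags the result rather than failing silently. Items
must show all five categories: an unobserved category leaves a threshold
unidentified, and the error names the item and category instead of
letting the optimizer wander. Model comparison uses
$\mathrm{AIC} = -2\mathrm{LL} + 2p$ and
$\mathrm{BIC} = -2\mathrm{LL} + p\ln N$ (`fitIndices()`); only the GRM
likelihood is implemented — the published model contest against GPCM,
GRSM and NRM is out of scope here, the index arithmetic is not.

At the suite's reference size (20 items, $n = 1000$) calibration recovers
generating slopes with $r \ge 0.97$ and thresholds with RMSE below 0.1,
comfortably inside the acceptance bounds ($r \ge 0.9$, RMSE $\le 0.25$).

## Bank quality control

`runQCPipeline()` iterates the published six-step screen to a fixed
point, recalibrating after every exclusion wave; re-running it on its own
survivors excludes nothing.

1. **Unidimensionality.** Eigen decomposition of the inter-item Pearson
   correlation matrix: first-factor variance proportion $\ge 0.20$,
   first/second eigenvalue ratio $\ge 4$, and per-item first-factor
   loadings (eigenvector scaled by $\sqrt{\lambda_1}$) $\ge 0.40$. Two
   deliberate simplifications: Pearson rather than polychoric
   correlations (the published analysis does not name its correlation
   type; polychoric is a documented extension), and the loading rule
   standing in for the weighted-least-squares single-factor CFA — the
   0.40 loading cut is the operative filter either way, and RMSEA is out
   of scope.
2. **Local independence (Yen's Q3).** Residuals $x_j - E[x_j \mid
   \hat\theta]$ at the EAP estimate, correlated pairwise; pairs above
   0.36 are dependent. Of each flagged pair the member with the lower
   item scalability $H_j$ is dropped (ties: lower $a$, then smaller id) —
   the source procedure removes "one item per pair" without naming the
   rule, so we chose one that keeps the more scalable member and is
   deterministic.
3. **Monotonicity (Mokken).** $H_{jk} = \mathrm{cov}(X_j,
   X_k)/\mathrm{cov}_{\max}(X_j, X_k)$, with the maximum covariance given
   the margins computed from the comonotonic coupling; items with $H_j <
   0.30$ leave. Perfect Guttman data attains $H = 1$ exactly.
4. **Item fit (S-X²).** Observed versus expected category frequencies in
   summed rest-score groups, expecteds from the Lord–Wingersky recursion
   (verified against exhaustive enumeration in the tests). Rest-score
   rows merge inward from both extremes until each holds expected mass
   $\ge 5$; within rows, adjacent cells collapse until every expected
   count is $\ge 1$ (the conventional minimum). $df = \sum_s (m_s - 1) -
   5$; non-positive $df$ marks an item untestable rather than fit.
   Empirically the test holds its size: about 1% of clean items flag at
   $\alpha = 0.01$.
5. **DIF.** Proportional-odds models on the matching EAP estimate: trait
   only (M1) versus trait + group + interaction (M3); McFadden's
   $R^2$ change above 0.02 flags total DIF. The uniform-only M2
   comparison is reported but not used for exclusion, and matching is a
   single pass on the current bank (no purification loop) — the source
   specifies only the $\Delta R^2$ rule.
6. **Discrimination.** Calibrated $a < 1.00$ leaves the pool.

When one item trips several step-5 screens its reason code follows the
step order (item fit, then DIF, then discrimination), so reason codes
partition the exclusions.

Two structural observations, both visible in the tests. First, a
genuinely weak item (slope well below 1) never survives to step 6: its
factor loading sits near 0.3 and the loading screen removes it in wave
one. The published screen shows the same signature — its discrimination
row excluded nothing. Second, with 20 items and a correctly sized 1%
item-fit test, the probability that a *clean* pool passes with zero
exclusions is $0.99^{20} \approx 0.82$, not higher; a pipeline that
passed clean pools more often would be running a conservative fit test.

## The synthetic study designs

`syntheticDesign()` fixes the study conditions the evaluation and QC
tests run under; its defaults are the conditions of the calibration study
the packaged bank came from, and they are not tuned per test:

- trait $\theta \sim N(0,1)$, $n = 1000$ persons, 20 items;
- slopes uniform on $[1.1, 2.6]$ and thresholds spanning about
  $[-2, 3.5]$, the span of the published bank. Upper thresholds of sharp
  items are compressed until the top category keeps at least 1% marginal
  mass: the published bank shows the same negative association between
  slope and top threshold, and without it a sharp item at $b_4 = 3.5$
  yields zero observed category-5 responses at $n = 1000$, violating
  calibration's own precondition;
- two-level covariates at the reference sample's rates (female 50.2%,
  rural 58.9%, under-18 roughly a third);
- diagnosis labels as $\theta > 1$ (about 16% prevalence, inside the
  range reported for student populations) with 5% label noise;
- planted defect sizes — DIF threshold shift 0.8, dependent-pair copy
  noise 0.1, weak-item slope 0.6, uniform noise items — chosen once so
  each targeted statistic detects its defect with power $\ge 0.8$ at
  $n = 1000$.

What the generator does *not* emulate: multidimensional content
structure, skewed or non-normal trait distributions, item wording
overlap between source scales, missing responses, and real response
styles (midpoint/extreme preferences). Passing tests therefore certify
the machinery under the model's own assumptions, not robustness to their
violation.

## The Monte-Carlo evaluation

`runMCSimulation()` draws one population and sweeps the stopping rules
over it, simulating responses on demand during administration. Overall
CBIAS/CMAE/CRMSE/CSEE are person-level means across all simulees —
binning first and averaging bin means would over-weight the sparse
extremes; conditional curves use bins of width 0.5 on $[-4, 4]$
(configurable). Marginal reliability is $1 - \overline{SE}^2$ with
$\overline{SE}$ the plain mean of per-person SEs. The full-bank run at
$n = 1000$ lands within 0.01 of the published CSEE/CMAE/CRMSE row, and
the per-bin bias curve shows the EAP shrinkage signature (positive below
the prior mean, negative above).

Predictive validity uses the rank-formulation AUC with half-credit ties
(identical to pairwise enumeration by construction, asserted exactly in
the tests), Hanley–McNeil confidence intervals by default with DeLong as
an option, and a Youden-index scan over midpoints between consecutive
predictor values, resolving exact ties toward the higher cut-off (higher
specificity). The two built-in diagnostic rules are the 20-item sum rule
(positive strictly above 39) and the count rule (at least four designated
items scoring 4 or 5); the designated subset is a parameter because the
source instrument does not enumerate it.

## Problem sizes and determinism

The test suite runs at $n = 1000$ persons for calibration, QC and the
evaluation sweep, 20 seeds for the planted-defect sensitivity checks, and
1,000 simulees for the precision table — sizes chosen to keep every
stochastic bound comfortably resolvable while the whole suite stays
desk-scale. Every stochastic component takes an explicit seed, and all
randomness in a CAT run flows from its config seed, so identical configs
reproduce identical records bit for bit.

## Known limitations

- Only the GRM is implemented; GPCM/GRSM/NRM comparisons, MLE/WLE/MAP
  scoring, exposure control beyond the random first item, content
  balancing and testlet/multidimensional extensions are out of scope.
- Missing responses are rejected rather than modelled.
- Exact reproduction of the published item parameters and the real-data
  validity tables would require the original 1,368-person responses,
  which were never released; the synthetic designs emulate their
  structure instead, and the real-data-dependent numbers are covered by
  arithmetic identities and property checks rather than value matching.
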