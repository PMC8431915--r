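---
title: "Regularized partial-correlation networks for ordinal questionnaire items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized partial-correlation networks for ordinal questionnaire items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

ordnet estimates a Gaussian graphical model (GGM) over questionnaire
items: a network whose nodes are items and whose edges are partial
correlations — the association between two items after conditioning on
every other item. For a precision (inverse covariance) matrix $K$ the
edge weight between items $i$ and $j$ is

$$ w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}}. $$

The motivating application is the relation between the twelve components
of intolerance of uncertainty (IUS-12, five-point items scored 1–5) and
the seven symptoms of generalized anxiety (GAD-7, items scored 0–3),
with the items divided a priori into two communities (IU and GAD).

Because the items are ordinal, association is measured by Spearman rank
correlations (average ranks for ties, then Pearson on the ranks). The
Spearman matrix is fed to the penalized Gaussian likelihood as if it were
a product-moment correlation matrix, which is the convention of the
network-psychometrics ecosystem; no nonparanormal re-transformation is
applied.

## Estimation: graphical lasso with EBIC selection

The precision matrix is estimated by the graphical lasso: maximize

$$ \log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|, $$

with the diagonal unpenalized (the standard GGM convention, which keeps
partial correlations well scaled). The solver is a block coordinate
descent (a lasso regression per column of the working covariance),
written in C++ for the bootstrap loops. Convergence is declared on the
duality gap

$$ \operatorname{tr}(SK) + \lambda\lVert K\rVert_{1,\mathrm{off}}
   - \log\det K - \log\det W - p, $$

which bounds the primal suboptimality and is driven below $10^{-6}$ by
default. The working covariance $W$ is dual feasible after the first
sweep, so the bound is valid throughout.

The penalty is chosen by the extended Bayesian information criterion,

$$ \mathrm{EBIC} = -2L + E\log n + 4E\gamma\log p, $$

over a log-spaced path of 100 penalties from $\lambda_{\max}$ (the
largest absolute off-diagonal of $S$, the smallest penalty giving an
empty graph) down to $0.01\,\lambda_{\max}$. Defaults mirror common
practice in the ecosystem. $\gamma = 0.5$ by default, trading a little
sensitivity for specificity; ties are broken toward the larger penalty
(the sparser model). Entries with magnitude below $10^{-10}$ are treated
as zero when counting edges, so numerical noise cannot inflate either
the EBIC penalty or reported edge counts.

Rank-based correlation matrices need not be positive definite, and the
graphical lasso requires a PD input, so estimation is always preceded by
an eigenvalue-clipping repair: eigenvalues are floored at $10^{-4}$
(small enough not to distort, large enough for stable log-determinants),
the matrix is reassembled and rescaled to unit diagonal, and the repair
is recorded. PD inputs pass through unchanged.

## Centralities and predictability

* **Expected influence** of a node is the sum of its signed edge
  weights (one step); a two-step variant is available behind a flag. The
  signed sum, rather than the absolute-value sum used by strength
  centrality, is the meaningful quantity in networks with negative
  edges.
* **Bridge expected influence** is the signed sum restricted to edges
  crossing the community boundary of an a-priori partition. Signed
  weights are used here too, matching the definition of the statistic;
  communities are never detected from the data.
* The exact identity *expected influence = bridge + within-community
  influence* holds for every node and partition and is enforced by
  tests.
* **Predictability** of a node is the $R^2$ of an ordinary
  least-squares regression of that item on all remaining items, treated
  as continuous and clipped to $[0, 1]$. With $n \gg p$ (hundreds of
  respondents, 19 items) the unregularized estimate is stable; for
  $n \le p$ the function refuses and points to a regularized
  alternative rather than silently overfitting. Raw responses are
  required — predictability is not identifiable from a correlation
  matrix alone.

## Bootstrap diagnostics

Edge-weight accuracy is assessed by a nonparametric bootstrap:
respondents are resampled with replacement and the *entire* pipeline
(Spearman, repair, EBIC selection) is re-run per replicate with the main
run's settings — no per-replicate re-tuning. Per-edge 95% intervals are
empirical quantiles. Replicates in which an item becomes constant are
dropped and counted; more than 5% failures aborts.

Stability of centrality orderings is assessed by a case-dropping
bootstrap: for drop fractions 10%–70% in steps of 10% (the conventional
grid), subsamples without replacement are re-estimated and their
centralities correlated (Pearson) with the full-sample values. The
correlation-stability (CS) coefficient is the largest tested fraction at
which that correlation stays at or above 0.7 with 95% probability; above
0.5 is preferred and below 0.25 inadequate. The 2.5th percentile is
computed as a plain order statistic so the coefficient can be reproduced
exactly from the stored draws. A subsample statistic with zero variance
(typically an empty network) is assigned correlation 0 — a constant
profile carries no ordering information.

Bootstrapped difference tests compare every pair of edges (or nodes)
through the bootstrap distribution of their difference; a pair differs
when the central 95% interval excludes zero. No multiplicity correction
is applied by default, which is the convention for these descriptive
diagnostics; a Bonferroni variant sits behind a flag.

## The synthetic-data generator

There is no public raw-response dataset for the motivating instruments,
so the package carries a generator that serves as the test bed for every
stage. It draws a sparse ground-truth partial-correlation network over
two communities (defaults: 12 + 7 items, density 0.2, nonzero weights
uniform in $[0.25, 0.4]$, 5% of edges negative — echoing the sparse
negativity of published item networks), converts it to a latent
correlation matrix, samples multivariate normal latent scores, and cuts
them into ordinal categories with per-item thresholds. The
latent-Gaussian threshold mechanism is the standard choice for
simulating Likert data and is compatible with Spearman-based estimation.

Two points deserve emphasis:

* A unit-diagonal precision built from a dense-ish random partial
  pattern is frequently not positive definite. It is then repaired by
  diagonal loading followed by re-standardization, and the *realized*
  (post-repair) partials are recorded as the ground truth — a
  self-consistent truth rather than an infeasible target. At the
  default density the repair usually engages and shrinks the realized
  weights below the nominal range; recovery results are always scored
  against the realized truth.
* The `paper_like` preset fixes per-item thresholds that were fitted
  once, offline, so that thresholding a standard normal reproduces the
  published per-item means and SDs of the two instruments (fit
  residuals below $10^{-6}$ on both moments; the package reproduces the
  targets within ±0.05 / ±0.08 at $n = 10^5$). Only the marginal
  moments are emulated: the preset says nothing about the instruments'
  true dependence structure, response styles, or measurement error, so
  passing recovery tests demonstrates correctness of the estimator
  under this generative model — not fidelity to the study population.

Edge indicators, magnitudes and signs are drawn in a documented
vectorized order, so the sampling is replayable exactly from the seed;
all simulation, estimation and bootstrap stages are bit-reproducible
given (seed, settings).

## What the estimator does and does not deliver

On study-shaped synthetic data ($p = 19$, $n = 624$) the EBIC graphical
lasso finds essentially every true edge and recovers the sign of every
true edge at large $n$. It does **not** produce a sparse estimate of a
sparse truth at these sample sizes: the selected networks keep roughly
60–70% of all possible edges, most of the extras being small-magnitude
false positives. Two forces drive this. First, shrinking strong true
edges costs likelihood, so the EBIC optimum sits at a small penalty
where many weak spurious edges survive; this dense-selection behaviour
of EBIC-glasso at moderate-to-large $n$ is well documented, and
published item networks of this kind show the same density. Second,
ordinalization distorts the dependence structure: the population
Spearman matrix of thresholded Gaussians does not have a sparse inverse
even when the latent precision does. Users should read edge *presence*
lists conservatively and lean on the bootstrap difference tests and
interval widths when interpreting individual edges.

## Numerical choices and degenerate inputs

* Duality-gap tolerance $10^{-6}$; inner coordinate-descent tolerance
  $10^{-9}$; 200 outer sweeps maximum, warm starts down the penalty
  path.
* Edge-count threshold $10^{-10}$; EBIC ties resolved toward sparsity.
* PD-repair floor $10^{-4}$.
* Constant items are refused by name wherever correlations are needed;
  constant bootstrap resamples are dropped and counted.
* Missing responses are rejected outright rather than pairwise-deleted:
  the instruments are forced-choice and the analysis assumes complete
  cases.
* Quantile conventions: bootstrap intervals use the default sample
  quantile; the CS coefficient uses the order-statistic quantile for
  exact replayability.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline at
the study size ($n = 624$, $p = 19$), a large-sample variant at
$n = 5000$, marginal-calibration checks at $n = 10^5$, and bootstrap
diagnostics at $B = 200$ replicates (an order of magnitude below the
$B = 2000$ one would use in a report, chosen so the whole suite runs in
minutes while leaving the bootstrap machinery fully exercised).

## Limitations

* Polychoric correlations are a named extension point, not implemented;
  Spearman input is the supported path.
* No missing-data handling, longitudinal structure, or non-Gaussian
  copulas in the generator.
* The community label of a collapsed total-score node is left
  undefined: no bridge statistics are computed for aggregate networks.
* Figure rendering is out of scope; the package exports edge lists and
  matrices for external layout tools.
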