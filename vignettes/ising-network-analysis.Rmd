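---
title: "Ising network analysis of binary questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ising network analysis of binary questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`isingnet` analyzes binary questionnaire items — here, mental-health
knowledge items scored correct/incorrect and stigma items dichotomized to
endorsement/non-endorsement — as a pairwise binary Markov random field
(an Ising model in {0,1} coding):

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\Big),
\qquad x \in \{0,1\}^p.$$

Each node $i$ has a threshold $\tau_i$ (its endorsement propensity when all
neighbours are 0; under this coding a rarely endorsed item has a strongly
negative threshold) and each pair a weight $w_{ij}$, the conditional
log-odds association after controlling for all other items. The coding
matters: the same data in $\pm 1$ coding would give different thresholds,
and the strongly negative thresholds typical of low-endorsement items only
make sense in {0,1} coding, which is what the estimator and the sampler
use throughout.

## Estimation: nodewise $\ell_1$ logistic regression with EBIC (eLasso)

The conditional distribution of one item given the rest is logistic,
$P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)$,
so the network is estimated nodewise: each item is regressed on all others
with an $\ell_1$ penalty along a geometric path of 100 penalties from
$\lambda_{\max}$ (the smallest penalty zeroing all coefficients) down to
$0.01\,\lambda_{\max}$. Each path point is scored by the extended BIC,

$$\mathrm{EBIC}_\gamma = -2\ell + k\log n + 2\gamma k \log(p-1),$$

with $k$ the number of nonzero coefficients and $\gamma = 0.25$ by
default; ties prefer the larger penalty (sparser model). The two directed
coefficient estimates per pair are symmetrized by the AND rule (an edge
exists only if both regressions retain it; its weight is the mean of the
two coefficients) or optionally the OR rule. Thresholds are the intercepts
of each node's own selected model. Predictors enter unstandardized, which
keeps weights and thresholds on the natural logit scale of the items.

The path solver is written in compiled code: coordinate descent on the
iteratively reweighted least-squares quadratic approximation (proximal
Newton) with warm starts, specialized to binary predictors so inner
products reduce to indexed sums, and solved in a centred parameterization
that decouples the intercept from the coefficients (identical $\ell_1$
solution, far fewer sweeps). The test suite cross-checks the solver
coefficient-by-coefficient against an independent generic implementation
(`glmnet`) along a shared path, and checks EBIC selection against
exhaustive best-subset search on small graphs.

Numerical choices worth knowing:

* convergence tolerance `tol = 1e-6` on the maximum coefficient step, with
  a quadratic-convergence early stop;
* a magnitude guard `beta_cap = 8`: quasi-separation (e.g. a duplicated
  item) drives penalized coefficients to absurd magnitudes at small
  penalties, so the path is truncated with a warning once any coefficient
  passes 8 — far above plausible pairwise logit weights (|w| rarely
  exceeds 3) and far below where separation takes coefficients;
* zero-variance items are rejected at load time, never imputed: the
  nodewise likelihood is undefined for them, and the data contract is
  complete responses.

## Centrality and bridges

Strength $\sum_j |w_{ij}|$, one-step expected influence $\sum_j w_{ij}$,
and bridge expected influence (the signed sum of a node's edges into the
other community) are computed per node, with z-scores across nodes using
the sample (n−1) standard deviation; the convention is recorded in the
table's metadata. Communities are given by the instruments (knowledge vs
stigma), not detected. A two-step expected influence is deliberately not
offered: the one-step definition is the one the downstream reports use.

## Stability

The case-dropping bootstrap drops a proportion $q$ of respondents
(grid 0.10–0.75 in steps of 0.05, 500 replicates by default),
re-estimates the network, and correlates subsample with full-sample
centralities (Pearson, nodes as units). The CS coefficient is the largest
$q$ at which at least 95% of replicates correlate at least 0.7; above 0.25
counts as acceptable stability and above 0.5 as good. Replicates whose
subsample loses a response category are skipped and counted, and
replicates with an undefined correlation (a constant centrality vector,
e.g. an empty re-estimate) count as failures rather than crashing.
Nonparametric bootstrap confidence intervals for edges resample rows with
replacement and take 2.5%/97.5% percentiles. All replicates draw from
index-derived sub-seeds, so results do not depend on execution order.

## Simulated interventions (threshold perturbation)

To rank nodes as intervention targets, each node's threshold is shifted by
±2 standard deviations of the estimated threshold vector — "aggravating"
(+, making the item easier to endorse/misbelieve) or "alleviating" (−) —
and respondents are Gibbs-sampled from the altered model. The summary per
condition is the mean network sum score $S = \sum_i x_i$ with a normal
95% CI (percentile CIs are available). Aggravating conditions are ranked
by descending mean, alleviating by ascending mean.

Two conventions here were genuinely open and are fixed as follows. The
"standard deviation" in ±2 SD is the sample SD of the p estimated
thresholds — not a per-node standard error — matching the convention of
the simulation algorithm this reimplements; all perturbations reference
the unperturbed vector's SD, so opposite shifts cancel exactly. And the
sum score includes all nodes (a single network-level score); per-community
subscores can be derived from the returned samples but are not claimed as
the primary output.

Under non-negative weights the {0,1} Ising measure is monotone in each
threshold, so aggravation can never lower and alleviation never raise the
exact expected sum score; the test suite verifies this by full
enumeration, and checks that simulated rankings reproduce enumeration
rankings for every node pair whose exact means are separated by more than
3 combined Monte-Carlo standard errors.

## Group comparison

The permutation comparison estimates a network per group and tests
invariance of global strength ($\sum_{i<j}|w_{ij}|$, absolute difference),
structure (maximum absolute edge difference), individual edges, and
per-node strength and expected influence. Null distributions come from
re-assigning group labels (sizes fixed) and re-running the full eLasso
estimation on both pseudo-groups each permutation — never by resampling
weights. P-values use the add-one estimator $(\#\{T^{perm} \ge T^{obs}\}+1)/(B+1)$,
which cannot return 0; edge and node families are Holm-corrected by
default. Permutations that produce a zero-variance pseudo-group column are
redrawn (counted, capped). 1,000 permutations is the default.

## The synthetic generator

Because the reference survey's raw data are not deposited, the package
generates its own ground truth: two communities (20 knowledge, 12 stigma
items) with intra-community edge probability 0.15, exactly 3 planted
inter-community bridges, weights uniform on [0.3, 1.2], and thresholds
calibrated so that item endorsement rates match the published per-item
rates (spanning 13.6%–92.1%; shipped in `inst/extdata` and exposed via
`reference_table()`). Calibration adjusts thresholds by damped
logit-scale offsets (damping 0.6 — full steps oscillate when positively
coupled items co-move), using exact enumeration below p = 17 and Gibbs
marginals above, to a default tolerance of 0.02.

Sampling uses fixed-order single-site Gibbs updates with an incremental
local field. Respondents are independent chains (default 1,000 burn-in
sweeps each, start from independent `Bernoulli(plogis(tau))` draws), so
rows are i.i.d. persons; a single thinned chain is available as an option.
For small networks the sampler is validated against exact $2^p$
enumeration. The generator emulates community structure, sparsity,
bridges and marginal endorsement rates; it does not emulate
response-style artifacts (acquiescence, social desirability),
item-wording effects, or any latent-trait structure, so passing tests
support the correctness of the algorithms, not the substantive
psychology of any particular survey.

## Problem sizes used by the validation suite

The simulations behind the automated checks use sizes chosen to give
clear signal at desk scale: recovery of the calibrated 32-node network at
n = 12,000 (plus 500/2,000/8,000 across 5 seeds for the consistency
check); sampler-vs-enumeration agreement at n = 20,000 for p ≤ 10;
comparison-test calibration with 200 null trials of 500 + 500 respondents
and 200 permutations each (power: 50 trials at 1,000 + 1,000), on a
6-node planted network with an estimation path of 40 penalties — the
permutation test's validity is estimator-agnostic, so the shorter path
changes cost, not calibration; case-dropping stability at 100 replicates
per grid point. The acceptance script repeats the same computations at
moderately reduced replication counts and records every quantity it
reports.

## Limitations

* The estimator assumes complete binary data; there is no missing-data
  machinery by design.
* EBIC selection with $\gamma = 0.25$ is conservative; weak edges
  (|w| ≈ 0.3) need thousands of respondents to enter reliably, which is
  visible in the recovery-vs-n checks.
* Intervention simulations explore one node at a time; combined or
  sequential interventions and any dynamic (time-series) interpretation
  are out of scope.
* The comparison test handles exactly two groups without covariate
  adjustment.
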