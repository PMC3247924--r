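---
title: "Correlated mutation analysis by regularized multinomial regression"
author: "rmrcm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated mutation analysis by regularized multinomial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmrcm)
```

## The problem

Columns of a protein multiple sequence alignment (MSA) that are in physical
contact, or functionally coupled, tend to mutate in a correlated way.
Pairwise statistics such as mutual information detect this, but they cannot
distinguish a *direct* dependency between columns $m$ and $p$ from an
*indirect* one induced by a shared partner $n$ (with $m$–$n$ and $n$–$p$
directly coupled). This package treats correlated-mutation detection as a
sparse structure-learning problem: each column is explained by *all* other
columns jointly, so that an indirect partner adds nothing once the direct
partner is in the model, and the penalty prunes it away.

## The model

Let $\mathbf{A}$ be the $n \times p$ alignment over 21 states (20 amino
acids, alphabetically coded 1–20, and the gap, coded 21). $\mathbf{A}$ is
expanded into a binary indicator matrix $\mathbf{M}$ with $21p$ columns:
cell $(s, i)$ of $\mathbf{A}$ sets exactly one 1 in the 21-column block of
column $i$ (`encodeAlignment()`).

For each response column $i$, the 21-level categorical response
$y = A_{\cdot i}$ is regressed on $X = M_{\cdot, -i}$ (all indicator
columns except column $i$'s own block) with a penalized multinomial model

$$\hat\beta(\lambda) \;=\; \arg\min_\beta\;
  -\tfrac1n\, \ell(y, X, \beta) \;+\;
  \lambda \sum_j \Big[ \tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j| \Big],$$

where $\ell$ is the multinomial log-likelihood in the symmetric softmax
parameterization and the class intercepts are never penalized. The mixing
parameter defaults to $\alpha = 0.99$ — almost pure lasso, with a small
ridge component that stabilizes groups of correlated indicators. The path
of $\lambda$ values is log-spaced from $\lambda_{\max}$ (the smallest
penalty with an all-zero solution) down to $\lambda_{\max}/100$, 100
values by default. (With $21(p-1)$ indicator predictors per fit,
alignment data always has far more predictors than sequences, where 1/100
is also the path solver's own floor; extending the path further only adds
saturated, poorly determined fits whose coefficient sums destabilize the
path-sum score.) The path is solved by coordinate descent (glmnet) with
convergence tolerance $10^{-7}$ and at most $10^5$ passes; the test suite
checks the fitted objective against an independent proximal-gradient
optimizer on small instances.

Nonzero coefficients link the response column to predictor columns. Three
projections of a fitted path onto per-column scores are available
(`projectLinks()`):

* **path_sum** (default): $\sum_\lambda \sum_c \sum_{a}
  |\beta_{c,j,a}(\lambda)|$ over all response classes $c$ and the 21
  indicators $a$ of predictor column $j$ — links supported along the whole
  path accumulate weight;
* **bic**: the same absolute-coefficient sum at the single path entry
  minimizing $\mathrm{BIC} = -2\ell + k\ln n$, with $k$ the number of
  nonzero non-intercept coefficients (ties go to the larger, sparser
  $\lambda$; selection is per column);
* **model_count**: the number of path entries in which column $j$ carries
  any nonzero coefficient.

Because column $i$ regressed on $j$ and column $j$ regressed on $i$ give
different coefficients, the asymmetric score table is symmetrized by
averaging the two directions; the diagonal is zero (`rmrcm()`). On our
simulations the path-sum ranking is the strongest and BIC the weakest of
the three, matching the original account of the method, so path_sum is the
default.

Two practical notes on the per-column fits. First, response classes
observed fewer than twice cannot be fitted by the coordinate-descent
solver; their observations are dropped from that column's fit (and its
likelihood), and such classes simply carry no coefficients. Second,
predictors are *not* standardized by default: one-hot indicators already
share a scale, and standardizing divides each by
$\sqrt{q(1-q)}$ (frequency $q$), which amplifies exactly the rarest,
noisiest characters. On a 50-node variant of the simulation
benchmark this costs about 0.06 AUC (0.944 unstandardized vs 0.883
standardized); `fitConfig(standardize = TRUE)` restores the conventional
behavior.

Fully conserved response columns carry no correlation signal; they are
skipped and contribute zero scores. Columns with more than 50% gaps are
removed beforehand (`filterGapColumns()`, cutoff strictly-greater-than);
surviving columns keep their original 1-based numbers in every report.

## The mutual-information baseline

For each column pair, the $21\times21$ joint count table gives plug-in
probabilities, $\mathrm{MI} = \sum p(a,b)\log[p(a,b)/(p(a)p(b))]$, and the
reported score is $\mathrm{MI}/H_{ab}$ with $H_{ab}$ the pair's joint
entropy — the entropy correction that removes most of the dependence of
raw MI on column variability. The ratio is basis-independent, lies in
$[0,1]$, and is defined as 0 for a conserved pair ($H_{ab}=0$). The gap
state counts as an ordinary 21st character, on the same footing as in the
regression. `miMatrix(corrected = FALSE)` exposes raw MI for comparison;
it performs worse and is never the default.

## The benchmark generator

To validate link predictions against a known ground truth, the package
simulates alignments from Markov random fields over random interaction
networks:

1. `generateNetwork(200, density)` includes each of the 19,900 possible
   node pairs independently with probability 0.1, 0.25 or 0.5
   (≈ 1,990 / 4,975 / 9,950 edges).
2. `buildPotentials(net, pPrefNode, pPrefEdge)` gives every node one
   uniformly chosen preferred character of probability `pPrefNode` (0.1 or
   0.3), the remaining 20 sharing the rest equally; and every edge a
   $21\times21$ pair distribution in which, for each character of the
   lower-numbered endpoint, two uniformly chosen partner characters are
   preferred. The 42 preferred cells share total mass `pPrefEdge` and the
   399 background cells share the remainder, so each table sums to one.
   This normalization is the one under which a per-cell
   background weight of $(1-p_{\mathrm{prefedge}})/399$ and the
   requirement that the table be a probability distribution are
   simultaneously consistent; giving each preferred *cell* the full mass
   $p_{\mathrm{prefedge}}$ instead makes the preferred/background ratio
   171 and freezes the sampler into a single configuration (pairwise
   identity 0.96, no recoverable signal), so that reading was rejected.
   With mass sharing the ratio is ≈ 4.1 at 0.3 and ≈ 1.06 at 0.1 — the
   latter explains why weak edge preferences yield essentially no
   detectable coevolution signal for any method.
3. `gibbsSample()` runs single-site Gibbs sampling: nodes are updated
   sequentially (order 1..p) with the conditional
   $P(x_v = a \mid \text{rest}) \propto \text{node}_v(a) \prod_{u \sim v}
   T_{vu}(a, x_u)$, an "iteration" is one full sweep, and after 100,000
   sweeps the last `nSamples` states recorded every `thinning` sweeps
   (50 by default; 1 and 200 as variants) become the alignment rows.
   States are initialized from the node potentials. The inner loop is
   compiled (Rcpp) with per-direction contiguous tables, ≈ 35 s per
   100,000-sweep chain at density 0.25 on one core.

Perturbations reproduce the robustness analyses: `addPositionNoise()`
(a stated fraction of cells changed to a different amino acid, never a
gap), `addSequenceNoise()` (a stated fraction of rows resampled from node
potentials alone), and `addDuplicates()` (append 10/25/50 copies of one
random row).

What the generator emulates: preference-driven column composition,
pairwise couplings of tunable strength, correlated samples from a single
chain (phylogeny-like relatedness in the crudest sense), near-duplicate
sequences. What it does not: real substitution processes, indels and gap
patterns, actual phylogenetic tree structure, or heterogeneous
conservation. Passing the simulation benchmark therefore shows that the
estimator recovers direct couplings from categorical data of this type,
not that it meets any particular accuracy on real protein families.

A caveat we measured rather than hid: at density 0.25 the random directed
partner tables frustrate each other and the single sequential chain
decorrelates only over $10^5$–$10^6$ sweeps. The 500 thinned samples are
then more correlated than ideal — corrected-MI AUC ≈ 0.55 against the
true edges, while 500 *independent* chains (an iid sample from the same
model) reach ≈ 0.93. The method's original simulation study reports ≈ 0.68 for
this setting, between the two, suggesting a sampler that decorrelated
faster than a plain sequential-scan Gibbs chain; no faithful variant we tested
(synchronous updates, node-level iterations, mixture conditionals,
symmetrized partner sets) reproduces that intermediate point while also
matching the density-0.1 results, which this implementation does
reproduce. The low-density results, the duplicate-robustness contrast,
and the identity / mean-MI calibrations are insensitive to this and land
within the originally reported spreads.

## Evaluation machinery

* `aucLinks()`: AUC of the pair ranking against the true edge set, by the
  rank-sum (Mann–Whitney) formulation — exact under ties, 0.5 for
  constant scores.
* `contactMap()` / `contactMapFromPDB()`: residue–residue distances from
  one representative atom per residue (Cβ; Cα for glycine), contact iff
  distance ≤ cutoff (8 Å for CASP-style assessment; 5/6/15 Å in other
  protocols).
* `caspScores()`: among candidate pairs separated by ≥ 24 residues, the
  top ⌊L/5⌋ or ⌊L/10⌋ by score give accuracy TP/(TP+FP); `Xd` contrasts
  the predicted-pair distance histogram with the all-pair histogram over
  15 bins of 4 Å (0–60 Å), $X_d = \sum_i (P^{pred}_i - P^{all}_i) /
  (15\, d_i)$ with $d_i$ the bin's upper bound normalized by 60 — zero
  when predictions are distance-blind, positive when enriched in short
  distances. Selection ties break by ascending pair index. Only Xd's
  zero point and ordering are asserted in tests; its absolute
  normalization has minor variants in the literature.
* `accuracyVsPercentile()`, `fScore()`, `distanceEnrichment()` (top-n
  short-distance fractions vs background with a 2×2 Pearson chi-square,
  no continuity correction).

## Interaction scoring

For two-molecule alignments (receptor + peptide style), `moleculeLabels`
mark the two blocks of columns and the predictor mask either allows all
other columns (`inter_and_intra`) or only the partner molecule
(`intermolecular_only`). `fitInteractionModel()` stores each column's
minimum-BIC fit; `loglikScore()` scores an aligned candidate pair by
summing, over columns, the log probability of the observed character
given the candidate's other columns. Class probabilities come from the
stored softmax restricted to the classes observed in training; each of
the 21 class probabilities then receives an additive pseudocount of
1/210 and the vector is renormalized (dividing by $1 + 21/210$), which
bounds every score away from $-\infty$. Applying the pseudocount after
rather than before the softmax is a documented choice; the all-zero
model then scores exactly $p\,\log\frac{1/21 + 1/210}{1 + 21/210}$ per
candidate, which the tests assert.

## Numerical and design choices

* Amino-acid order is alphabetical one-letter (A=1 … Y=20, gap=21) and
  recorded in every encoded object; results are invariant to the order.
* Ambiguity codes (B, Z, X, U, O) collapse to the gap state with a
  warning.
* Pairwise identity uses positions where both sequences are non-gap; a
  pair with no comparable positions scores 0.
* Column indices are 1-based in every user-facing report and always refer
  to the original, pre-filter alignment.
* All randomness flows through explicit seeds; `deriveSeed()` maps a
  master seed and a task counter to per-task seeds below $2^{31}$, and
  `runBenchmark()` derives every network/potential/chain seed that way,
  so a factorial run is reproducible end to end.
* BIC ties break toward the sparser model; degenerate (conserved)
  columns yield zero scores rather than errors.

## Problem sizes used in the validation suite

The packaged tests run the full generator scale throughout: 200-node
networks, 500 sequences, 100,000-sweep chains, and the regression method
at 200 columns with a 25-value lambda path down to the same
$\lambda_{\max}/100$ floor — one to two minutes per link map on one
core; the coarser path tracks the 100-value default's ranking closely
while keeping the suite fast. For quick
command-line experiments, `runBenchmark(scaleFactor = 0.25)` shrinks the
factorial (nodes scale linearly while sequences and the lambda grid are
floored at 60% and 40% so the scaled fits keep enough observations per
predictor); note that 50-node networks at density 0.25 are a much easier
target for plain MI than 200-node ones — fewer indirect paths and a
faster-mixing chain — so method orderings observed at reduced scale do
not transfer to the full benchmark.

## Known limitations

* No phylogenetic correction or sequence weighting: closely related
  sequences count as independent observations (the duplicate-sequence
  analysis quantifies the method's robustness to this, but a real
  correction is future work).
* No similarity-informed (BLOSUM-style) penalties; every character pair
  is equally distant.
* The regression is nodewise (one column at a time with averaged
  symmetrization), not a joint MRF estimate.
* Alignment-to-structure mapping must be supplied (or be the identity);
  the package does not align sequences to structures.
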