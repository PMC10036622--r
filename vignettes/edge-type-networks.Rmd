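---
title: "Edge-type network comparison: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-type network comparison: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etnet)
```

## The problem

Omics experiments on animal cohorts deliver a molecule × sample matrix per
condition (genotype × timepoint), with perhaps a dozen samples each. A
statistical-dependence network over the molecules can be inferred per
condition, but with so few samples both the individual edges and any
edge-by-edge comparison between conditions are noisy. `etnet` implements a
condition-level comparison: each network is reduced to the distribution of
its **edge types** — the categories defined by the unordered pair of the
endpoints' biological annotations — and the distributions, rather than the
edges, are compared.

## Mutual-information network inference

Dependence between molecules $i$ and $j$ is measured by mutual information,
$I(X;Y)=\sum_{uv}\hat p(u,v)\log\frac{\hat p(u,v)}{\hat p_x(u)\hat p_y(v)}$
(nats), which detects nonlinear as well as linear relationships — the
reason it is preferred here over Pearson correlation. The joint density is
estimated by B-spline fractional binning: each standardized sample value is
mapped linearly from its observed range onto the knot domain and spread
over up to $k$ adjacent bins by the order-$k$ B-spline basis (a partition
of unity), and the joint cell mass is the sample mean of the outer products
of the two weight rows. With $k=1$ this is an ordinary 2-D histogram, which
is the basis of the oracle tests: on bin-aligned data the estimator must
equal the contingency-table MI exactly.

Tunables, defaults, and why:

* **Spline order $k$** (default 3, dimensionless). Order 3 smooths the
  histogram enough to tame small-sample bias without oversmoothing;
  $k=1$ is kept as the exactly-testable special case.
* **Bin number $M$** (per pair). The original description determines $M$
  per variable pair but the cited rule is not reproducible; we therefore
  default to a documented, deterministic sample-size rule
  $M=\lceil \log_2 n\rceil + 1$ clamped to $[k,\,n/2]$, with `"sqrt"` and
  `"fixed:M"` selectable. Any monotone-in-$n$ rule that both variables
  share preserves the estimator's symmetry; which rule reproduces the
  original edge counts is unknowable from the text, and none of the
  package's conclusions depend on the choice.
* **Permutations $B$** (default 500). The null for independence is built
  by permuting $x$ only, $y$ fixed; $p$ = (# null MI > observed)/$B$. The
  plain ratio can be 0 — faithful to the stated method — and a
  $(c+1)/(B+1)$ variant is available via `mi_config(add_one = TRUE)`.
* **Threshold $p_0$** (default 0.05). Edge existence uses the strict
  inequality $p<p_0$.
* **Seeding.** Per-pair seeds are derived from the root seed and the
  sorted molecule IDs, so results are identical under any pair-evaluation
  order or matrix row order.

For the MI-difference test between conditions the resampling scheme is not
prescribed by the original description; we pool the paired $(x,y)$
observations of both conditions and re-split them at random into groups of
the original sizes. This preserves the within-sample pairing (the
dependence being tested) while enforcing the null that both conditions
share one joint distribution. The statistic is $|I_0-I_4|$.

## Edge typing and weighting

With $s$ node-type labels the catalog holds all unordered label pairs
including self-pairs, $t=s(s-1)/2+s$ (66 for the default 11 KEGG
metabolism classes). A molecule may carry several labels; an edge's ET set
is all pairwise combinations of the endpoints' labels, collapsed to
*distinct* unordered pairs, each weighted $1/\#E_{type}$ so every typed
edge contributes total weight 1. Collapsing before weighting matters: for
endpoints both labelled $\{A, C\}$ the set is $\{A\!-\!A, A\!-\!C,
C\!-\!C\}$ and each ET gets $1/3$, not $1/4$. Edges with an unannotated
endpoint are excluded from counts and reported separately, never silently
dropped.

For per-ET response histograms, A→A pairs are typed with the same
fractional weighting as present edges; this keeps the four-fate histogram
a partition of all typed pairs. Distance computations default to the
four-bin histogram, with a three-bin (response-edges-only) variant behind
`include_absent = FALSE`.

The ET graph density divides the weighted edge count of an ET by
$N_{ET}(N_{ET}-1)/2$, where $N_{ET}$ counts nodes carrying either of the
ET's labels. For a cross-type ET this denominator includes same-type pairs;
we implement the formula exactly as stated, with a tighter bipartite
denominator $N_aN_b$ available behind `bipartite = TRUE`.

## Comparison machinery

* **χ² histogram distance** $\tfrac12\sum_i (P_i-Q_i)^2/(P_i+Q_i)$ on
  normalized histograms: bounded in $[0,1]$, 0 iff equal, 1 iff disjoint;
  not a metric, and no triangle property is relied on.
* **Cramér–von Mises** two-sample test via the rank (midrank) form of the
  statistic, equal to the integrated squared ECDF difference over the
  pooled sample. ET distributions are made into samples by treating the
  catalog index as an ordinal value and expanding weighted counts rounded
  to a configurable resolution (default: nearest 1). This
  ordinal-expansion step is an interpretive choice — the original
  description applies a continuous-data test to categorical fingerprints
  without saying how — so reported $A^2$ values are comparable within the
  package but not bit-comparable to other implementations' tables. The
  asymptotic p-value centers and scales the finite-sample statistic to
  the limit law's mean $1/6$ and variance $1/45$ and evaluates the
  Brownian-bridge limit CDF (Bessel-$K$ series); a seeded permutation
  p-value is available for small samples.
* **Torgerson MDS** by eigendecomposition of the double-centered squared
  distance matrix; negative eigenvalues (the χ² distance need not be
  Euclidean) are truncated and reported via the `"eigenvalues"`
  attribute, and each coordinate column's largest-magnitude loading is
  made positive so different eigensolvers give identical maps.
* **Robustness scans** correlate (absolute Spearman) the per-ET density
  vector and each conventional per-node statistic vector against the
  reference threshold's vectors. Correlating scalar graph summaries is
  undefined, so per-node vectors are used for the conventional
  statistics; missing entries (isolated nodes, undefined ETs) are
  excluded pairwise.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the package targets: two
genotypes × two timepoints, 11–12 samples per condition, tens to hundreds
of molecules, multi-label annotations (default 80% single-, 20%
double-label over the 11 KEGG classes) and a planted dependence structure.
Planted pairs are linear ($x_j=\rho x_i+\sqrt{1-\rho^2}\epsilon$),
symmetric-quadratic, or XOR-like (random per-sample sign); the latter two
have (population) zero Pearson correlation, so recovering them exercises
exactly the advantage MI has over linear correlation. Condition differences
are encoded purely as planted-edge-set differences, mirroring the
P→P/P→A/A→P taxonomy. Default dependence strength is 0.95 — strong and
detectable at $n=12$, as planted ground truth should be.

What the generator does *not* emulate: realistic concentration scales or
count distributions (standardization removes scale anyway), correlated
measurement error across molecules, batch structure, or indirect
(conditional) dependence chains. Passing tests on these fixtures therefore
demonstrates correctness of the machinery and calibration of the tests,
not biological fidelity of any particular inferred network.

## Numerical and design notes

* Constant molecules cannot be standardized; they are excluded with a
  warning and reported, and their pairs are untested rather than A→A.
* B-spline evaluation nudges the domain maximum inwards by a relative
  $10^{-12}$ because the basis is right-open at the final knot.
* Zero joint cells contribute zero to the MI sum; the plug-in estimate is
  nonnegative up to ~$10^{-12}$ rounding.
* Exact recovery of planted fates in validation uses a Bonferroni-style
  threshold $p_0 = 0.05/\#\text{planted}$: at $p_0=0.05$ each truly
  independent pair still has a 5% false-positive chance, so family-wise
  exactness over 12–20 planted pairs requires the tighter threshold,
  while power is unaffected (at $n=500$, planted dependencies beat all
  500 permuted nulls).
* Net-change ranking ties break lexicographically by catalog index;
  MDS with an all-zero distance matrix returns the origin.
* Problem sizes in the test-suite and acceptance runs — up to 40
  molecules, $n\le 500$, $B=500$, 1000 calibration replicates — were
  chosen as the smallest sizes at which each property is
  well-identified (e.g. the binomial error of a calibration rate at 1000
  replicates is ±0.7pp); the architecture streams pairs and caches
  per-molecule weights, so transcriptome-scale runs are structurally
  supported but not exercised here.

## Known limitations

* No conditional-independence (partial-information) inference: edges
  reflect marginal dependence and may be indirect.
* No analytic MI bias correction; with $n\approx 12$ MI values are used
  only through their permutation ranks, never as effect sizes (edge
  intensities are deliberately dropped downstream).
* The CvM ordinal-expansion of weighted ET counts discards sub-integer
  weight detail at the default resolution.
* Degree-distribution comparisons default to the CvM test for internal
  consistency; the choice of test for that published comparison is not
  documented and KS is provided as an alternative.
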