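---
title: "Methods: phage-bacteria infection network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage-bacteria infection network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbin)
```

## The data model

The central object is the phage-bacteria infection matrix (PBIM): a binary
hosts x phages matrix in which cell $(h, p) = 1$ means phage $p$ produced
visible lysis on host strain $h$ in a double-layer agar spot test. Upstream
of the matrix sit the raw categorical scores: confluent (CL), semi-confluent
(SCL) and opaque (OL) lysis, countable plaques (TV), or resistance (R),
possibly replicated across several multiplicities of infection (MOI).
`binarize_lysis()` pools replicates with a logical OR — any evidence of
lysis at any MOI makes the pair sensitive — because a spot assay detects
permissiveness, not efficiency; efficiency-of-plating is explicitly out of
scope. A pair every one of whose replicates is missing stays `NA` and is
resolved only by row removal in `filter_matrix()`, never by imputation:
hosts not screened against the full panel are dropped first, then hosts
with no lysis at all (an all-zero row carries no profile information and
breaks Jaccard similarity). All-zero *columns* are retained with a warning,
since the panel of phages is fixed by design while the host collection is
an open sample.

## Infection profiles

Each phage's infection profile is the set of hosts it lyses; hosts dually
carry the set of phages lysing them. Profile dissimilarity is the Jaccard
distance $1 - |A \cap B| / |A \cup B|$ (`pairwise_jaccard()`), a metric on
sets, and profile groups come from complete-linkage agglomeration
(`hclust_complete()`). Complete linkage is the natural choice here: it
controls the *diameter* of a cluster, so members of a group are guaranteed
mutually similar profiles. The implementation is deliberately in-package
rather than a wrapper, because the merge tie-break is part of the contract:
among pairs at equal distance, the pair whose smallest member labels sort
lexicographically first merges, making dendrograms reproducible across
platforms (reference implementations leave ties undocumented). The tree is
cut to exactly `k` clusters with `k` supplied by the user — the study
convention is 4 phage clusters and 21 host clusters — because the source
analyses report counts, not a selection criterion; no automatic `k` is
offered. `principal_coordinates()` performs classical metric scaling of
the distance matrix (PCoA), the standard realization of "principal
components of a distance matrix"; negative eigenvalues, which Jaccard
distances can produce, are clamped to zero and excluded from the
variance-explained denominator.

Group-level target ranges (`group_target_summary()`) report the mean,
min-max range, and mean as a percent of the strains screened. With group
sizes of 2-5 phages a parametric confidence interval is not meaningful;
the min-max range reproduces every interval printed for this panel.
Presentation values round half-up; raw means are always retained, since
half-up rounding and the source tables disagree by one unit in one case
(a mean of 100.6 printed as 100).

## Nestedness: NODF

`nodf()` implements the paired overlap-and-decreasing-fill metric. For an
unordered pair of columns with fills $f_i > f_j > 0$, the pair scores
$100 \cdot |ones_i \cap ones_j| / f_j$; tied fills score 0 ("decreasing"
is strict). Row pairs are scored identically, and the components average
over pair counts. A perfectly nested (staircase) matrix with distinct
fills scores 100; a permutation matrix, all fills tied, scores 0. The
score depends only on fills and overlaps, so it is invariant under row and
column permutation — the test suite verifies this, verifies agreement with
a brute-force pair enumerator on hundreds of small random matrices, and
cross-checks the reference implementation in `vegan` (with its sorting
option enabled; its unsorted variant is position-dependent and is *not*
the standard metric). One subtlety uncovered during development: because
the components are pair *means*, duplicating a row can raise the row
component even though the twin pair itself scores 0 — the mirrored pairs
shift the average. The tests pin down the exact arithmetic rather than a
plausible-looking but false monotonicity.

## Modularity: Barber's Q

For a bipartite network, Barber's modularity for a partition that assigns
every host and phage a module label is

$$Q = \frac{1}{m}\sum_{i,j}\left(A_{ij} - \frac{k_i d_j}{m}\right)
      \delta(g_i, h_j)$$

with $m$ total interactions and $k_i, d_j$ the degrees. Only host-phage
co-membership contributes; the single-module partition cancels exactly to
0, a useful fixed point for testing. `optimize_modularity()` searches for
the maximizing partition by weighted label propagation: given the row
labels, each column's optimal module is independent of the other columns
(and vice versa), so alternating full sweeps are exact coordinate ascent;
a node whose best gain is non-positive goes to its own singleton module.
When no single-node move improves Q, an agglomerative stage repeatedly
applies the best module-pair merge while any merge improves Q (steepest
ascent). Moves that leave Q unchanged are rejected, which guarantees
termination; empty modules are compacted each round. The search runs from
20 restarts by default (the first from deterministic singleton rows, the
rest from seeded random groupings); per-restart scores are kept in the
result so the stochastic spread is inspectable, and restart $r$ draws its
seed from the master seed and $r$ alone, so enlarging the budget never
changes earlier restarts (hence never lowers the returned Q). On all
matrices up to 4x4 the optimizer is tested against exhaustive enumeration
of every joint set partition.

## Null models and significance

Three randomizations, in increasing stringency:

* **sim1** — keeps only the total fill; interactions land uniformly on
  cells.
* **sim8** — keeps the total fill; cells are drawn sequentially without
  replacement with weight proportional to (row total x column total).
* **curveball** — preserves both margin vectors exactly by repeatedly
  trading the non-shared partners of two random rows. The default of
  5 x (rows + columns) trade attempts per replicate mixes matrices at
  this scale comfortably and is configurable; each replicate re-randomizes
  the *observed* matrix, never a previous replicate.

`significance_test()` simulates `n_replicates` matrices (study convention:
1200), computes NODF or optimized modularity on each — null matrices get
the same restart budget as the observed one — and reports the one-tailed
(greater) add-one estimator $p = (1 + \#\{null \ge obs\})/(n + 1)$, which
can never return 0 and matches the "fewer than 5% of null scores above the
observed" thresholding convention; the 95th percentile of the null scores
is reported as that threshold. Replicate $i$ runs on an RNG sub-stream
seeded `seed + i`, so the ensemble is reproducible bit-for-bit and
independent of evaluation order. Calibration is tested: on unstructured
random matrices the NODF/sim1 test rejects at close to its nominal 5%
level (bounded at 7% over 200 seeds in the suite).

## Network view and bicliques

`build_graph()` turns the matrix into the bipartite infection network
(one edge per 1-cell), `rearrange_matrix()` degree-sorts rows and columns
for visual inspection of nesting (NODF is unaffected), and
`find_cliques()` enumerates *maximal bicliques* — host and phage subsets
with every cross pair an edge. In a bipartite graph no mixed triangle
exists, so a literal clique larger than one edge is impossible; the
"edge density 1" cluster concept maps to the biclique. Enumeration closes
every subset of the smaller side, which is exact and fast up to 16
entities there (8k-65k closures; a 13-phage panel needs 8191). Default
size thresholds of 2 hosts x 2 phages suppress the trivial stars.

## Supporting statistics

`friedman_test()` (tie-corrected chi-square form; $n(k-1)$ under perfect
concordance), `dunn_posthoc()` (rank-sum differences standardized by
$\sqrt{nk(k+1)/6}$, Bonferroni-adjusted over all pairs — the convention of
the prevailing GUI statistics software), `mantel_test()` (Pearson
correlation of lower triangles, one-tailed add-one permutation p under
simultaneous row/column relabeling), and `spearman_test()` (mid-rank
Pearson; exact enumeration $n \le 8$, else normal approximation) are
implemented in-package and validated in the tests against base-R and
`vegan` references and closed forms. The chi-square (not F) Friedman
variant is used because the study-scale statistics are printed on the
chi-square scale. Genetic distances for the Mantel analysis are consumed
precomputed; genome alignment is out of scope.

## The synthetic generator

`gen_one_to_one()`, `gen_modular()`, `gen_nested()` and `gen_random()`
produce the four canonical infection-network structures with known ground
truth (planted partitions, containment chains), which the tests exploit:
closed-form Q of $(k-1)/k$ for $k$ equal complete blocks, NODF 100 for
distinct-fill staircases, NODF 0 for permutation matrices, monotone NODF
decay as nested matrices are noised toward randomness.

`gen_salmonella_like()` emulates the filtered study matrix: 133 hosts x 13
phages whose column sums equal the published target-range vector exactly
(1001 interactions). Ones are placed per phage by weighted sampling
without replacement over a graded host-susceptibility weight,
$w \propto e^{4u}$, $u$ uniform on $[0,1]$ — about a 55-fold ratio between
the most and least susceptible strain, a gradient strong enough to produce
the generalist-to-specialist nesting such panels show. All-zero hosts are
repaired by moving one interaction from a multiply-infected host within
the same column, so column margins stay exact while row margins remain
distributional (the true row margins are not published in printable form).
Host serovars and isolate origins are drawn from the published frequency
lists.

What the emulator does and does not show: its matrices reproduce the
scale, margins, strong nestedness and the null-model significance
*pattern* of the real panel (nested against sim1 and sim8, not against
curveball — margin-driven nesting), but they are slightly more nested and
less modular than the real matrix, and their optimized modularity is not
significant against the nulls, unlike the study matrix whose modular
signal comes from real biological block structure the susceptibility
gradient does not encode. Tests passing on synthetic data therefore
validate the machinery and its calibration, not biological conclusions.

## Pipeline, problem sizes, determinism

`run_pipeline()` chains the stages (ingest, filter, cluster, summarize,
NODF, modularity, null ensembles, bicliques, optional Mantel) and writes
stable file names under one output directory; identical configuration and
seed give byte-identical reports (no timestamps in the body). Defaults
mirror the study conventions (1200 replicates, all three null models,
4/21 clusters, 20 restarts, 9999 Mantel permutations). The package's own
reporting choices for routine runs keep compute modest: the acceptance
script uses 1200 replicates for NODF ensembles and 199 replicates with 5
optimizer restarts for the much costlier modularity ensembles; the test
suite exercises oracle equivalence at up to 6x6 (NODF, 200 seeds) and 4x4
(exhaustive modularity), and type-I calibration at 200 seeds x 199
replicates.

## Known limitations

* The modularity optimizer is a local search; global optimality is only
  guaranteed where verified by enumeration (tiny matrices). Restarts
  mitigate but do not eliminate this — the per-restart spread is the
  diagnostic.
* Biclique enumeration is exponential in the smaller side and capped at
  16 entities there.
* `sim8`'s sequential weighted draw is one of several "proportional to
  margins" conventions in the ecology literature; it is the one matching
  an exact enumeration oracle and is stated as such.
* The host-cluster count (21) reuses the user-supplied-k interface; no
  claim is made that an automatic criterion would choose it.
* Lysis categories are collapsed to presence/absence; partial-resistance
  gradations (OL vs CL) are deliberately discarded.
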