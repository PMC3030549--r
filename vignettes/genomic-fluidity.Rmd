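---
title: "Genomic fluidity: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic fluidity: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidity)
```

## The statistic

For a group of $N$ genomes, each reduced to its set of gene families,
genomic fluidity is the average pairwise dissimilarity at the gene level:

$$\hat\varphi \;=\; \frac{2}{N(N-1)} \sum_{k<l}
  \frac{U_k + U_l}{M_k + M_l},$$

where $M_k$ is the number of gene families in genome $k$ and $U_k$ the
number found in $k$ but not in its partner $l$. Fluidity is 0 when all
genomes have identical gene content and 1 when every pair is disjoint.
Because it is an average over pairs (a U-statistic), the same formula
estimates the same quantity whether the group is an entire population or a
small sample from it — which is why it is estimable from a handful of
genomes, unlike pan or core genome sizes.

`fluidity()` computes the pair ratios through a sparse family-by-genome
incidence matrix (one cross-product gives all shared counts), so groups of
hundreds of genomes with thousands of families each are cheap.

### Variance: the leave-one-out jackknife

`jackknife_variance()` implements

$$\hat\sigma^2 = \frac{N-1}{N} \sum_{i=1}^{N}
  \left(\hat\varphi_{(i)} - \hat\varphi\right)^2,
\qquad
\hat\varphi_{(i)} = \frac{2}{(N-1)(N-2)} \sum_{\substack{k<l\\ k\neq i\neq l}}
  \frac{U_k + U_l}{M_k + M_l},$$

with deviations centered on the full-group estimate $\hat\varphi$. The
textbook jackknife centers on the mean of the leave-one-out values; since
$\sum_i (x_i - c)^2$ is minimized at the mean, centering on
$\hat\varphi$ can only make the estimate slightly larger, i.e. it is a
mildly conservative variant. We keep this form deliberately — it is the
variance the downstream z-test and all reported uncertainties use — and
our type-I-error simulations (see `test-acceptance.R`) confirm the
resulting test holds its nominal 5% level at $N = 10$ genomes per group.
The jackknife needs at least 3 genomes; with exactly 2,
`estimate_fluidity()` returns the point estimate with the variance marked
unavailable rather than guessing.

### Comparing groups

Fluidity estimates are asymptotically normal, so
`compare_fluidity()` uses a plain two-sample two-sided z-test,

$$z = \frac{\hat\varphi_1 - \hat\varphi_2}
  {\sqrt{\hat\sigma_1^2 + \hat\sigma_2^2}},$$

with the standard normal reference. The jackknife variances already absorb
the effective degrees of freedom, so no t-type correction is applied.
If both variances are exactly zero while the estimates differ, the test is
undefined and the function fails loudly instead of reporting a spurious
$p = 0$. No multiple-testing correction is applied to pairwise matrices
(`rank_significance()`): flags are per-pair at a configurable
$\alpha = 0.05$.

### Subsampling convergence and "total" variance

`subsample_convergence()` draws, for each size $m$, random $m$-genome
subsets and reports the mean estimate together with

$$\text{total SD} = \sqrt{\operatorname{Var}_{\text{between subsamples}}
  [\hat\varphi_m] + \overline{\hat\sigma^2_m}},$$

the between-subsample spread plus the mean within-subsample jackknife
variance. These are the two distinct sources of uncertainty when only $m$
of the genomes are examined — which subset was drawn, and how well any
subset of that size pins down the population value — and the sum counts
each exactly once. At $m = N$ only one subsample exists and the first term
vanishes.

A useful identity for interpreting these tables: averaged over *all*
$m$-subsets, $\hat\varphi_m$ equals the full-group $\hat\varphi_N$ exactly,
because every genome pair appears in the same number of subsets. The mean
of a subsampling column therefore converges to the full-group estimate,
whose own sampling error is the full-group jackknife variance; the
unbiasedness checks in the test suite use
$\sqrt{\hat\sigma^2_N + \text{Var}_{\text{between}}/R}$ (with a
conservative upper bound for the between term) as the standard error of a
subsample average over $R$ replicates.

## Gene families from alignments

Fluidity is defined over gene families, which must first be built from
all-vs-all protein alignments. The pipeline choices:

* **Homology criterion.** A gene pair is homologous if a single alignment
  covers more than fraction $c$ of *each* gene's length and its identity
  exceeds $i$ — both strict inequalities. Coverage is the aligned span
  `(end - start + 1) / length`; when a pair has several HSPs only the best
  (smallest E-value) qualifying one represents the pair, with no HSP
  tiling. One qualifying record in either direction suffices; the
  criterion is already symmetric in the two genes' lengths.
* **Strict-clique clustering.** Edges are processed in increasing E-value
  order so weak alignments cannot disrupt families seeded by strong ones.
  A free gene joins an existing family only if it has a qualifying edge to
  every member; edges between two already-assigned genes are skipped
  (families never merge); leftover genes become singletons. E-value ties
  are broken by identity (descending), then minimum coverage (descending),
  then lexicographic pair, making the catalog fully deterministic. The
  output is a partition — every gene in exactly one family — and every
  multi-member family is a clique, both asserted exhaustively in the
  tests, which also verify the partition against an independently written
  naive implementation on hundreds of random instances.
* Orthologs, paralogs and xenologs are deliberately not distinguished;
  within-genome paralogs collapse to a single family occurrence when
  genome family sets are formed.

Raising either threshold can only remove edges (asserted as a monotone
property), which splits families; family counts rise and fluidity rises
with them. The `run_sweep()` module makes this explicit: magnitudes of
$\hat\varphi$ shift across an inclusive $(i, c)$ grid, but the *rank
ordering* of groups is the robust quantity. Note that the inclusive range
0.5–0.8 in steps of 0.02 has 16 values per axis, hence 256 grid points;
descriptions of similar sweeps sometimes quote 225 (15 × 15) trials, a
bookkeeping discrepancy we resolve in favor of the printed range and
document here rather than silently matching either count.

## The synthetic population model

`species_template()` fixes what a population must honor: pan size $P$
(total families), core size $C$ (families at frequency 1), expected genome
size $G$, and an accessory frequency range $[f_{\min}, f_{\max}]$ split
into $K$ classes. `build_distribution()` places the accessory families on
log-spaced frequencies with counts $n_j \propto f_j^{-\alpha}$, solving
$\alpha$ numerically (log-sum-exp weights, bisection via `uniroot`) so
that $\sum_j n_j f_j = G - C$, then rounds by largest remainder and
repairs single-family transfers until the expected size is within 0.1% of
target. Genomes are sampled by independent per-family inclusion:
family $j$ enters each genome with probability $f_j$, sampled sparsely
(one binomial count per class, then uniform index draws), so classes with
$10^7$ families are never enumerated. Genome sizes therefore *fluctuate*
around $G$ with variance $\sum_j n_j f_j (1 - f_j)$; conditioning on an
exact size of 2000 would distort the per-family frequencies, so we do not.
Each genome draws from its own substream derived deterministically from
the root seed, so genome $g$ is identical whether 10 or 1000 genomes are
requested.

Under this sampling model the population's true fluidity has a closed
form, the ratio of the expected unique-family count to the expected
genome size for a random pair:

$$\varphi_{\text{true}} =
  \frac{\sum_j n_j f_j (1 - f_j)}{\sum_j n_j f_j}.$$

### The built-in species

* **speciesA**: $P = 10^5$, $C = 10^3$, $G = 2000$, accessory frequencies
  $10^{-4}$–0.99 in 40 classes; $\varphi_{\text{true}} \approx 0.313$.
* **speciesC**: same $P$, $C$, $G$ as A but a different shape
  ($10^{-3}$–0.99, 30 classes); $\varphi_{\text{true}} \approx 0.387$.
  The $\ge 5$-point gap makes A and C separable by the z-test from about
  10 genomes per group, even though their pan and core sizes are
  identical — fluidity detects what rarefaction cannot.
* **speciesB**: $P = 10^7$, $C = 10$, $G = 2000$. This population is
  *not* a single power law. A power law constrained to those sizes has a
  very different visible frequency profile from speciesA (its expected
  100-genome singleton count is about 2.5-fold higher), which would make
  the two trivially distinguishable and defeat the point of the
  demonstration: that radically different pan/core sizes can be
  *unobservable*. Instead `companion_distribution()` derives speciesB
  from speciesA by three mass-conserving moves: 990 of the 1000 core
  families are relaxed to frequency $1 - 10^{-5}$ (still present in
  essentially every sampled genome); 0.5 expected genes of mass (5000
  families) are trimmed from A's rarest class ($f = 10^{-4}$); and the
  same mass is spread over the ~9.9 million ultra-rare tail families
  (frequencies $10^{-9}$–$10^{-5}$) needed to reach $P = 10^7$. Because a
  family at frequency $f \ll 1/n$ appears in an $n$-genome sample with
  probability $\approx n f$, any mass-preserving rearrangement among such
  families leaves every expected observable — spectrum bins, pan and core
  curves — unchanged to first order. The construction yields pan $10^7$
  and core 10 exactly, expected genome size within 0.1% of 2000, and
  expected 100-genome observables matching speciesA's to better than
  0.1%.

### What the simulator does and does not emulate

The generator reproduces the statistical structure that matters for the
estimators: a frequency spectrum with a core spike, a broad accessory
slope and an undetectable rare tail, with independent genomes. It does not
emulate phylogenetic correlation between genomes (real isolates are
related, so their family sets are not independent draws), linkage between
gene families, annotation error, or alignment noise — the gene families of
simulated genomes are known exactly rather than reconstructed from
alignments. Passing tests therefore demonstrate properties of the
estimators under the stated sampling model, not robustness to those
real-data complications; the threshold-sweep machinery addresses the
alignment-parameter side separately on constructed fixtures.

## Numerical and interface choices

* Pair ratios come from one sparse cross-product; all leave-one-out values
  reuse the same ratio matrix, so the jackknife costs $O(N^2)$ after it.
* `build_distribution()` rejects infeasible templates (accessory mass
  outside $[(P-C)f_{\min}, (P-C)f_{\max}]$) with the violated bound named.
* Degenerate inputs fail explicitly: fewer than 2 genomes for
  $\hat\varphi$, fewer than 3 for the jackknife, zero-variance
  comparisons with differing estimates.
* Identifiers are opaque UTF-8 strings throughout; outputs are TSV with
  `#` metadata headers (seed, parameters) or JSON for scalar results, and
  every writer round-trips through its reader.
* Randomized operations (`sample_genomes()`, `subsample_convergence()`,
  `rarefaction_curves()`) take explicit seeds, restore the caller's RNG
  state, and are bit-reproducible given (input, seed).

## Problem sizes used by the checks

The bundled verification suite runs at deliberately modest scales chosen
to exercise the claims without waste: 1000 sampled genomes for the
genome-size calibration; 50 genomes × 200 subsamples for unbiasedness at
$m \in \{5, 10, 20\}$; 40 replicate pairs of 100-genome samples for the
speciesA/speciesB indistinguishability checks; 500 replicate pairs of
10-genome groups for the type-I error of the z-test; 500 random instances
(≤ 12 genes) for the clustering oracle; and a 16-point threshold grid over
three constructed groups for rank-ordering robustness.

## Known limitations

* Fluidity depends on the phylogenetic breadth of the group; comparing
  groups of very different internal diversity invites normalization by
  average phylogenetic distance, which this package does not attempt.
* The jackknife normal approximation is asymptotic; with very few genomes
  (N near 3) or near-degenerate groups the z-test should be read
  cautiously, and high-variance groups may simply be unrankable — the
  honest outcome the significance matrix reports.
* The clusterer's greedy, order-dependent rule is faithful to its
  specification but is not a globally optimal clique partition; its
  determinism, not optimality, is the guarantee.
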