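---
title: "Methods: compositional networks, robustness and knockouts in mosqnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional networks, robustness and knockouts in mosqnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosqnet)
```

mosqnet analyses genus-level microbiome count tables from small two-group
study designs — typically ten individual insects per site, a handful of
sterile-water extraction controls, and a dominant endosymbiont occupying
most of the reads. This vignette documents the models and the numerical
and design decisions behind each stage, in the order the pipeline runs
them.

## The synthetic study

Real sequencing data are not required anywhere in the package: the
generator in `synth_spec()`/`generate_table()` produces tables with the
statistical structure the analysis assumes, plus a *planted* interaction
network that downstream inference can be scored against.

The generative model is log-normal–multinomial. For each group, active
taxa (the dominant taxon, a shared core, and that group's accessory
genera) receive per-sample log-abundances from a multivariate normal.
Ordinary taxa have unit log-variance; a planted pair $(i, j)$ with sign
$s$ and effect size $e$ contributes an off-diagonal covariance $s \cdot e$
(so with unit variances $e$ *is* the planted log-scale correlation). If
planting leaves the covariance non-positive-definite, a minimal diagonal
ridge restores it. Abundances are exponentiated, closed to proportions,
and read out by multinomial sampling at the configured depth, so
biological row sums equal the depth exactly. This is the same
log-correlation-under-closure world that SparCC's own derivation assumes,
which is precisely why it is the right test bed for it.

Defaults encode the study conditions the package emulates: 2 groups × 10
samples, 15 shared core genera, 100 vs 61 group-specific accessory
genera, dominant fraction 0.9, 4 negative controls carrying 2
contaminant-only taxa, 50,000 reads per sample (per-sample depths are
unreported in this kind of study; 50k is a realistic ONT-scale choice),
planted effect size 0.8 (calibrated once with a pilot run so that planted
pairs are recoverable at 20 samples, then frozen). A single integer seed
drives every random draw.

The dominant taxon gets near-zero log-variance ($10^{-4}$). This
reproduces, by construction, the well-known phenomenon that dominant,
low-variance genera (e.g. *Wolbachia*) are absent from inferred
co-occurrence networks: a taxon whose log-abundance barely varies carries
no identifiable basis variance (see the SparCC guard below).

**What the generator does not emulate:** taxonomic misclassification
noise, chimeras, overdispersed library sizes, rank-abundance tails (all
non-dominant taxa share one abundance scale), or rare-taxon sparsity
patterns of real amplicon data. Consequently the demo networks are
denser than real mosquito co-occurrence networks — with 10 samples per
group, correlation estimates are noisy and many pairs cross the |r| ≥ 0.5
threshold; in real tables most genera are too sparse to do so. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative model, not expected edge counts on field data.

## Contaminant filtering

The prevalence method classifies a taxon by contrasting its
presence/absence (count ≥ 1; no relative-abundance floor) in controls
versus biological samples. The score is the one-sided Fisher exact tail
probability of control enrichment at least as extreme, computed on the
2×2 presence table — exact at the n ≈ 14-sample scale of extraction
controls, and a deliberate, documented approximation to the chi-square
style score of the reference implementation of the prevalence method. A
taxon is flagged when score < 0.5 (configurable), and flagged taxa are
removed before analysis by default (removal versus mere flagging is
configurable, since practice varies).

Rarefaction curves use the exact hypergeometric expectation
$E[S_d] = \sum_t \left(1 - \binom{N-n_t}{d}\big/\binom{N}{d}\right)$
by default, which removes any sensitivity to a Monte-Carlo replicate
count; a seeded Monte-Carlo estimator exists for cross-checking.

## Diversity

Shannon entropy uses log base 2 (bits), matching the convention of the
QIIME2 ecosystem these tables usually come from; the base is an argument.
Pielou's evenness is undefined at observed richness 1 and reported `NA`;
fully tied group comparisons return H = 0, p = 1 under the tie
correction. Bray–Curtis is computed on raw counts without prior
rarefaction; Jaccard on presence (count ≥ 1). Two all-zero samples get
distance 0 with a warning.

PERMANOVA uses the standard distance-based pseudo-F and the
$(1+x)/(1+N)$ permutation estimator so p is never 0. For two groups with
few samples, all distinct label splits are enumerated exactly
(complementary splits identified when group sizes are equal); with 2v2
samples this gives the exact support {1/3, 2/3, 1}. Monte-Carlo
permutations (default 999, seeded) are used otherwise; exhaustive
enumeration is restricted to two groups because the two-site design is
the package's target. Beta dispersion goes through `vegan::betadisper`
with `type = "centroid"` — distance to the group centroid in the
negative-eigenvalue-corrected PCoA space — so the reported quantity
matches its documented definition. PCoA itself is classical scaling;
negative eigenvalues are reported, not hidden. UPGMA (average linkage)
clustering is emitted with Newick export.

## SparCC

The estimator is implemented from first principles. Fractions are
Dirichlet posterior means $(x + 1)/\sum(x + 1)$ for point estimates and
single Dirichlet draws for resamples (pseudocount configurable). The
variation matrix is computed from the covariance of log fractions. Basis
variances solve the sparsity linear system (diagonal $D-1$, off-diagonal
1); exclusion of a pair zeroes its off-diagonal entries, decrements the
two diagonals, and removes its $t$ contribution from the row sums. The
iterative loop excludes the strongest pair while its |r| exceeds 0.1, up
to 10 exclusions (the estimator's canonical settings — the upstream
studies name the method but not its parameters, so the canonical defaults
are declared and configurable). The final matrix is the elementwise
*median* over 20 Dirichlet resamples, which is robust to occasional
degenerate solves. No bootstrap p-values are computed: the edge criterion
is the magnitude threshold |r| ≥ 0.5 alone, bounds inclusive.

Numerical guards, in order:

* **Informative-taxa guard.** Taxa that are all-zero, have zero count
  variance, or whose log-fraction variance is below
  `max(min_variance, 0.05 × median log-fraction variance)` (default
  absolute floor $10^{-3}$) are dropped and logged. The relative
  component makes the rule scale-free; the rationale is that the
  correlation normalization divides by $\sqrt{\hat\omega}$, so a
  near-constant taxon's unidentifiable basis variance would only produce
  clipped ±1 artifacts. This is also the mechanism by which knocked-out
  (all-zero) taxa and dominant endosymbionts vanish from inferred
  networks.
* **Omega floor.** Non-positive basis-variance estimates are floored at
  $10^{-6}$ before the square root; occurrences are recorded.
* **Exclusion sanity.** A pair is not excluded if that would leave a
  taxon without partners (singular system) or fewer than 4 connected
  taxa; a failed solve reverts the exclusion and stops the loop.
* Correlations are clipped to $[-1, 1]$ and the diagonal forced to 1.

The $D = 3$ closed form $\omega_1 = (t_{12} + t_{13} - t_{23})/2$ is kept
as an algebraic oracle in the test suite and must agree with the linear
solve to $10^{-10}$.

## Networks and topology

Networks are built over taxa with at least one |r| ≥ 0.5 edge; isolated
taxa are dropped (the "connected nodes" convention of topology tables).
Signs are node/edge *attributes*, never filters — negative edges stay in
the data structure; the GraphML/GEXF writers take a `positive_only` flag
for figure-style exports.

Metric conventions, chosen where the convention is genuinely open:

* Degree, betweenness (normalized, unweighted shortest paths), closeness
  (normalized within each node's component; harmonic aggregation across
  components deliberately off), eigenvector centrality on |r| weights.
* Eigenvector centrality is computed by power iteration to $10^{-8}$ on
  the shifted matrix $A + cI$ with $c$ the maximum weighted degree: the
  shift preserves eigenvectors while breaking the ± eigenvalue symmetry
  of bipartite graphs (a star would otherwise oscillate forever), and a
  deterministic uniform start makes runs bit-reproducible.
* Diameter is reported for the largest connected component, unweighted —
  these networks are fragmented, so a global diameter would be
  undefined.
* The clustering coefficient is the unweighted mean local coefficient
  with degree < 2 nodes contributing 0 (the Gephi statistic); global
  transitivity is also emitted for reference.
* Modularity and module count come from Louvain on |r| weights at
  resolution 1, run under a fixed derived seed so results are
  reproducible; size-2 modules count.
* Average degree is reported at 3 decimals and sign percentages at 1
  decimal, matching how such tables are printed; the identities
  `average_degree = 2E/N` and `pct_positive + pct_negative = 100` are
  asserted in tests.

## Network comparison

Most-central node sets are "strictly above the empirical 75th percentile"
(linear-interpolation quantile; ties at the threshold excluded, so a
constant centrality yields an empty set — both choices logged and
configurable). The Jaccard index of two sets is compared against an
exact null: both sets drawn uniformly without replacement from the union
of the two networks' node names with sizes fixed at the observed values.
The overlap is then hypergeometric and, because J is monotone in the
overlap, $P(J \le j)$ and $P(J \ge j)$ (each including the observed
value) follow by direct pmf summation — no simulation. Hub taxa are
nodes in the top quartile of degree, betweenness and eigenvector
centrality simultaneously; the measure set is configurable since
comparison frameworks vary in their hub rule.

## Robustness

Attacks remove nodes one at a time: uniformly at random (seeded), by
precomputed degree or betweenness ranking, or cascading (betweenness
recomputed after every removal). Ties break lexicographically by taxon
name for reproducibility. Connectivity loss is the pair-connectivity
functional $1 - \text{(connected pairs)}/\text{(initial connected
pairs)}$ — well-defined and monotone on fragmented graphs; the LCC-based
loss is emitted alongside because reference implementations differ. The
80%-disconnection point is the smallest removed fraction whose loss
reaches 0.8.

Node addition attaches each new node by `m` edges (default 1) to
uniformly chosen existing nodes, recording LCC size and APL (mean
shortest path within the LCC) after every addition; the grid
{100, 300, 500, 700, 1000} is run as independent replicates per grid
size. With `m = 1` additions can only extend components, never merge
them — so LCC growth is monotone; `m ≥ 2` permits bridging and is
available because the "random node introduction" of published analyses
does not pin the attachment count. Paired step series are compared with
the Wilcoxon signed-rank test: zero differences are dropped, and for up
to 25 informative pairs the exact two-sided p is computed by a
dynamic-programming convolution over doubled (tie-averaged) ranks — valid
under ties, unlike the textbook exact tables — with the normal
approximation beyond. BH adjustment is applied across the tested
metric×grid family, and a seeded percentile bootstrap (2.5/97.5, 1000
draws) gives the CI of the mean difference.

## Knockouts

A knockout zeroes one taxon's counts in every sample (the column is
retained; the zero-variance guard then removes it from SparCC input, so
it vanishes from re-inferred networks). Knockouts are single-taxon and
independent, never cumulative, and the baseline and depleted runs share
the same Dirichlet-resampling seed so that topology differences are
attributable to the knockout rather than resampling noise. Reports
compare topology before/after per group, list emergent edges split by
sign and emergent taxa (set algebra over name pairs), and re-run all four
attack strategies on baseline and depleted networks.

## Pipeline

`run_config()`/`run_all()` (and the thin CLI `inst/cli/mosqnet.R`)
execute the stages in order with per-stage seeds derived from one master
seed by fixed offsets. Every output file is a TSV/Newick/GraphML/GEXF
under the output directory and is listed in a manifest with an MD5
checksum; identical config and seed give identical checksums, which the
test suite asserts. Unknown config keys are rejected rather than
ignored.

## Problem sizes in the test suite

The suite keeps oracle comparisons honest but small, by choice: graph
metrics, attack curves, UPGMA and PCoA are checked against naive
brute-force implementations (Floyd–Warshall, explicit path counting,
exhaustive partition search for modularity, $O(n^3)$ agglomeration,
direct Gram-matrix eigendecomposition) on hundreds of random instances of
≤ 12 nodes; SparCC calibration uses 20 generator seeds at 20 samples ×
~20 taxa; PERMANOVA and Kruskal–Wallis type-I error use 200 null
simulations at 12 samples drawn from a single RNG stream; the full demo
pipeline runs twice at study scale to assert byte-identical manifests.

## Known limitations

* SparCC at 10 samples per group has high estimator variance; demo
  networks are denser than real ones (see the generator section). The
  package reports what the estimator produces rather than post-filtering
  edges by bootstrap significance, because the magnitude threshold is the
  published criterion.
* The exhaustive PERMANOVA mode covers two groups only.
* Closeness on fragmented graphs is per-component; cross-component
  comparisons of closeness values are not meaningful.
* The contaminant score is a Fisher-exact realization of the prevalence
  contrast, not a reimplementation of any specific package's statistic.
* No phylogeny-aware diversity metrics: no tree exists at genus level
  here.
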