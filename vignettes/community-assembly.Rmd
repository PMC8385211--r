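---
title: "Inferring community assembly processes and co-occurrence structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes and co-occurrence structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microassembly)
```

# The inference problem

A microbial survey delivers an OTU-by-sample count table, a phylogeny over
the OTUs, and sample metadata (season, temperature, nutrients). Two
complementary questions follow. First, *which ecological processes
assembled these communities* — deterministic environmental filtering
(selection) or stochastic processes (dispersal and drift)? Second, *what
co-occurrence structure do the surviving taxa form*, and how does it
differ between the abundant core and the rare biosphere? This vignette
describes the models the package implements, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the numerical choices a user may want to audit.

# Rare and abundant taxa

Classification uses each OTU's minimum and maximum relative abundance
across samples against two cuts, `rare_cut = 1e-4` (0.01%) and
`abundant_cut = 1e-2` (1%), both stored as fractions:

| condition on (min, max) | category |
|---|---|
| max ≥ 1%, min ≥ 1% | AAT (always abundant) |
| max ≥ 1%, min ≥ 0.01% | CAT (conditionally abundant) |
| max ≥ 1%, min < 0.01% | CRAT (conditionally rare and abundant) |
| max < 1%, min ≥ 0.01% | MT (moderate) |
| max < 0.01% | ART (always rare) |
| max < 1% otherwise | CRT (conditionally rare) |

The boundary semantics follow the printed inequalities of the
conventional scheme: the abundant and lower-rare bounds are inclusive
("≥"), the rare conditions strict ("<"), so exactly 1e-4 everywhere is MT
and exactly 1e-2 everywhere is AAT. Testing `max ≥ abundant_cut` first
resolves the overlap between the CRAT and CRT plain-language definitions.
All-zero OTUs fall out as ART (min = max = 0) and are flagged rather than
dropped, so category counts always total the table's OTUs. The coarse
roll-up is AT = {AAT, CAT, CRAT, MT}, RT = {ART, CRT}.

Relative abundances are computed *after* rarefaction: depth normalization
(without replacement, i.e. multivariate hypergeometric — `rarefy_counts()`
offers no with-replacement mode) precedes every analysis, and the
pipeline enforces that order.

# The null-model machinery

## betaMNTD and betaNTI

For communities a, b with cophenetic distances d(i, j),

$$\beta MNTD(a,b) = \tfrac12\Big[\sum_{i\in a} w_i \min_{j\in b} d(i,j)
  + \sum_{j\in b} w_j \min_{i\in a} d(i,j)\Big],$$

with weights w either relative abundances renormalized over present OTUs
(`weighted = TRUE`, the default) or uniform over present OTUs. The null
model is the *taxa shuffle*: one random permutation of tip identities
applied jointly to rows and columns of the distance matrix per replicate,
leaving richness and abundances untouched; each replicate re-evaluates
every sample pair, so all pairs share the same null draws (the standard
formulation, and the one that keeps 999 replicates affordable).
βNTI is the z-score of the observed value against the replicate
distribution. A degenerate null (σ = 0, e.g. two identical samples)
yields `NA`, reported separately — never ±∞.

## RC-Bray

Null communities preserve observed richness and total abundance: species
are drawn without replacement with probability proportional to
metacommunity occupancy frequency, each drawn species seats one
individual, and the remainder is filled multinomially by metacommunity
relative abundance. The metacommunity is the set of samples in the
analyzed table, so a per-season or per-subcommunity run uses its own
pool. RC = 2·[(#{null BC < obs} + ½·#{null BC = obs}) / reps] − 1, ties
at half weight. Sub-seeds are keyed on the unordered *pair of sample
identifiers* and the two null communities are drawn in lexicographic
order, so RC(a, b) = RC(b, a) exactly and results are independent of
sample order in the table.

## Process partition

Per pair: βNTI > +2 → variable selection; βNTI < −2 → homogeneous
selection; otherwise RC > +0.95 → dispersal limitation, RC < −0.95 →
homogenizing dispersal, else undominated. Fractions are reported for all
pairs, within-group pairs and between-group pairs; `undefined` pairs
(degenerate βNTI null) are excluded from the denominators and counted
alongside. Dispersal limitation is a fully reachable category even though
many surveys never populate it.

Subcommunity runs (CRT / ART / AT) operate on the pruned tree with
abundances renormalized within the subcommunity; samples with no reads in
a subcommunity are excluded from that run, since βMNTD is undefined for
an empty community.

## Niche optima and phylogenetic signal

An OTU's niche optimum is its relative-abundance-weighted mean
environment. The correlogram bins OTU pairs into equal-frequency
phylogenetic-distance classes and, per class k, computes
r_k = −cor(niche distance, class-k indicator) over all pairs, so positive
r at short distances means closely related OTUs hold similar niches.
p-values are two-sided permutation probabilities with optima permuted
across tips and class membership fixed. With a single class the statistic
degenerates to an indicator with zero variance, so interpret n_classes ≥ 2;
constant optima return a flagged all-`NA` result.

# The co-occurrence network

OTUs with more than 20 reads in total (`min_total = 21`, applied to the
pooled metacommunity before correlation) are correlated pairwise with the
mid-rank Spearman coefficient; the two-sided p comes from the
t approximation with n − 2 degrees of freedom, which is accurate at
survey sample sizes (n ≈ 48) where exact enumeration is infeasible. Edges
require |rho| > 0.8 *and* p < 0.01; no multiple-testing correction is
applied by default, mirroring how such networks are conventionally built,
and a Benjamini–Hochberg option (`adjust_p = TRUE`) is exposed for users
who want the corrected variant. Isolated nodes are dropped from the graph
but counted in the report.

Conventions the metric names alone do not pin down: betweenness is
normalized by (n−1)(n−2)/2 within each connected component; closeness is
(reachable − 1)/Σ distances within the component; eigenvector centrality
is the principal adjacency eigenvector of the largest component at unit
L2 norm, zero elsewhere; the clustering coefficient is the mean local
value with degree < 2 nodes contributing 0; diameter and average path
length are hop counts on the largest component. The power-law fit
regresses log10 frequency on log10 degree over raw integer degrees and
reports slope alongside R², so a flat (slope ≈ 0) perfect fit is not
mistaken for scale-freeness. Small-world comparisons use G(n, m)
Erdős–Rényi graphs with matching node and edge counts.

Natural connectivity is computed from the adjacency spectrum via a
log-sum-exp shift (exact for the edgeless graph: 0). The robustness
default removes random nodes over fractions 0–0.8 in 17 steps with
replicated nested removal orders; hub-first (`degree_descending`) removal
is deterministic. Modularity uses seeded Louvain; enrichment labels come
from two-sided Wilcoxon rank-sum tests on relative abundances (exact when
the pooled n ≤ 12 without ties, otherwise normal approximation with tie
and continuity corrections), with the significant OTU assigned to the
group holding the larger mean rank.

# The synthetic metacommunity generator

The generator emulates the *post-OTU-table* state of a two-season,
24-stations-per-season marine survey: ~3,000 OTUs at
20,446 reads/sample by default, a strongly skewed abundance distribution,
and phylogenetically conserved thermal niches. It does **not** emulate
sequencing (no reads, chimeras or OTU picking), spatially explicit
dispersal, or multi-variable environments — the single synthetic axis is
"temperature", the dominant driver in the seasonal setting it mimics, and
a multi-variable extension would be additive in the fitness kernel.

Mechanics: a Yule tree (`birth_rate = 1`) sets the phylogeny; Brownian
motion (`bm_rate = 3`, giving tip optima an sd of ≈ 4 °C on a tree of
expected depth ln n) sets niche optima; a lognormal carrying capacity
K_i (`abundance_lognormal_sd = 3`) sets the rare/abundant skew — at
survey scale ~0.2–1% of OTUs carry 70% of reads, matching the skew such
surveys report; and a sample at environment E draws `depth` reads
multinomially with

$$p_i \propto \big[w\,e^{-(E-\mathrm{opt}_i)^2/2\sigma^2} + (1-w)\big]\,K_i.$$

`w` interpolates pure selection (1) to neutrality (0); σ is
`niche_breadth`. The neutral component is a constant fitness floor rather
than an explicit dispersal kernel — homogenizing dispersal is emulated by
all samples sharing one metacommunity pool — which keeps the generator
analytic and the planted truth interpretable. A fresh tree is simulated
per seed so tests cover topology variability. Two optional fields extend
the basic model: `trait_root` decouples the Brownian root state from the
environment means (see below), and `drift_lognormal_sd` adds mean-one
per-sample demographic noise (default 0, leaving the expected-abundance
formula above exact).

## Regime presets and what they can show

The presets are *defined by the inference they should trigger* and are
validated only against it (the survey they emulate is observational — no
generative truth exists to copy):

* `variable_selection` — w = 1, seasons at 26 °C and 29.5 °C
  (monsoon / intermonsoon), σ = 1.5: between-season pairs experience
  heterogeneous filtering and betaNTI exceeds +2.
* `homogeneous_selection` — w = 1, both seasons at 28 ± 0.6 °C,
  σ = 0.5, `trait_root = 20`, depth 700, carrying-capacity sd 1. The
  off-centre root matters: a filter centred on the Brownian root state
  selects taxa scattered across the tree (many lineages pass through the
  centre of the trait distribution), which makes homogeneous selection
  undetectable *by construction*; aiming the filter at the +1.9 sd tail
  selects a clade-restricted pool, and shallow sampling turns membership
  over within it, which is exactly the signal betaNTI < −2 detects.
* `homogenizing_dispersal` — w = 0 at full depth: all samples are
  multinomial draws from one pool.
* `drift` — w = 0 at depth 1,000: high demographic sampling noise.

Validation runs use 300 OTUs, 24 + 24 samples, 199 null replicates and
three simulation seeds per preset (the package's standing validation
scale; a full-survey-sized run simply takes proportionally longer), with
*unweighted* betaMNTD: at 300-tip scale the turnover signal lives in
presence/absence of rare taxa, which abundance weighting suppresses.
Recovered fractions are averaged over the three seeds; single seeds
fluctuate (the homogeneous-selection fraction ranged 0.30–1.00 over eight
seeds during calibration) because whether the trait-tail forms one tight
clade varies by tree realization. Passing these checks shows the
inference chain is wired correctly and directionally sensitive; it does
not certify performance on real data, where richness is one to two orders
of magnitude higher, niches are multi-dimensional and conservatism is
imperfect.

# Numerical choices

* Chao1 uses the classic form S + F1²/(2 F2), switching to the
  bias-corrected form only when F2 = 0; ACE uses the standard
  abundance-based coverage estimator with rare cutoff 10 and returns a
  flagged `NaN` when coverage is 0 (all rare OTUs singletons).
* Spearman p-values: t approximation by default; |rho| = 1 returns p = 0
  by convention; exact permutation enumeration is available for n ≤ 8.
* Mantel p = (1 + #{r_perm ≥ r_obs})/(permutations + 1): one-tailed with
  the add-one floor 1/(permutations + 1); 999 permutations by default.
* Null replicates default to 999; 199 is the documented fast mode and
  changes preset process fractions by < 0.05.
* Seeds are explicit everywhere; pair-level work derives sub-seeds from
  the master seed by hashing sample identifiers, and `with_seed()`
  restores the caller's RNG state, so no call mutates global randomness.
  Pipelines are byte-identical across reruns of the same config + seed
  (no timestamps are written).
* Ties: Louvain uses a seeded RNG; degree-descending removal breaks
  degree ties by node order; Wilcoxon uses mid-ranks with tie-corrected
  variance.

# Known limitations

Spearman co-occurrence networks ignore compositionality (no
SparCC/SPIEC-EASI-style correction); the uncorrected p < 0.01 edge rule
reproduces the conventional construction, not a false-discovery
guarantee. The taxa-shuffle null conditions on the observed abundance
matrix, so it cannot separate selection acting identically on all samples
from a restricted regional pool. The generator's single environmental
axis and Gaussian kernel are deliberate simplifications; parameter
recovery on it bounds correctness, not field performance.
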