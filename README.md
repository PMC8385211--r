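# microassembly

Community-assembly inference and co-occurrence network analysis for
microbial surveys, with explicit treatment of the rare biosphere.

Marine bacterioplankton (and microbial communities generally) are a few
abundant species plus a long tail of rare ones, and the ecological
processes that assemble the two components can differ. `microassembly`
takes an OTU count table, a rooted phylogeny and per-sample metadata and
answers three questions a community ecologist asks of such a survey:

1. **Which taxa are rare, and in what way?** Every OTU is classified from
   its per-sample relative abundances into always abundant (AAT),
   conditionally abundant (CAT), conditionally rare and abundant (CRAT),
   moderate (MT), conditionally rare (CRT) and always rare (ART) taxa,
   using the conventional 0.01% / 1% cuts; CRT + ART form the rare taxa
   (RT), the rest the abundant taxa (AT).
2. **Which ecological processes assemble the community?** For every
   sample pair the beta mean nearest taxon distance

   βMNTD(a, b) = ½ [ Σ<sub>i∈a</sub> w<sub>i</sub> min<sub>j∈b</sub> d(i, j) +
   Σ<sub>j∈b</sub> w<sub>j</sub> min<sub>i∈a</sub> d(i, j) ]

   is compared against a 999-replicate "taxa shuffle" null (tip identities
   permuted on the cophenetic matrix), giving the beta nearest taxon index
   βNTI = (βMNTD<sub>obs</sub> − μ<sub>null</sub>) / σ<sub>null</sub>.
   Pairs with |βNTI| < 2 are passed to the Bray–Curtis-based Raup–Crick
   null (RC<sub>Bray</sub>), whose null communities preserve each sample's
   richness and total abundance while drawing species by metacommunity
   occupancy and abundance. The joint rule assigns one of five processes:
   βNTI > +2 variable selection; βNTI < −2 homogeneous selection; else
   RC > +0.95 dispersal limitation; RC < −0.95 homogenizing dispersal;
   otherwise undominated.
3. **Who co-occurs with whom, and how robust is the web?** OTUs with more
   than 20 reads are correlated pairwise (Spearman); |r| > 0.8 and
   p < 0.01 define edges. The package computes node centralities (degree,
   betweenness, closeness, eigenvector), network topology (connectance,
   diameter, path length, clustering, power-law R², Louvain modularity),
   Wilcoxon-based season-enrichment labels with a positive/negative edge
   census, and robustness as natural connectivity
   λ̄ = ln((1/N) Σ e<sup>λᵢ</sup>) under node removal.

A synthetic metacommunity simulator (Yule phylogeny, Brownian-motion
niche optima, lognormal carrying capacities, Gaussian environmental
filtering with a selection weight w) generates surveys with *known*
assembly regimes, so the whole inference chain is testable without any
sequencing data.

## Worked example

Simulate a two-season survey under pure heterogeneous selection, then run
the classification, the null models and the network:

```r
library(microassembly)

sim <- simulate_survey(regime_preset("variable_selection", n_otus = 120,
                                     n_samples_per_group = 8, seed = 1))

cls <- classify_all(relative_abundance(sim$table))
print(cls)
#> abundance_classification: 120 OTUs
#> category
#>  AAT  CAT CRAT   MT  ART  CRT
#>    9   11    2   15   29   54

b  <- beta_nti_matrix(sim$table, sim$tree, reps = 199, seed = 2)
rc <- rc_bray_matrix(sim$table, reps = 199, seed = 3)
part <- partition_processes(b, rc)
print(part)
#> process_summary over 120 sample pairs
#>                 process  fraction
#>      variable_selection 0.5333333
#>   homogeneous_selection 0.0000000
#>    dispersal_limitation 0.0000000
#>  homogenizing_dispersal 0.2916667
#>             undominated 0.1750000

net <- build_network(relative_abundance(filter_min_sequences(sim$table)))
print(net)
#> co_network: 72 nodes, 1313 edges (80 OTUs tested, 8 isolated)
natural_connectivity(net)
#> [1] 38.868
```

Reading the output: 83 of 120 OTUs are rare (CRT + ART) — the simulated
skew concentrates reads in a few abundant taxa. All 64 between-season
pairs exceed βNTI = +2 (variable selection, as planted by the preset),
while within-season pairs split between homogenizing dispersal and
undominated assembly. The network keeps the 72 OTUs with at least one
robust correlation; its natural connectivity is the intact-network
baseline for the robustness curve (`robustness_curve()`).

`run_full_pipeline(pipeline_config(...))` chains every stage (rarefaction
→ classification → per-class null models → enrichment → network →
robustness) and writes a TSV/JSON report bundle that is byte-identical
for identical config and seed.

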