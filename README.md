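# circanet

Metabolism is a major output of the circadian clock: in organisms from fish
to mammals, large fractions of the enzymes of intermediary metabolism peak in
expression at specific times of day. circanet is an R package for asking
*which parts of a metabolic network oscillate together*. It integrates two
data types that are usually analysed separately — the circadian peak times
(phases) of rhythmic genes, and a genome-scale metabolic reconstruction
connecting enzymatic reactions through shared metabolites — and extracts
clusters of enzymes that are simultaneously close in the network and
synchronised on the 24 h clock. It is aimed at chronobiologists and systems
biologists with a table of circadian phases (from microarray or RNA-seq time
courses) and a reaction table (e.g. KEGG-derived) for their organism.

## The method

Reactions are nodes of an undirected graph with an edge whenever two
reactions share a substrate or product (ubiquitous currency metabolites such
as ATP, NAD(H) or water are excluded from connectivity by default). Because
genes and reactions are many-to-many, the clustering unit is the
(gene, reaction) pair, each carrying the circadian phase *p* of its gene. The
dissimilarity between two units *i* and *j* is

$$D_{ij} \;=\; d_{ij} \;+\; 4\lambda\,\sin^2\!\Big(\frac{\pi\,(p_i - p_j)}{24}\Big)$$

where *d<sub>ij</sub>* is the shortest-path hop count between their reactions
and the second term is the squared chord distance between unit vectors on the
24 h phase circle, weighted by λ. With λ = 1 the penalty equals 0, 1, 2, 3, 4
for phase differences of 0, 4, 6, 8, 12 h, i.e. an antiphase pair is as far
apart as four reaction steps. Complete-linkage hierarchical clustering of
*D* (one dendrogram per connected component), cut strictly below height
*h* = 12, yields phase-coherent clusters, which are summarised by circular
mean phase, a Rayleigh coherency test, and one-sided Fisher's exact pathway
enrichment.

The package also implements the supporting rhythm-detection statistics used
to produce phase tables and metabolite calls: a periodogram g-test at the
Fourier frequency nearest a 24 h dominant period with dual-condition (LD and
DD) selection and a permutation FDR estimate, grid cosinor regression over
periods 20–28 h with an F-test, one-way ANOVA across timepoints,
total-intensity scaling of spectra, and an FPKM abundance/fold-change filter.
Seeded generators produce synthetic reaction networks with planted
phase-coherent modules and cosine-plus-noise time series with ground truth.

## Worked example

```r
library(circanet)

sim   <- simulate_reaction_network(seed = 7)   # 2 planted modules + background
net   <- build_reaction_graph(sim$reactions)
nodes <- gene_reaction_nodes(sim$reactions, sim$phases)
fit   <- cluster_phase_coherent(nodes, net, lambda = 1, h = 12,
                                records = sim$reactions)
fit$clusters
#> # A tibble: 5 × 8
#>   cluster component n_members n_genes mean_phase coherency_p top_pathway top_pathway_p
#>     <int>     <int>     <int>   <int>      <dbl>       <dbl> <chr>               <dbl>
#> 1       1         3         7       7      16.6      0.423   PWY_BG          0.00155
#> 2       2         1         5       5      14.2      0.00140 PWY_M2          0.0000645
#> 3       3         1         5       5       1.90     0.00159 PWY_M1          0.0000645
#> 4       4         2         2       2       4.29     0.918   PWY_BG          0.237
#> 5       5         4         1       1       9.28    NA       PWY_BG          0.5
```

The two planted five-gene modules (centred at 2 h and 14 h) are recovered as
clusters 2 and 3: five members each, circular mean phases near the planted
centres, small Rayleigh coherency p-values (phases are tightly concentrated),
and their planted pathway as the top enrichment. The larger background
component (cluster 1) has a non-significant coherency p-value of 0.42 — its
phases are scattered around the clock. `tidy(fit)` returns the node-level
membership table, `glance(fit)` a one-row summary, and `autoplot(fit)` rose
diagrams of cluster phases; `export_newick()` and
`write_itol_phase_annotation()` export the dendrograms for tree viewers.

Metabolite-centred queries work the same way:

```r
link_metabolite_to_enzymes(sim$reactions, "m1_met03", nodes)
#> # A tibble: 2 × 4
#>   metabolite gene   reaction_id phase
#> 1 m1_met03   gm1_02 M1_R02       1.40
#> 2 m1_met03   gm1_03 M1_R03       1.65
```

File-based pipelines (`run_build_cluster()`, `run_detect_rhythms()`,
`run_simulate_network()`, `run_simulate_series()`) read and write the TSV
dialects described in the function documentation; `inst/cli/circanet.R` wraps
them as shell subcommands (`build-cluster`, `detect-rhythms`,
`simulate-network`, `simulate-series`, `link-metabolite`, `enrich`).

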