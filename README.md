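# hspnet

Network-based analysis of peptide chemical space, built around the
**half-space proximal network** (HSPN): a sparse, connected similarity
graph over alignment-free peptide descriptors. The package targets
researchers mining curated peptide collections — e.g. antibiofilm or
antimicrobial peptide sets — for representative scaffolds and conserved
sequence motifs.

## What it does

1. **Descriptor space.** Peptides are embedded with alignment-free
   physicochemical descriptors (composition, length, charge, hydropathy,
   hydrophobic moment, residue-class fractions, Boman-style solubility),
   min–max normalised and compared by Euclidean distance; similarity is
   `s(i,j) = 1 − d(i,j)/d_max`.
2. **HSP graph.** For each node *u*, candidates are visited nearest
   first; each visited candidate *v* gets an edge, and every remaining
   candidate *w* with `d(w,v) < d(w,u)` is discarded (it lies on *v*'s
   side of the bisecting half-space). The undirected union is a
   low-degree spanner of the complete graph that stays connected.
3. **Cutoff scan and communities.** Edges are filtered over a similarity
   cutoff grid (0, 0.30 … 0.95); each filtered network is clustered with
   weight-aware Louvain modularity optimisation and summarised (density,
   modularity, clustering coefficient, communities, singletons, path
   statistics) so a working cutoff can be chosen.
4. **Centralities and scaffolds.** Degree, harmonic, betweenness and
   hub-bridge centralities rank nodes; greedy scaffold extraction keeps
   a peptide only if its Smith–Waterman identity to every higher-ranked
   kept peptide is below an identity cutoff, yielding non-redundant
   representative subsets (and their union across metrics) with coverage
   percentages.
5. **Metadata networks.** Bipartite peptide↔(field, value) graphs over
   categorical annotations (database, origin, activity, target,
   toxicity), ranked by bipartite betweenness.
6. **Motif discovery.** Per community: center-star alignment with an
   uppercase/lowercase/`x` consensus convention, plus an exhaustive
   enriched-k-mer scan (widths 3–5) against composition-preserving
   shuffled controls with a one-sided Fisher exact test, scored by the
   pseudo-count enrichment ratio
   `((TP+1)/(NPOS+1)) / ((FP+1)/(NNEG+1))`.
7. **Synthetic studies.** A generator of motif-sharing peptide families
   plus background singletons with truth labels, used to validate the
   entire pipeline end to end.

See `vignettes/hspnet-methods.Rmd` for the model, parameter defaults and
numerical conventions.

## Worked example

```r
library(hspnet)

sim <- generate_families(family_config(n_families = 3, family_size = 6,
                                       n_singletons = 5,
                                       length_range = c(12, 30), seed = 42))
d   <- distance_matrix(minmax_normalize(compute_descriptors(sim$peptides)))
s   <- to_similarity(d)
net <- hsp_edges(d, s)

cutoff_scan(d, s, grid = c(0, 0.4, 0.5, 0.6, 0.65, 0.7), seed = 1)
#>   cutoff n_edges density modularity n_communities n_singletons
#> 1   0.00      44  0.1739      0.416             4            0
#> 2   0.40      34  0.1344      0.492             4            0
#> 3   0.50      19  0.0751      0.634             8            5
#> 4   0.60      17  0.0672      0.647             9            6
#> 5   0.65      16  0.0632      0.631            10            7
#> 6   0.70      11  0.0435      0.673            12            8
```

Density falls and modularity rises with the cutoff while communities and
singletons accumulate; 0.65 keeps the three implanted families separable
at tolerable singleton cost. At that cutoff:

```r
model <- apply_cutoff(net, 0.65)
part  <- louvain_communities(model, seed = 1)
cent  <- compute_centralities(model, part)
head(cent[order(-cent$harmonic), ], 3)
#>      node_id degree harmonic betweenness hub_bridge community
#> 2  fam01_m02      3      4.0         6.5          3         0
#> 16 fam03_m04      3      4.0         2.5          3         4
#> 18 fam03_m06      3      4.0         2.5          3         4

union_subsets(extract_scaffolds(sim$peptides, cent, "harmonic", 0.4),
              extract_scaffolds(sim$peptides, cent, "hub_bridge", 0.4),
              sim$peptides)
#> scaffold_subset [union @ identity < 0.40]: 8 of 23 peptides (35%)
```

Eight peptides — pairwise below 40% local-alignment identity, spanning
hubs to singletons — represent the 23-peptide space (35% coverage). The
k-mer scan recovers the motif implanted in family 1 as its top hit:

```r
fam1 <- subset_peptides(sim$peptides,
                        sim$truth$peptide_id[sim$truth$family == "1"])
head(enriched_kmers(fam1, scan_params(widths = 3:5, seed = 1)), 3)
#>   motif matches_query matches_control sites_percent     p_value
#> 1   YHV             6               0         100.0 0.001082251
#> 2   AYD             5               0          83.3 0.007575758
#> 3  AYDN             5               0          83.3 0.007575758

sim$truth$motif[1]
#> [1] "YHV"
```

`matches_query`/`matches_control` are the numbers of family versus
shuffled-control sequences containing each k-mer; `sites_percent` is the
family fraction carrying it; the p-value is the one-sided Fisher exact
test on that 2×2 table.

For real data, start from `load_peptides("peptides.fasta")` (plus
`attach_metadata()` / `read_metadata_tsv()`) or run everything at once
with `run_pipeline(pipeline_config(fasta = ..., metadata = ...))`, which
also writes TSV tables, GraphML networks and the representative-subset
FASTA to an output directory.

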