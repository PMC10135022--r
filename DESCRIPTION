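Package: hspnet
Title: Half-Space Proximal Networks for Peptide Chemical-Space Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based exploration of peptide chemical space built around
    the half-space proximal (HSP) graph, a sparse connected spanner of the
    complete pairwise-similarity graph. Peptides are embedded with
    alignment-free physicochemical descriptors, min-max normalised and
    compared by Euclidean distance; the resulting HSP network is filtered
    over a grid of similarity cutoffs, clustered with the Louvain method and
    summarised with the usual topology statistics (density, modularity,
    clustering coefficient, path lengths). Degree, harmonic, betweenness and
    hub-bridge centralities drive a greedy scaffold-extraction step that
    selects representative, non-redundant peptide subsets under
    Smith-Waterman local-alignment identity cutoffs. Bipartite
    peptide-to-metadata networks, community-guided consensus calling and an
    enriched k-mer motif scan with composition-preserving shuffled controls
    and a pseudo-count enrichment ratio complete the pipeline. A synthetic
    peptide-family generator with known implanted motifs supports validation
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
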