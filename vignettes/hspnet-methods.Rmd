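---
title: "Methods: half-space proximal networks for peptide chemical space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: half-space proximal networks for peptide chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspnet)
```

## The model

`hspnet` represents a set of peptides as points in an alignment-free
physicochemical descriptor space and summarises their pairwise relations
with a *half-space proximal* (HSP) graph. The HSP test is a local
proximity rule: for each node $u$, candidates are visited from nearest to
farthest; each visited candidate $v$ receives an edge $u \to v$, and every
remaining candidate $w$ with $d(w, v) < d(w, u)$ — i.e. lying on $v$'s
side of the bisecting hyperplane between $u$ and $v$ — is discarded. The
undirected union of these directed edges is a sparse, connected spanner
of the complete similarity graph: it preserves the global connectivity of
the chemical space while keeping only a small fraction of the
$\binom{n}{2}$ possible edges, which is what makes community structure
legible.

Two conventions matter in degenerate geometry. Elimination uses a
*strict* inequality, so candidates equidistant from $u$ and $v$ survive;
this preserves the connectivity guarantee when points coincide or are
symmetric. Ties in the nearest-candidate choice are broken by input
order, making construction deterministic. The emitted neighbour itself is
always removed explicitly, which keeps the loop finite when duplicate
points (distance 0) occur.

## Descriptor space

The default panel maps each peptide to 32 quantities: the 20 amino-acid
composition fractions; sequence length; net charge at pH 7 (K, R $+1$;
H $+0.5$; D, E $-1$; termini ignored); mean Kyte–Doolittle hydropathy; a
mean hydrophobic-moment term (Eisenberg consensus scale, $\alpha$-helical
$100^\circ$ periodicity, window 11, falling back to the full sequence for
peptides shorter than the window — peptides down to 8 aa must be
representable); six residue-class fractions (aliphatic AILV, aromatic
FHWY, polar CNQSTY, positive HKR, negative DE, tiny ACGST); aromaticity
(FWY); and a Boman-style mean solubility term built from
water-to-cyclohexane transfer free energies (proline, which has no
published value, contributes 0). The panel is pluggable by name: the
pipeline's contracts are descriptor-agnostic, and any user-supplied
subset of the panel can stand in.

Columns are min–max normalised to $[0,1]$ (constant columns map to 0;
the bounds are stored so new data can be projected consistently), and
peptides are compared by Euclidean distance. Similarity is the global
complement $s(i,j) = 1 - d(i,j)/d_{\max}$ with $d_{\max}$ the largest
off-diagonal distance. The global normalisation (rather than per-pair or
a fixed constant) is a deliberate choice: it maps distances onto $[0,1]$
exactly, so the similarity-cutoff grid $0, 0.30, \dots, 0.95$ applies
uniformly to any input set, and it preserves the distance ordering
exactly ($d$-ordering is the reverse of $s$-ordering, a tested
invariant).

## Cutoff selection and communities

Filtering retains edges whose similarity is *strictly greater* than the
cutoff; nodes are never removed, so weakly similar peptides surface as
singletons. `cutoff_scan()` computes the HSP edge set once, filters it
at each grid value, clusters each filtered graph and tabulates density,
modularity, average clustering coefficient, communities, singletons,
diameter and average path length. The package reports the scan and takes
the working cutoff as user input (default 0.65): the choice is a
trade-off judgement (density dropping while modularity rises, with a
tolerable singleton count), not a formal optimum, and we prefer to keep
that judgement visible.

Communities come from Louvain modularity optimisation, run
*weight-aware* on the similarity weights (an unweighted variant is
selectable). The resolution parameter defaults to 1. The algorithm is
seeded through R's RNG so partitions are reproducible. Isolated nodes
are their own communities; an edgeless graph yields one community per
node with modularity 0 by convention (and a warning), since the
modularity formula is undefined at $m = 0$. The reported modularity is
recomputed from the returned membership, and a test asserts
self-consistency to $10^{-9}$.

Path statistics (diameter, average path length) use hop counts over
reachable pairs only, matching how interactive graph tools report them
on disconnected graphs; a graph with no reachable pair reports 0 with an
explicit `path_stats_defined = FALSE` flag rather than `NA`, so scan
tables stay rectangular.

## Centralities

Four per-node measures: degree (unweighted), harmonic centrality
$\sum_{u \neq v} 1/\mathrm{dist}(u,v)$ with $1/\infty = 0$, Brandes
betweenness (unnormalised — only rankings are consumed downstream, and
unnormalised values make small worked examples exact), all on hop
distances; and hub-bridge centrality. No published formula for
hub-bridge exists in the sources this design follows, so the package
documents and pins its own:
$$\mathrm{HB}(v) = \deg(v)\,\bigl(1 + \#\{\text{foreign neighbour
communities}\}\bigr),$$
which is 0 for isolated nodes, collapses to degree inside a single
community (a tested invariant), and boosts nodes whose neighbourhoods
span communities — the qualitative behaviour the measure's name and uses
imply. It is a pluggable strategy: an alternative formula can be dropped
in without touching the extraction machinery.

## Scaffold extraction and sequence identity

Scaffold extraction ranks all nodes — hubs to singletons — by a
centrality, then greedily retains a peptide only if its local-alignment
identity to every already-retained peptide is strictly below the
identity cutoff. Equal centralities are ordered by node id for
determinism. Coverage is reported as the half-up-rounded percentage of
the source set retained (base R's banker's rounding would report 89.08%
as 89 but 46.55% as 46 vs 47 inconsistently with the convention used in
the field's tables).

Identity comes from Smith–Waterman local alignment under BLOSUM62 with
gap open 10 and gap extend 0.5 (the classical defaults of pairwise
local-alignment tools; a gap of length $L$ costs $10 + 0.5L$). Two
numerical choices deserve emphasis:

* **Denominator.** Identity is identical aligned positions divided by
  the *shorter sequence length*, not by alignment columns. With the
  alignment-column denominator, any two unrelated peptides sharing a
  short perfect local match (a common tripeptide suffices) score
  identity 1.0, and greedy redundancy removal at 0.98 collapses a
  174-peptide set to a few dozen — behaviour useless for redundancy
  control. Normalising by the shorter sequence means only pairs that
  match over (nearly) the whole shorter member approach 1, which is the
  semantics redundancy removal and identity-threshold extraction
  require. Raw match and column counts remain available via
  `sw_align_stats()`.
* **Tie-breaking.** Co-optimal local alignments can differ in identity
  at equal score, so "the" identity is ill-defined without a traceback
  convention. The implementation (in C++) pins one: the traceback starts
  at the first maximal cell in row-major order, prefers diagonal over
  vertical over horizontal moves, and closes gaps as early as possible.
  The test suite checks the implementation against an independently
  coded plain-R dynamic program following the same contract, and checks
  scores (which are convention-free) against an independent alignment
  library.

Redundancy removal (`dedupe()`, default cutoff 0.98) is the same greedy
scan in input order and is idempotent. Single-metric subsets satisfy,
by construction and by post-hoc test, that all pairwise member
identities are below the cutoff, and subset sizes shrink monotonically
as the cutoff tightens. The union of two subsets (taken at equal
cutoffs) orders members by the best rank either parent assigned.

## Metadata networks

`build_metn()` builds a strictly bipartite graph: peptides on one layer,
distinct (field, value) categories on the other, one unweighted edge per
annotation record (records are presence/absence facts). Multi-field
networks use composite `field:value` node keys so one builder serves
single-field and combined views. Betweenness is computed directly on the
bipartite graph — not on a projection — because category hubs acquire
their importance precisely from the peptide paths that run through them.

## Motif discovery

Motif mining runs per community (communities of at least 2 members;
all post-cutoff singletons are pooled into one cluster, since atypical
sequences are most informative analysed together).

* **Alignment route.** A center-star multiple alignment (center = the
  sequence with the highest summed pairwise global-alignment score;
  "once a gap, always a gap" merging) feeds a consensus caller. Per
  column, with $f$ the plurality-residue frequency among non-gap
  characters (ties alphabetical): a capital letter when $f \ge 0.5$, a
  lowercase letter when the plurality residue still scores positively
  (BLOSUM62 $> 0$) against at least half of the column's residues, `x`
  otherwise. Center-star is a deliberate simplification of progressive
  aligners: deterministic, oracle-checkable, and adequate for blocks of
  short, related peptides; two-member communities degenerate naturally
  to a single pairwise global alignment.
* **Alignment-free route.** An exhaustive enriched-k-mer scan replaces
  position-weight-matrix refinement: for widths 3–5 (configurable within
  2–10), every k-mer occurring in the positives is tested against a
  control set of composition-preserving shuffles (one per positive by
  default, so NNEG = NPOS) with a one-sided Fisher exact test on
  sequences-containing counts. Exhaustive enumeration restricted to
  observed k-mers is desk-scale, fully reproducible, and testable
  against a hypergeometric oracle — properties a stochastic PWM
  optimiser lacks. Reported k-mers pass $p < 0.05$ and a 20%
  minimum-sites fraction, rank by ascending $p$ (ties: descending match
  count, then alphabetical), and suppress lower-ranked k-mers contained
  in them as substrings. Sites-% is reported to one decimal, half-up.
* **Enrichment scoring.** Motif lists are scored on external query and
  control sets with the pseudo-count ratio
  $\bigl((TP+1)/(NPOS+1)\bigr) / \bigl((FP+1)/(NNEG+1)\bigr)$, matched
  by exact substring with optional `[..]` alternative positions. The
  ratio is strictly increasing in TP and strictly decreasing in FP,
  exhaustively verified for set sizes up to 20.

## The synthetic generator

`generate_families()` produces the structure the analysis assumes:
families derived from a random background ancestor (per-position
substitution outside the motif at `mutation_rate`, drawing from the
background *excluding* the current residue so the nominal rate is the
realised mismatch probability), one identical ungapped motif implanted
per family at a member-specific random offset, i.i.d. background
singletons, and categorical metadata (a distinct synthetic origin per
family; random activity/target/toxicity labels). Defaults are fixed once
at the scale of the motivating study — 10 families × 14 members + 34
singletons = 174 peptides, lengths 8–45, motif lengths 3–8, uniform
background, `mutation_rate` 0.1 (inside the ≤ 0.2 regime where
within-family identity demonstrably exceeds family-vs-singleton
identity) — and are not tuned per analysis. A uniform residue background
is used deliberately: no natural-abundance table is assumed, and
uniformity gives clean null behaviour for shuffled controls.

What the generator does **not** emulate: real antimicrobial-peptide
composition bias (cationic, amphipathic), secondary structure, length–
activity correlations, or correlated metadata. Passing tests therefore
demonstrate algorithmic correctness and statistical behaviour under a
controlled null, not biological validity on real peptide databases.

## Problem sizes and numerical conventions

The test suite runs at deliberately modest scale: HSP oracle equivalence
on 100 random metric instances with up to 30 points; alignment oracle
equivalence on 50 random pairs of 8–45 residues; betweenness oracle
checks on graphs of up to 12 nodes (explicit path enumeration);
enrichment-ratio exhaustiveness up to set size 20; scaffold invariants
on a 100-peptide synthetic set; motif recovery over 20 generator seeds
with 10-member families. The acceptance script analyses the full
174-peptide default study. Degenerate inputs have pinned behaviour
throughout: empty FASTA (empty set, warning), single-sequence alignment
blocks (1-row block, warning), edgeless graphs (modularity 0, path
statistics flagged), constant descriptor columns (normalise to 0),
all-zero distance matrices (similarity 1 everywhere).

## Known limitations

The descriptor panel is a documented default, not an optimised feature
selection; analyses sensitive to the embedding should supply their own
panel. Hub-bridge centrality is this package's own pinned formula.
Center-star alignment is not iterative-refinement MSA quality; consensus
strings on diverse communities should be read as column summaries, not
curated motifs. The enriched-k-mer scan finds exact ungapped words only
— degenerate motifs appear as families of related words rather than as
one bracketed pattern. Louvain is seed-deterministic but not
partition-unique; near-degenerate modularity landscapes can yield
different (equally valid) partitions across seeds.
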