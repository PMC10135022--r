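# Smith-Waterman identity, redundancy removal and centrality-ranked
# scaffold extraction.
#
# Identity between two peptides is computed from the best local alignment
# (affine gaps; a gap of length L costs gap_open + L * gap_extend) as
# identical aligned positions over the length of the shorter peptide.
# Normalising by the shorter sequence rather than by alignment columns
# keeps unrelated peptides that merely share a short perfect local match
# from scoring as near-duplicates, which is what redundancy removal at
# high cutoffs requires. Redundancy removal and scaffold extraction are
# greedy scans that keep a peptide only while it stays below the identity
# cutoff against everything already kept.

#' Local-alignment parameters
#'
#' Pinned to the classical defaults of pairwise local alignment tools:
#' BLOSUM62, gap open 10, gap extend 0.5.
#'
#' @param substitution_matrix A named 20x20 (or larger) integer scoring
#'   matrix; default BLOSUM62.
#' @param gap_open Gap opening penalty (positive; default 10).
#' @param gap_extend Gap extension penalty per gap column (positive,
#'   <= gap_open; default 0.5).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(substitution_matrix = NULL, gap_open = 10,
                             gap_extend = 0.5) {
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop("need gap_open >= gap_extend > 0", call. = FALSE)
  }
  structure(list(substitution_matrix = substitution_matrix %||% blosum62(),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

sw_encode <- function(seq, mat) {
  idx <- match(strsplit(seq, "")[[1]], rownames(mat))
  if (anyNA(idx)) {
    stop("sequence contains residues missing from the substitution matrix",
         call. = FALSE)
  }
  idx
}

#' Smith-Waterman local alignment statistics
#'
#' Full dynamic-programming local alignment with affine gaps (a gap of
#' length L costs `gap_open + L * gap_extend`). Among co-optimal
#' alignments the reported one is canonical: the traceback starts at the
#' first maximal cell in row-major order, prefers diagonal over vertical
#' over horizontal moves, and closes gaps as early as possible, so the
#' identity is deterministic.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param params An [alignment_params()].
#' @return List with `score`, `matches` (identical aligned positions),
#'   `length` (alignment columns including gaps) and `identity`
#'   (matches over the shorter sequence length); an empty optimal
#'   alignment reports all zeros.
#' @export
sw_align_stats <- function(a, b, params = alignment_params()) {
  mat <- params$substitution_matrix
  out <- sw_align_cpp(sw_encode(a, mat), sw_encode(b, mat), mat,
                      params$gap_open, params$gap_extend)
  out$identity <- out$matches / min(nchar(a), nchar(b))
  out
}

#' Smith-Waterman local-alignment identity
#'
#' Identity of the best local alignment: identical aligned positions
#' divided by the length of the shorter peptide, so that only sequences
#' matching over (nearly) their whole shorter member approach 1. When no
#' positive-scoring local alignment exists the identity is 0.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param params An [alignment_params()].
#' @return Identity in \[0, 1\].
#' @export
sw_identity <- function(a, b, params = alignment_params()) {
  sw_align_stats(a, b, params)$identity
}

#' All-vs-all Smith-Waterman identity matrix
#'
#' @param set A `peptide_set`.
#' @param params An [alignment_params()].
#' @return Symmetric n x n identity matrix with unit diagonal, dimnames =
#'   peptide ids.
#' @export
sw_identity_matrix <- function(set, params = alignment_params()) {
  stopifnot(inherits(set, "peptide_set"))
  n <- length(set)
  m <- diag(1, n)
  dimnames(m) <- list(set$ids, set$ids)
  if (n < 2L) return(m)
  mat <- params$substitution_matrix
  enc <- lapply(set$sequences, sw_encode, mat = mat)
  lens <- nchar(set$sequences)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- sw_align_cpp(enc[[i]], enc[[j]], mat,
                          params$gap_open, params$gap_extend)
      v <- aln$matches / min(lens[i], lens[j])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Remove redundant peptides above an identity cutoff
#'
#' Greedy scan in input order: a peptide is kept iff its local-alignment
#' identity to every already-kept peptide is strictly below `cutoff`.
#' Deterministic and idempotent.
#'
#' @param set A `peptide_set`.
#' @param cutoff Identity cutoff in (0, 1\] (default 0.98).
#' @param params An [alignment_params()].
#' @param identities Optional precomputed matrix from
#'   [sw_identity_matrix()].
#' @return The deduplicated `peptide_set`.
#' @export
dedupe <- function(set, cutoff = 0.98, params = alignment_params(),
                   identities = NULL) {
  stopifnot(inherits(set, "peptide_set"))
  if (!(cutoff > 0 && cutoff <= 1)) {
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (length(set) <= 1L) return(set)
  kept <- integer(0)
  for (i in seq_along(set$ids)) {
    ok <- TRUE
    for (j in kept) {
      idv <- if (!is.null(identities)) {
        identities[set$ids[i], set$ids[j]]
      } else {
        sw_identity(set$sequences[i], set$sequences[j], params)
      }
      if (idv >= cutoff) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  subset_peptides(set, kept)
}

#' Extract a centrality-ranked scaffold subset
#'
#' Peptides are sorted by descending centrality (ties by lexicographic
#' node id) and scanned greedily: a peptide is retained iff its identity
#' to every already-retained peptide is strictly below `identity_cutoff`.
#' All nodes participate, from hubs to singletons. Coverage is the
#' half-up-rounded percentage of the source set retained.
#'
#' @param set A `peptide_set` (the network's node set).
#' @param cent A centrality table from [compute_centralities()] covering
#'   every peptide.
#' @param metric Ranking metric (degree, harmonic, betweenness,
#'   hub_bridge).
#' @param identity_cutoff Identity cutoff in (0, 1\].
#' @param params An [alignment_params()].
#' @param identities Optional precomputed identity matrix (recommended when
#'   extracting at several cutoffs).
#' @param graph Optional `hsp_network` used to count edges induced by the
#'   subset.
#' @return A `scaffold_subset`: member_ids (descending centrality), metric,
#'   identity_cutoff, coverage_percent, n_edges_induced, and the rank of
#'   each member.
#' @export
extract_scaffolds <- function(set, cent, metric, identity_cutoff,
                              params = alignment_params(),
                              identities = NULL, graph = NULL) {
  stopifnot(inherits(set, "peptide_set"))
  if (!metric %in% CENTRALITY_METRICS) {
    stop("unknown metric '", metric, "'", call. = FALSE)
  }
  if (!(identity_cutoff > 0 && identity_cutoff <= 1)) {
    stop("identity_cutoff must lie in (0, 1]", call. = FALSE)
  }
  missing <- setdiff(set$ids, cent$node_id)
  if (length(missing)) {
    stop("no centrality value for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- cent[[metric]][match(set$ids, cent$node_id)]
  ord <- order(-vals, set$ids)
  seqs <- set$sequences
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      idv <- if (!is.null(identities)) {
        identities[set$ids[i], set$ids[j]]
      } else {
        sw_identity(seqs[i], seqs[j], params)
      }
      if (idv >= identity_cutoff) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  new_scaffold_subset(set$ids[kept], metric, identity_cutoff,
                      total_n = length(set), graph = graph,
                      ranks = rank_of(set$ids[kept], list(set$ids[kept])))
}

rank_of <- function(ids, parent_orders) {
  # best (smallest) rank of each id across parent member orderings
  vapply(ids, function(id) {
    r <- vapply(parent_orders, function(o) {
      pos <- match(id, o)
      if (is.na(pos)) Inf else pos
    }, numeric(1))
    min(r)
  }, numeric(1))
}

new_scaffold_subset <- function(member_ids, metric, identity_cutoff,
                                total_n, graph = NULL, ranks = NULL) {
  n_edges <- NA_integer_
  if (!is.null(graph)) {
    e <- graph$edges
    n_edges <- sum(e$from %in% member_ids & e$to %in% member_ids)
  }
  structure(list(member_ids = member_ids,
                 metric = metric,
                 identity_cutoff = identity_cutoff,
                 coverage_percent = as.integer(
                   round_half_up(100 * length(member_ids) / total_n)),
                 n_edges_induced = n_edges,
                 total_n = total_n,
                 ranks = ranks),
            class = "scaffold_subset")
}

#' @export
print.scaffold_subset <- function(x, ...) {
  cat(sprintf(
    "scaffold_subset [%s @ identity < %.2f]: %d of %d peptides (%d%%)\n",
    x$metric, x$identity_cutoff, length(x$member_ids), x$total_n,
    x$coverage_percent))
  invisible(x)
}

#' Union of two scaffold subsets
#'
#' Members of either subset, ordered by the best rank either parent gave
#' them (ties by id); coverage is recomputed against the full source set.
#' Both subsets must come from the same source set at the same identity
#' cutoff.
#'
#' @param a,b `scaffold_subset` objects with equal identity cutoffs.
#' @param total The source `peptide_set`.
#' @param graph Optional `hsp_network` for the induced edge count.
#' @return A `scaffold_subset` with metric `"union"`.
#' @export
union_subsets <- function(a, b, total, graph = NULL) {
  stopifnot(inherits(a, "scaffold_subset"), inherits(b, "scaffold_subset"),
            inherits(total, "peptide_set"))
  if (!isTRUE(all.equal(a$identity_cutoff, b$identity_cutoff))) {
    stop("subsets were extracted at different identity cutoffs (",
         a$identity_cutoff, " vs ", b$identity_cutoff, ")", call. = FALSE)
  }
  ids <- union(a$member_ids, b$member_ids)
  missing <- setdiff(ids, total$ids)
  if (length(missing)) {
    stop("subset member(s) not in the source set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  best <- rank_of(ids, list(a$member_ids, b$member_ids))
  ids <- ids[order(best, ids)]
  new_scaffold_subset(ids, "union", a$identity_cutoff,
                      total_n = length(total), graph = graph,
                      ranks = sort(best))
}

#' Scaffold-extraction report over an identity-cutoff grid
#'
#' One row per (cutoff, metric): subset size, induced edges and coverage —
#' the tabular summary used to pick the representative subset.
#'
#' @param set The network's `peptide_set`.
#' @param cent Centrality table.
#' @param metrics Metrics to rank by (default harmonic + hub_bridge).
#' @param cutoffs Identity cutoffs (default 0.9 down to 0.3).
#' @param params Alignment parameters.
#' @param identities Optional precomputed identity matrix.
#' @param graph Optional `hsp_network` for induced edge counts.
#' @return Data.frame with columns cutoff, metric, n_edges, n_nodes,
#'   coverage_percent.
#' @export
scaffold_report <- function(set, cent,
                            metrics = c("harmonic", "hub_bridge"),
                            cutoffs = seq(0.9, 0.3, by = -0.1),
                            params = alignment_params(),
                            identities = NULL, graph = NULL) {
  if (is.null(identities)) identities <- sw_identity_matrix(set, params)
  rows <- list()
  for (cut in cutoffs) {
    for (m in metrics) {
      sub <- extract_scaffolds(set, cent, m, cut, params,
                               identities = identities, graph = graph)
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cut, metric = m, n_edges = sub$n_edges_induced,
        n_nodes = length(sub$member_ids),
        coverage_percent = sub$coverage_percent)
    }
  }
  do.call(rbind, rows)
}
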