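# Community-guided motif discovery.
#
# Three cooperating pieces: a center-star multiple aligner feeding a
# consensus caller (capital = strong consensus, lowercase = weak positive
# consensus, 'x' = none), an exhaustive enriched-k-mer scan against
# composition-preserving shuffled controls (one-sided Fisher test), and a
# pseudo-count enrichment ratio for scoring motif lists on benchmark sets.

nw_align <- function(a, b, params) {
  Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximising its summed global pairwise
#' alignment score against all others (ties by input order); every other
#' sequence is aligned to the center and the pairwise alignments are
#' merged under the "once a gap, always a gap" rule. A fast, deterministic
#' stand-in for a full progressive aligner, adequate for the short peptide
#' blocks consensus calling operates on.
#'
#' @param set A `peptide_set` with >= 2 sequences (a single sequence is
#'   returned as a 1-row block with a warning).
#' @param params An [alignment_params()].
#' @return An `alignment_block`: `ids` and equal-length gapped `rows`;
#'   de-gapping row i recovers sequence i exactly.
#' @export
center_star_align <- function(set, params = alignment_params()) {
  stopifnot(inherits(set, "peptide_set"))
  n <- length(set)
  if (n == 0L) stop("empty peptide set", call. = FALSE)
  if (n == 1L) {
    warning("single sequence: returning a 1-row alignment block",
            call. = FALSE)
    return(structure(list(ids = set$ids, rows = set$sequences),
                     class = "alignment_block"))
  }
  seqs <- set$sequences
  total <- numeric(n)
  for (i in seq_len(n)) {
    others <- seqs[-i]
    total[i] <- sum(Biostrings::score(nw_align(rep(seqs[i], n - 1L),
                                               others, params)))
  }
  ci <- which.max(total)
  center <- seqs[ci]
  L <- nchar(center)
  others_idx <- setdiff(seq_len(n), ci)

  # per sequence: residues inserted before each center position (slot
  # j = 1..L) or after the last (slot L+1), and the residue (or '-')
  # aligned to each center position
  parse_one <- function(caln, saln) {
    cc <- strsplit(caln, "")[[1]]
    sc <- strsplit(saln, "")[[1]]
    inserts <- vector("list", L + 1L)
    for (k in seq_len(L + 1L)) inserts[[k]] <- character(0)
    aligned <- character(L)
    j <- 1L
    for (k in seq_along(cc)) {
      if (cc[k] == "-") {
        inserts[[j]] <- c(inserts[[j]], sc[k])
      } else {
        aligned[j] <- sc[k]
        j <- j + 1L
      }
    }
    list(inserts = inserts, aligned = aligned)
  }

  parsed <- vector("list", n)
  parsed[[ci]] <- list(inserts = rep(list(character(0)), L + 1L),
                       aligned = strsplit(center, "")[[1]])
  for (i in others_idx) {
    aln <- nw_align(center, seqs[i], params)
    parsed[[i]] <- parse_one(as.character(Biostrings::alignedPattern(aln)),
                             as.character(Biostrings::alignedSubject(aln)))
  }
  master_ins <- vapply(seq_len(L + 1L), function(j) {
    max(vapply(parsed, function(p) length(p$inserts[[j]]), integer(1)))
  }, integer(1))

  build_row <- function(p) {
    out <- character(0)
    for (j in seq_len(L)) {
      ins <- p$inserts[[j]]
      out <- c(out, ins, rep("-", master_ins[j] - length(ins)), p$aligned[j])
    }
    ins <- p$inserts[[L + 1L]]
    out <- c(out, ins, rep("-", master_ins[L + 1L] - length(ins)))
    paste(out, collapse = "")
  }
  rows <- vapply(parsed, build_row, character(1))
  structure(list(ids = set$ids, rows = rows), class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d rows x %d columns\n",
              length(x$rows), if (length(x$rows)) nchar(x$rows[1]) else 0L))
  for (i in seq_along(x$rows)) cat(sprintf("  %-12s %s\n", x$ids[i], x$rows[i]))
  invisible(x)
}

#' Consensus string of an alignment block
#'
#' Per column, with f the frequency of the plurality residue among non-gap
#' characters (ties alphabetical): uppercase residue when f >=
#' `upper_threshold`; lowercase when f is below the threshold but the
#' plurality residue still scores positively (BLOSUM62 > 0) against at
#' least half of the column's non-gap residues; otherwise 'x'. All-gap
#' columns give 'x'. The call is invariant to row order.
#'
#' @param block An `alignment_block`.
#' @param upper_threshold Plurality frequency required for a capital
#'   letter (default 0.5).
#' @return A consensus string, one character per alignment column.
#' @export
consensus <- function(block, upper_threshold = 0.5) {
  stopifnot(inherits(block, "alignment_block"))
  if (length(block$rows) == 0L) return("")
  mat <- do.call(rbind, strsplit(block$rows, ""))
  b62 <- blosum62()
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) return("x")
    tab <- sort(table(res), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    p <- sort(top)[1]
    f <- max(tab) / length(res)
    if (f >= upper_threshold) return(p)
    pos_frac <- mean(b62[p, res] > 0)
    if (pos_frac >= 0.5) tolower(p) else "x"
  }, character(1))
  paste(cons, collapse = "")
}

#' Parameters for the enriched k-mer scan
#'
#' @param widths Motif widths to scan (default 3:5; must lie in 2..10).
#' @param p_threshold Fisher-test p-value threshold (default 0.05).
#' @param min_sites_fraction Minimum fraction of positives containing the
#'   k-mer (default 0.20).
#' @param n_control_shuffles Shuffled controls generated per positive
#'   sequence (default 1).
#' @param seed RNG seed for the control shuffles.
#' @return A `scan_params` list.
#' @export
scan_params <- function(widths = 3:5, p_threshold = 0.05,
                        min_sites_fraction = 0.20,
                        n_control_shuffles = 1L, seed = 1L) {
  stopifnot(all(widths >= 2 & widths <= 10),
            p_threshold > 0, p_threshold < 1,
            min_sites_fraction > 0, min_sites_fraction < 1,
            n_control_shuffles >= 1)
  structure(list(widths = as.integer(widths), p_threshold = p_threshold,
                 min_sites_fraction = min_sites_fraction,
                 n_control_shuffles = as.integer(n_control_shuffles),
                 seed = as.integer(seed)),
            class = "scan_params")
}

all_kmers <- function(seqs, w) {
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    unique(substring(s, seq_len(n - w + 1L), seq(w, n)))
  })))
}

count_containing <- function(kmers, seqs) {
  vapply(kmers, function(k) sum(vapply(seqs, function(s) {
    grepl(k, s, fixed = TRUE)
  }, logical(1))), integer(1))
}

#' Enriched ungapped k-mers versus shuffled controls
#'
#' The control set holds `n_control_shuffles` composition-preserving
#' shuffles of every positive sequence (seeded). Every k-mer occurring in
#' at least one positive is tested with a one-sided (greater) Fisher exact
#' test on the 2x2 table of sequences containing / not containing it in
#' positives versus controls. K-mers pass at `p < p_threshold` and
#' positive-set frequency >= `min_sites_fraction`, are ranked by ascending
#' p (ties by descending match count, then alphabetically), and a reported
#' k-mer suppresses lower-ranked k-mers contained within it as substrings.
#'
#' @param positives A `peptide_set` with >= 2 sequences.
#' @param params A [scan_params()].
#' @param cluster Optional cluster/community label carried into the report.
#' @param controls Optional explicit control `peptide_set`; when supplied
#'   it replaces the shuffled controls.
#' @return A MotifReport data.frame: motif, cluster, cluster_size,
#'   matches_query, matches_control, sites_percent (1 decimal), p_value,
#'   method.
#' @export
enriched_kmers <- function(positives, params = scan_params(), cluster = NA,
                           controls = NULL) {
  stopifnot(inherits(positives, "peptide_set"))
  if (length(positives) < 2L) {
    stop("need at least 2 positive sequences", call. = FALSE)
  }
  pos <- positives$sequences
  npos <- length(pos)
  controls <- if (!is.null(controls)) {
    stopifnot(inherits(controls, "peptide_set"))
    controls$sequences
  } else {
    with_seed(params$seed, {
      unlist(lapply(seq_len(params$n_control_shuffles), function(r) {
        vapply(pos, function(s) paste(sample(strsplit(s, "")[[1]]),
                                      collapse = ""), character(1))
      }))
    })
  }
  nneg <- length(controls)
  minlen <- min(nchar(pos))
  out <- list()
  for (w in params$widths) {
    if (w > minlen) {
      warning("width ", w, " exceeds the shortest positive sequence (",
              minlen, " aa); skipped", call. = FALSE)
      next
    }
    kmers <- all_kmers(pos, w)
    tp <- count_containing(kmers, pos)
    fp <- count_containing(kmers, controls)
    # one-sided Fisher exact test = hypergeometric upper tail
    p <- stats::phyper(tp - 1L, npos, nneg, tp + fp, lower.tail = FALSE)
    keep <- p < params$p_threshold & tp / npos >= params$min_sites_fraction
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        motif = kmers[keep], matches_query = tp[keep],
        matches_control = fp[keep], p_value = p[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(), cluster = character(),
                      cluster_size = integer(), matches_query = integer(),
                      matches_control = integer(), sites_percent = numeric(),
                      p_value = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  }
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$p_value, -rep$matches_query, rep$motif), ,
             drop = FALSE]
  kept <- character(0)
  keep_row <- logical(nrow(rep))
  for (i in seq_len(nrow(rep))) {
    m <- rep$motif[i]
    suppressed <- any(vapply(kept, function(k) {
      nchar(m) < nchar(k) && grepl(m, k, fixed = TRUE)
    }, logical(1)))
    if (!suppressed) {
      kept <- c(kept, m)
      keep_row[i] <- TRUE
    }
  }
  rep <- rep[keep_row, , drop = FALSE]
  data.frame(motif = rep$motif, cluster = cluster, cluster_size = npos,
             matches_query = rep$matches_query,
             matches_control = rep$matches_control,
             sites_percent = round_half_up(100 * rep$matches_query / npos, 1),
             p_value = rep$p_value, method = "kmer_scan",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pseudo-count enrichment ratio
#'
#' `((TP + 1)/(NPOS + 1)) / ((FP + 1)/(NNEG + 1))`: the smoothed ratio of
#' motif match rates in a query set of NPOS sequences (TP matched) versus
#' a control set of NNEG sequences (FP matched). Strictly increasing in TP
#' and strictly decreasing in FP.
#'
#' @param TP,FP Matched sequence counts in query and control.
#' @param NPOS,NNEG Query and control set sizes (>= 1).
#' @return The enrichment ratio (> 0).
#' @export
enrichment_ratio <- function(TP, FP, NPOS, NNEG) {
  if (NPOS < 1 || NNEG < 1) stop("NPOS and NNEG must be >= 1", call. = FALSE)
  if (TP < 0 || TP > NPOS) stop("need 0 <= TP <= NPOS", call. = FALSE)
  if (FP < 0 || FP > NNEG) stop("need 0 <= FP <= NNEG", call. = FALSE)
  ((TP + 1) / (NPOS + 1)) / ((FP + 1) / (NNEG + 1))
}

motif_to_regex <- function(motif) {
  if (!grepl("^([ACDEFGHIKLMNPQRSTVWY]|\\[[ACDEFGHIKLMNPQRSTVWY]+\\])+$",
             motif)) {
    stop("malformed motif pattern: '", motif,
         "' (uppercase residues, optional [..] alternatives)",
         call. = FALSE)
  }
  motif
}

#' Scan a motif list against query and control sets
#'
#' Each motif is matched as an exact substring; a bracketed position such
#' as `[GR]GG` matches any of the bracketed residues there. Results carry
#' the pseudo-count enrichment ratio and are sorted by descending ratio.
#'
#' @param motifs Character vector of ungapped motifs (optionally with
#'   bracket alternatives).
#' @param query,control `peptide_set`s.
#' @return Data.frame: motif, TP, FP, NPOS, NNEG, ratio.
#' @export
sea_scan <- function(motifs, query, control) {
  stopifnot(length(motifs) > 0, inherits(query, "peptide_set"),
            inherits(control, "peptide_set"),
            length(query) > 0, length(control) > 0)
  res <- lapply(motifs, function(m) {
    rx <- motif_to_regex(m)
    tp <- sum(grepl(rx, query$sequences))
    fp <- sum(grepl(rx, control$sequences))
    data.frame(motif = m, TP = tp, FP = fp,
               NPOS = length(query), NNEG = length(control),
               ratio = enrichment_ratio(tp, fp, length(query),
                                        length(control)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$ratio, out$motif), , drop = FALSE]
}

#' Community-wise motif discovery
#'
#' Runs the enriched-k-mer scan and consensus calling per community of an
#' HSP network: communities with >= `min_size` members are scanned
#' directly; all degree-0 singletons are pooled into one `"singletons"`
#' cluster, mirroring the practice of analysing atypical sequences
#' together.
#'
#' @param set The network's `peptide_set`.
#' @param g The `hsp_network` (for singleton detection).
#' @param p Its `community_partition`.
#' @param params A [scan_params()].
#' @param min_size Smallest community scanned (default 2).
#' @return List with `motifs` (row-bound MotifReport) and `consensus`
#'   (data.frame cluster/consensus string per aligned community).
#' @export
community_motifs <- function(set, g, p, params = scan_params(),
                             min_size = 2L) {
  stopifnot(inherits(set, "peptide_set"))
  deg <- igraph::degree(as_igraph(g))
  singleton_ids <- names(deg)[deg == 0]
  memb <- p$membership[set$ids]
  groups <- split(set$ids, memb)
  groups <- lapply(groups, setdiff, y = singleton_ids)
  groups <- groups[vapply(groups, length, integer(1)) >= min_size]
  if (length(singleton_ids) >= min_size) {
    groups[["singletons"]] <- singleton_ids
  }
  reports <- list(); consensi <- list()
  for (cl in names(groups)) {
    sub <- subset_peptides(set, groups[[cl]])
    reports[[cl]] <- enriched_kmers(sub, params, cluster = cl)
    block <- center_star_align(sub)
    consensi[[cl]] <- data.frame(cluster = cl,
                                 n_members = length(sub),
                                 consensus = consensus(block),
                                 stringsAsFactors = FALSE)
  }
  list(motifs = do.call(rbind, c(reports, list(make.row.names = FALSE))),
       consensus = do.call(rbind, c(consensi, list(make.row.names = FALSE))))
}
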