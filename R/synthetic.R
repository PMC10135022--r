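# Synthetic peptide families with implanted motifs.
#
# The generator produces the statistical structure the network analysis
# assumes: several motif-sharing families (mutated copies of a family
# ancestor, each carrying one identical ungapped motif at a random offset),
# unrelated background singletons, and categorical metadata. A
# composition-preserving shuffle provides the null sequences used as motif
# scan controls.

#' Configuration for the synthetic family generator
#'
#' @param n_families Number of families (>= 0).
#' @param family_size Members per family (>= 2).
#' @param n_singletons Number of unrelated background peptides (>= 0).
#' @param length_range Integer pair (min, max) peptide length; min >= 8,
#'   max <= 60.
#' @param motif_length_range Integer pair, implanted motif length bounds
#'   (within 3..8).
#' @param background_frequencies Named 20-vector of residue probabilities
#'   summing to 1 (default uniform 1/20).
#' @param mutation_rate Per-position substitution probability applied
#'   outside the motif when deriving family members from the ancestor.
#'   Substitutions draw from the background excluding the current residue,
#'   so this is the realised mismatch probability.
#' @param seed Integer seed; the whole set is reproducible from it.
#' @return A `family_config` list.
#' @export
family_config <- function(n_families = 10L, family_size = 14L,
                          n_singletons = 34L, length_range = c(8L, 45L),
                          motif_length_range = c(3L, 8L),
                          background_frequencies = NULL,
                          mutation_rate = 0.1, seed = 1L) {
  bg <- background_frequencies %||%
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  if (is.null(names(bg))) names(bg) <- AA_ALPHABET20
  if (!setequal(names(bg), AA_ALPHABET20)) {
    stop("background_frequencies must be named by the 20 amino acids",
         call. = FALSE)
  }
  bg <- bg[AA_ALPHABET20]
  if (abs(sum(bg) - 1) > 1e-9) {
    stop("background_frequencies must sum to 1 (within 1e-9)", call. = FALSE)
  }
  stopifnot(n_families >= 0, n_singletons >= 0,
            n_families == 0 || family_size >= 2,
            length_range[1] >= 8, length_range[2] <= 60,
            length_range[1] <= length_range[2],
            motif_length_range[1] >= 3, motif_length_range[2] <= 8,
            motif_length_range[1] <= motif_length_range[2],
            mutation_rate >= 0, mutation_rate <= 1)
  if (motif_length_range[2] > length_range[1]) {
    stop("motif may exceed the minimum peptide length: motif up to ",
         motif_length_range[2], " aa vs min length ", length_range[1],
         call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 n_singletons = as.integer(n_singletons),
                 length_range = as.integer(length_range),
                 motif_length_range = as.integer(motif_length_range),
                 background_frequencies = bg,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "family_config")
}

# sample one value from a vector, immune to R's scalar-expansion rule
pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

random_background <- function(n, bg) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE, prob = bg), collapse = "")
}

#' Generate synthetic peptide families with implanted motifs
#'
#' Each family is derived from a random background ancestor: members copy
#' the ancestor, substitute non-motif positions at `mutation_rate` (drawing
#' from the background distribution excluding the current residue), and
#' carry the family motif verbatim at a member-specific random offset.
#' Singletons are i.i.d. background sequences. Metadata assigns each family
#' a distinct synthetic origin and random activity/target/toxicity labels.
#'
#' @param config A [family_config()].
#' @return A list with components `peptides` (a `peptide_set`, metadata
#'   attached), `truth` (data.frame: peptide_id, family — integer index or
#'   "singleton" —, motif, offset), and `metadata` (the raw record table).
#' @export
generate_families <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  with_seed(config$seed, {
    bg <- config$background_frequencies
    ids <- character(0); seqs <- character(0)
    fam <- character(0); motifs <- character(0); offs <- integer(0)
    meta <- empty_metadata()
    activities <- c("antibiofilm", "antibacterial", "antifungal",
                    "immunomodulatory")
    targets <- c("gram-positive", "gram-negative", "fungus", "membrane")
    for (f in seq_len(config$n_families)) {
      mlen <- pick1(seq(config$motif_length_range[1],
                        config$motif_length_range[2]))
      motif <- random_background(mlen, bg)
      alen <- pick1(seq(config$length_range[1], config$length_range[2]))
      ancestor <- strsplit(random_background(alen, bg), "")[[1]]
      for (m in seq_len(config$family_size)) {
        member <- ancestor
        mutate <- stats::runif(alen) < config$mutation_rate
        for (pos in which(mutate)) {
          others <- setdiff(AA_ALPHABET20, member[pos])
          p <- bg[others]
          member[pos] <- sample(others, 1L, prob = p / sum(p))
        }
        off <- pick1(seq_len(alen - mlen + 1L))
        member[off:(off + mlen - 1L)] <- strsplit(motif, "")[[1]]
        id <- sprintf("fam%02d_m%02d", f, m)
        ids <- c(ids, id); seqs <- c(seqs, paste(member, collapse = ""))
        fam <- c(fam, as.character(f)); motifs <- c(motifs, motif)
        offs <- c(offs, off)
        meta <- rbind(meta, data.frame(
          peptide_id = id,
          field = c("database", "origin", "activity", "target", "toxicity"),
          value = c("synthetic",
                    sprintf("origin_%02d", f),
                    sample(activities, 1L),
                    sample(targets, 1L),
                    sample(c("toxic", "non-toxic"), 1L, prob = c(.2, .8))),
          stringsAsFactors = FALSE))
      }
    }
    for (s in seq_len(config$n_singletons)) {
      slen <- pick1(seq(config$length_range[1], config$length_range[2]))
      id <- sprintf("sing%02d", s)
      ids <- c(ids, id)
      seqs <- c(seqs, random_background(slen, bg))
      fam <- c(fam, "singleton"); motifs <- c(motifs, NA_character_)
      offs <- c(offs, NA_integer_)
      meta <- rbind(meta, data.frame(
        peptide_id = id,
        field = c("database", "origin", "activity", "target", "toxicity"),
        value = c("synthetic", "origin_singleton",
                  sample(activities, 1L), sample(targets, 1L),
                  sample(c("toxic", "non-toxic"), 1L, prob = c(.2, .8))),
        stringsAsFactors = FALSE))
    }
    set <- peptide_set(ids, seqs, name = "synthetic")
    set <- attach_metadata(set, meta)
    truth <- data.frame(peptide_id = ids, family = fam, motif = motifs,
                        offset = offs, stringsAsFactors = FALSE)
    list(peptides = set, truth = truth, metadata = meta)
  })
}

#' Write generator outputs to disk
#'
#' Writes `<prefix>.fasta`, `<prefix>.meta.tsv` and `<prefix>.truth.json`
#' for a [generate_families()] result, so a simulated study can be re-read
#' with [load_peptides()] / [read_metadata_tsv()].
#'
#' @param gen A list from [generate_families()].
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_synthetic <- function(gen, prefix) {
  fasta <- paste0(prefix, ".fasta")
  meta <- paste0(prefix, ".meta.tsv")
  truth <- paste0(prefix, ".truth.json")
  write_peptides(gen$peptides, fasta)
  write_metadata_tsv(gen$metadata, meta)
  jsonlite::write_json(gen$truth, truth, dataframe = "rows", na = "null",
                       pretty = TRUE)
  invisible(c(fasta = fasta, meta = meta, truth = truth))
}

#' Composition-preserving sequence shuffle
#'
#' Returns a uniformly random permutation of the residues of `seq`: same
#' length, same composition. Used to build motif-scan control sets.
#'
#' @param seq A non-empty amino-acid string.
#' @param seed Integer seed; the same (seq, seed) pair always yields the
#'   same permutation.
#' @return The shuffled string.
#' @export
shuffle_sequence <- function(seq, seed) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("'seq' must be a single non-empty string", call. = FALSE)
  }
  with_seed(seed, {
    paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  })
}
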