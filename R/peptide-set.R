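# Peptide sets: the single source of the peptide data model.
#
# A peptide_set is a light S3 container: parallel vectors of unique ids and
# validated uppercase sequences over the 20 standard amino-acid letters,
# plus an optional long-format metadata table (peptide_id, field, value).

METADATA_FIELDS <- c("database", "origin", "activity", "target", "toxicity")

#' Construct a peptide set
#'
#' @param ids Character vector of unique, non-empty identifiers.
#' @param sequences Character vector of amino-acid sequences (uppercased on
#'   input); only the 20 standard one-letter codes are accepted.
#' @param notes Optional free-text descriptions (e.g. the FASTA header after
#'   the first whitespace); never used as identifiers.
#' @param name Name of the set.
#' @return An object of class `peptide_set`.
#' @export
peptide_set <- function(ids, sequences, notes = NULL, name = "peptides") {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop("'ids' and 'sequences' must have equal length", call. = FALSE)
  }
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("peptide ids must be non-empty strings", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate peptide id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequences) | !nzchar(sequences)
  if (any(bad)) {
    offending <- vapply(sequences[bad], function(s) {
      chars <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET20)
      paste(chars, collapse = "")
    }, character(1))
    stop("invalid residue(s) in sequence(s): ",
         paste(sprintf("%s ['%s']", ids[bad], offending), collapse = "; "),
         call. = FALSE)
  }
  structure(
    list(ids = ids,
         sequences = sequences,
         notes = notes %||% rep("", length(ids)),
         metadata = empty_metadata(),
         name = name),
    class = "peptide_set"
  )
}

empty_metadata <- function() {
  data.frame(peptide_id = character(), field = character(),
             value = character(), stringsAsFactors = FALSE)
}

#' @export
length.peptide_set <- function(x) length(x$ids)

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set '%s': %d peptide(s), %d metadata record(s)\n",
              x$name, length(x$ids), nrow(x$metadata)))
  n <- min(6L, length(x$ids))
  if (n > 0L) {
    for (i in seq_len(n)) {
      cat(sprintf("  %s  %s (%d aa)\n", x$ids[i], x$sequences[i],
                  nchar(x$sequences[i])))
    }
    if (length(x$ids) > n) cat(sprintf("  ... %d more\n", length(x$ids) - n))
  }
  invisible(x)
}

#' @export
as.data.frame.peptide_set <- function(x, ...) {
  data.frame(id = x$ids, sequence = x$sequences, length = nchar(x$sequences),
             note = x$notes, stringsAsFactors = FALSE)
}

#' Subset a peptide set by id or index (metadata carried along)
#'
#' @param set A `peptide_set`.
#' @param ids Character vector of member ids, or integer indices.
#' @return A `peptide_set` restricted to the requested peptides, in the
#'   requested order.
#' @export
subset_peptides <- function(set, ids) {
  stopifnot(inherits(set, "peptide_set"))
  idx <- if (is.character(ids)) match(ids, set$ids) else as.integer(ids)
  if (anyNA(idx)) {
    stop("unknown peptide id(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- peptide_set(set$ids[idx], set$sequences[idx], set$notes[idx],
                     name = set$name)
  out$metadata <- set$metadata[set$metadata$peptide_id %in% out$ids, ,
                               drop = FALSE]
  rownames(out$metadata) <- NULL
  out
}

#' Read peptides from a FASTA file
#'
#' The header token before the first whitespace is the peptide id; the rest
#' of the header is kept as a note. Sequences are uppercased and validated
#' against the 20-letter amino-acid alphabet; ambiguity codes (B, J, O, U,
#' X, Z) are rejected rather than silently remapped, because all downstream
#' descriptors assume the standard alphabet.
#'
#' @param path Path to a FASTA file.
#' @param name Optional set name (defaults to the file name).
#' @return A `peptide_set`; input record order is preserved.
#' @export
load_peptides <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aa) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(peptide_set(character(), character(),
                       name = name %||% basename(path)))
  }
  headers <- names(aa)
  if (any(!nzchar(headers))) {
    stop("malformed FASTA '", path, "': record ",
         which(!nzchar(headers))[1], " has an empty header", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", headers)
  notes <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  peptide_set(ids, as.character(aa), notes, name = name %||% basename(path))
}

#' Write a peptide set to FASTA
#'
#' Emits UTF-8 with LF line endings, one record per peptide, preserving set
#' order so that write/load round-trips are exact.
#'
#' @param set A `peptide_set`.
#' @param path Output path.
#' @param width Line width for the sequence (default 70).
#' @return `path`, invisibly.
#' @export
write_peptides <- function(set, path, width = 70L) {
  stopifnot(inherits(set, "peptide_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(set$ids)) {
    hdr <- if (nzchar(set$notes[i])) {
      paste(set$ids[i], set$notes[i])
    } else {
      set$ids[i]
    }
    chunks <- substring(set$sequences[i],
                        seq(1, nchar(set$sequences[i]), by = width),
                        pmin(seq(width, nchar(set$sequences[i]) + width - 1,
                                 by = width), nchar(set$sequences[i])))
    writeLines(c(paste0(">", hdr), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a metadata table from TSV
#'
#' Expects a header row with columns `peptide_id`, `field`, `value`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame of metadata records.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("peptide_id", "field", "value")
  if (!all(need %in% names(tab))) {
    stop("metadata TSV must have columns peptide_id, field, value",
         call. = FALSE)
  }
  tab[, need]
}

#' Write a metadata table to TSV
#'
#' @param metadata Data.frame with columns peptide_id, field, value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("peptide_id", "field", "value"), collapse = "\t"), con)
  if (nrow(metadata)) {
    writeLines(paste(metadata$peptide_id, metadata$field, metadata$value,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Attach categorical metadata records to a peptide set
#'
#' Records are (peptide_id, field, value) triples with field one of
#' `database`, `origin`, `activity`, `target`, `toxicity`. Duplicate triples
#' are stored once. Every peptide_id must resolve to a member of the set.
#'
#' @param set A `peptide_set`.
#' @param records Data.frame with columns peptide_id, field, value.
#' @return The annotated `peptide_set`.
#' @export
attach_metadata <- function(set, records) {
  stopifnot(inherits(set, "peptide_set"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("peptide_id", "field", "value")
  if (!all(need %in% names(records))) {
    stop("metadata records need columns peptide_id, field, value",
         call. = FALSE)
  }
  records <- records[, need]
  unknown_id <- setdiff(unique(records$peptide_id), set$ids)
  if (length(unknown_id)) {
    stop("metadata refers to unknown peptide id(s): ",
         paste(unknown_id, collapse = ", "), call. = FALSE)
  }
  unknown_field <- setdiff(unique(records$field), METADATA_FIELDS)
  if (length(unknown_field)) {
    stop("unknown metadata field(s): ",
         paste(unknown_field, collapse = ", "),
         " (allowed: ", paste(METADATA_FIELDS, collapse = ", "), ")",
         call. = FALSE)
  }
  merged <- rbind(set$metadata, records)
  merged <- merged[!duplicated(merged), , drop = FALSE]
  rownames(merged) <- NULL
  set$metadata <- merged
  set
}

#' Metadata records of one peptide, grouped by field
#'
#' @param set An annotated `peptide_set`.
#' @param id A peptide id.
#' @return Named list mapping each metadata field to a character vector of
#'   values (possibly empty).
#' @export
peptide_metadata <- function(set, id) {
  stopifnot(inherits(set, "peptide_set"))
  if (!id %in% set$ids) stop("unknown peptide id: ", id, call. = FALSE)
  recs <- set$metadata[set$metadata$peptide_id == id, , drop = FALSE]
  out <- lapply(METADATA_FIELDS, function(f) recs$value[recs$field == f])
  names(out) <- METADATA_FIELDS
  out
}
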