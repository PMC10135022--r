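# Bipartite peptide-metadata networks (METNs).
#
# One layer holds peptides, the other holds (field, value) metadata
# categories; an unweighted edge links a peptide to every category it is
# annotated with. Betweenness on the bipartite graph ranks the metadata
# hubs that organise the peptide space.

#' Build a bipartite metadata network
#'
#' One metadata node per distinct (field, value) pair among the requested
#' fields, keyed `field:value`; one edge per metadata record. Peptides
#' without matching records stay as isolated peptide-layer nodes.
#'
#' @param set An annotated `peptide_set` (see [attach_metadata()]).
#' @param fields Non-empty subset of database, origin, activity, target,
#'   toxicity.
#' @return An undirected bipartite `igraph` with vertex attributes `layer`
#'   (peptide/metadata), `field` (metadata nodes) and logical `type`
#'   (TRUE for metadata).
#' @export
build_metn <- function(set, fields) {
  stopifnot(inherits(set, "peptide_set"))
  if (length(fields) == 0L) stop("'fields' must be non-empty", call. = FALSE)
  unknown <- setdiff(fields, METADATA_FIELDS)
  if (length(unknown)) {
    stop("unknown metadata field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  recs <- set$metadata[set$metadata$field %in% fields, , drop = FALSE]
  meta_keys <- unique(paste(recs$field, recs$value, sep = ":"))
  vertices <- data.frame(
    name = c(set$ids, meta_keys),
    layer = c(rep("peptide", length(set$ids)),
              rep("metadata", length(meta_keys))),
    field = c(rep(NA_character_, length(set$ids)),
              sub(":.*$", "", meta_keys)),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = recs$peptide_id,
                      to = paste(recs$field, recs$value, sep = ":"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$layer == "metadata"
  g
}

#' Betweenness centrality on a metadata network
#'
#' Brandes betweenness, unnormalised, hop distances, computed directly on
#' the bipartite graph (no projection). Metadata nodes are listed first,
#' ranked by descending betweenness.
#'
#' @param g A metadata network from [build_metn()].
#' @return Data.frame with columns node_id, layer, field, betweenness.
#' @export
metn_betweenness <- function(g) {
  stopifnot(inherits(g, "igraph"))
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  out <- data.frame(node_id = igraph::V(g)$name,
                    layer = igraph::V(g)$layer,
                    field = igraph::V(g)$field,
                    betweenness = btw, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$layer != "metadata", -out$betweenness, out$node_id), ,
      drop = FALSE]
}

#' Export a metadata network to GraphML
#'
#' @param g A metadata network from [build_metn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metn_graphml <- function(g, path) {
  # GraphML has no NA notion; blank out the field attribute on peptides
  f <- igraph::V(g)$field
  f[is.na(f)] <- ""
  igraph::V(g)$field <- f
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
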