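# Node centralities and atypical-peptide detection.

#' Degree, harmonic, betweenness and hub-bridge centralities
#'
#' Degree is the unweighted incident-edge count. Harmonic centrality is
#' the sum of reciprocal hop-count shortest-path distances (unreachable
#' nodes contribute 0). Betweenness is Brandes shortest-path betweenness,
#' unnormalised, on hop distances. Hub-bridge centrality is
#' `degree(v) * (1 + f(v))` where f(v) is the number of distinct
#' communities other than v's own represented among v's neighbours: 0 for
#' singletons, equal to degree inside a single community, and boosted for
#' nodes that bridge communities.
#'
#' @param g An `hsp_network`.
#' @param p A `community_partition` computed on `g`.
#' @return A data.frame (CentralityTable) with columns node_id, degree,
#'   harmonic, betweenness, hub_bridge, community.
#' @export
compute_centralities <- function(g, p) {
  stopifnot(inherits(g, "hsp_network"), inherits(p, "community_partition"))
  ig <- as_igraph(g)
  ids <- igraph::V(ig)$name
  deg <- igraph::degree(ig)
  harm <- igraph::harmonic_centrality(ig, weights = NA, normalized = FALSE)
  btw <- igraph::betweenness(ig, weights = NA, normalized = FALSE)
  memb <- p$membership[ids]
  hb <- vapply(seq_along(ids), function(i) {
    if (deg[i] == 0) return(0)
    nb <- igraph::neighbors(ig, i)$name
    foreign <- setdiff(unique(memb[nb]), memb[i])
    deg[i] * (1 + length(foreign))
  }, numeric(1))
  data.frame(node_id = ids, degree = as.integer(deg), harmonic = harm,
             betweenness = btw, hub_bridge = hb,
             community = as.integer(memb), row.names = NULL,
             stringsAsFactors = FALSE)
}

CENTRALITY_METRICS <- c("degree", "harmonic", "betweenness", "hub_bridge")

#' Top-k nodes by a centrality metric
#'
#' Descending by the metric, ties broken by lexicographic node id; k larger
#' than the table is clamped to a full ranking.
#'
#' @param tab A centrality table from [compute_centralities()].
#' @param metric One of degree, harmonic, betweenness, hub_bridge.
#' @param k Number of nodes (>= 1).
#' @return Character vector of node ids.
#' @export
top_k <- function(tab, metric, k = 10L) {
  if (!metric %in% CENTRALITY_METRICS) {
    stop("unknown metric '", metric, "' (use one of ",
         paste(CENTRALITY_METRICS, collapse = ", "), ")", call. = FALSE)
  }
  stopifnot(k >= 1)
  ord <- order(-tab[[metric]], tab$node_id)
  tab$node_id[ord][seq_len(min(k, nrow(tab)))]
}

#' Cross-metric top-k membership counts
#'
#' For each node appearing in at least one metric's top-k, reports how many
#' of the four centrality rankings include it — the structure behind
#' "consensus most-central" tables.
#'
#' @param tab A centrality table.
#' @param k Top-list size per metric.
#' @return Data.frame with columns node_id, n_metrics, metrics, sorted by
#'   decreasing n_metrics then node id.
#' @export
top_k_overlap <- function(tab, k = 10L) {
  tops <- lapply(CENTRALITY_METRICS, function(m) top_k(tab, m, k))
  names(tops) <- CENTRALITY_METRICS
  ids <- sort(unique(unlist(tops)))
  n_metrics <- vapply(ids, function(id) {
    sum(vapply(tops, function(t) id %in% t, logical(1)))
  }, integer(1))
  metrics <- vapply(ids, function(id) {
    paste(CENTRALITY_METRICS[vapply(tops, function(t) id %in% t,
                                    logical(1))], collapse = ",")
  }, character(1))
  out <- data.frame(node_id = ids, n_metrics = n_metrics, metrics = metrics,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_metrics, out$node_id), , drop = FALSE]
}

#' Atypical peptides: singletons and isolated pairs
#'
#' Enumerates connected components; size-1 components are singletons
#' (degree 0 after cutoff filtering), size-2 components are the simplest
#' possible communities.
#'
#' @param g An `hsp_network`.
#' @return List with `singletons` (character vector) and `isolated_pairs`
#'   (list of length-2 character vectors).
#' @export
find_atypicals <- function(g) {
  stopifnot(inherits(g, "hsp_network"))
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  ids <- igraph::V(ig)$name
  singletons <- character(0)
  pairs <- list()
  for (c_idx in seq_len(comp$no)) {
    members <- ids[comp$membership == c_idx]
    if (length(members) == 1L) {
      singletons <- c(singletons, members)
    } else if (length(members) == 2L) {
      pairs[[length(pairs) + 1L]] <- sort(members)
    }
  }
  list(singletons = sort(singletons), isolated_pairs = pairs)
}
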