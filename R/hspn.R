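# Half-space proximal network construction and cutoff analysis.
#
# The HSP test builds, for each node, edges to successively nearest
# candidates while discarding every candidate that lies closer to the new
# neighbour than to the node itself (it falls on the neighbour's side of
# the bisecting hyperplane). The undirected union over all nodes is a
# sparse connected spanner of the complete similarity graph.

#' Half-space proximal network from distance/similarity matrices
#'
#' For each node u the candidate set starts as all other nodes; repeatedly
#' the nearest candidate v (ties broken by input order) receives a directed
#' edge u -> v, and every candidate w with d(w, v) < d(w, u) is discarded
#' (strict inequality: equidistant candidates stay, which preserves the
#' connectivity guarantee in degenerate configurations). Directed edges are
#' symmetrised by union and weighted with the similarity s(u, v).
#'
#' @param d A `distance_matrix` (n >= 2).
#' @param s A `similarity_matrix` over the same peptides in the same order.
#' @return An `hsp_network` with no cutoff applied.
#' @export
hsp_edges <- function(d, s) {
  stopifnot(inherits(d, "distance_matrix"), inherits(s, "similarity_matrix"))
  if (!identical(d$ids, s$ids)) {
    stop("distance and similarity matrices must share peptide order",
         call. = FALSE)
  }
  n <- length(d$ids)
  if (n < 2L) stop("need at least 2 peptides", call. = FALSE)
  dm <- d$values
  seen <- matrix(FALSE, n, n)
  from <- integer(0); to <- integer(0)
  for (u in seq_len(n)) {
    cand <- setdiff(seq_len(n), u)
    while (length(cand)) {
      v <- cand[which.min(dm[u, cand])]
      a <- min(u, v); b <- max(u, v)
      if (!seen[a, b]) {
        seen[a, b] <- TRUE
        from <- c(from, a); to <- c(to, b)
      }
      keep <- dm[cand, v] >= dm[cand, u]
      cand <- setdiff(cand[keep], v)
    }
  }
  edges <- data.frame(from = d$ids[from], to = d$ids[to],
                      weight = s$values[cbind(from, to)],
                      stringsAsFactors = FALSE)
  structure(list(node_ids = d$ids, edges = edges, cutoff = NA_real_),
            class = "hsp_network")
}

#' @export
print.hsp_network <- function(x, ...) {
  cat(sprintf("hsp_network: %d nodes, %d edges, cutoff %s\n",
              length(x$node_ids), nrow(x$edges),
              if (is.na(x$cutoff)) "none" else format(x$cutoff)))
  invisible(x)
}

#' Filter an HSP network by similarity cutoff
#'
#' Only edges whose similarity weight is strictly greater than the cutoff
#' are retained; nodes are never removed, so low-similarity peptides become
#' singletons.
#'
#' @param g An `hsp_network`.
#' @param t Cutoff in \[0, 1).
#' @return The filtered `hsp_network` with `cutoff = t`.
#' @export
apply_cutoff <- function(g, t) {
  stopifnot(inherits(g, "hsp_network"))
  assert_scalar_number(t, "t")
  if (t < 0 || t >= 1) stop("cutoff must lie in [0, 1)", call. = FALSE)
  if (!is.na(g$cutoff) && g$cutoff >= t) {
    stop("graph was already filtered at cutoff ", g$cutoff,
         "; rebuild from the unfiltered network", call. = FALSE)
  }
  g$edges <- g$edges[g$edges$weight > t, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$cutoff <- t
  g
}

#' Convert an HSP network to an igraph object
#'
#' Isolated nodes are retained; edge weights carry the similarity.
#'
#' @param g An `hsp_network`.
#' @return An undirected weighted `igraph` graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "hsp_network"))
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = data.frame(name = g$node_ids))
  ig
}

#' Louvain community detection on an HSP network
#'
#' Greedy modularity optimisation (local moves + aggregation) on the
#' similarity-weighted graph. Isolated nodes become their own communities.
#' An edgeless graph yields one community per node with modularity 0 by
#' convention (and a warning).
#'
#' @param g An `hsp_network` or `igraph` graph.
#' @param seed Integer seed making the partition deterministic.
#' @param resolution Louvain resolution parameter (default 1).
#' @param weighted Use similarity weights (default TRUE).
#' @return A `community_partition`: `membership` (named integer vector,
#'   community indices contiguous from 0), `n_communities`, `modularity`.
#' @export
louvain_communities <- function(g, seed = 1L, resolution = 1,
                                weighted = TRUE) {
  ig <- if (inherits(g, "hsp_network")) as_igraph(g) else g
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(ig)) {
    igraph::E(ig)$weight
  } else {
    NULL
  }
  if (igraph::ecount(ig) == 0L) {
    warning("edgeless graph: every node is its own community, modularity 0",
            call. = FALSE)
    memb <- seq_len(igraph::vcount(ig)) - 1L
    names(memb) <- igraph::V(ig)$name
    return(structure(list(membership = memb,
                          n_communities = length(memb),
                          modularity = 0),
                     class = "community_partition"))
  }
  cl <- with_seed(seed, igraph::cluster_louvain(ig, weights = w,
                                                resolution = resolution))
  memb <- igraph::membership(cl)
  # relabel contiguously from 0 in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(memb) <- igraph::V(ig)$name
  q <- igraph::modularity(ig, memb + 1L, weights = w)
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 modularity = q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Topology summary of an HSP network
#'
#' Density, modularity, average clustering coefficient (nodes of degree
#' < 2 contribute 0), number of communities and singletons (degree-0
#' nodes), and hop-count diameter / average path length over reachable
#' pairs only. A network with no reachable pairs reports 0 for both with
#' `path_stats_defined = FALSE`.
#'
#' @param g An `hsp_network`.
#' @param p A `community_partition` computed on `g`.
#' @return One-row data.frame (a NetworkSummary record).
#' @export
network_summary <- function(g, p) {
  stopifnot(inherits(g, "hsp_network"), inherits(p, "community_partition"))
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  m <- igraph::ecount(ig)
  density <- if (n >= 2) 2 * m / (n * (n - 1)) else 0
  local_cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0  # degree-1 nodes
  acc <- if (n > 0) mean(local_cc) else 0
  deg <- igraph::degree(ig)
  sp <- igraph::distances(ig, weights = NA)
  finite <- sp[upper.tri(sp)][is.finite(sp[upper.tri(sp)])]
  defined <- length(finite) > 0
  data.frame(
    n_nodes = n,
    n_edges = m,
    density = density,
    modularity = p$modularity,
    average_clustering_coefficient = acc,
    n_communities = p$n_communities,
    n_singletons = sum(deg == 0),
    diameter = if (defined) max(finite) else 0,
    average_path_length = if (defined) mean(finite) else 0,
    path_stats_defined = defined,
    cutoff = if (is.na(g$cutoff)) 0 else g$cutoff
  )
}

#' Degree histogram of a network
#'
#' @param g An `hsp_network`.
#' @return Data.frame with columns `degree` and `count`; counts sum to the
#'   number of nodes.
#' @export
degree_distribution_table <- function(g) {
  stopifnot(inherits(g, "hsp_network"))
  deg <- igraph::degree(as_igraph(g))
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Default similarity-cutoff grid
#'
#' 0 (no cutoff) then 0.30 to 0.95 in steps of 0.05.
#'
#' @return Numeric vector of cutoffs.
#' @export
default_cutoff_grid <- function() {
  c(0, seq(0.30, 0.95, by = 0.05))
}

#' Scan network topology over a similarity-cutoff grid
#'
#' The HSP edge set is computed once and filtered at each cutoff; each
#' filtered network is clustered (Louvain, seeded) and summarised. Used to
#' choose the working cutoff by inspecting how density, modularity, ACC,
#' communities/singletons and path statistics trade off.
#'
#' @param d A `distance_matrix`.
#' @param s The matching `similarity_matrix`.
#' @param grid Sorted cutoffs in \[0, 1) (default [default_cutoff_grid()]).
#' @param seed Seed passed to Louvain at every cutoff.
#' @return Data.frame with one NetworkSummary row per cutoff.
#' @export
cutoff_scan <- function(d, s, grid = default_cutoff_grid(), seed = 1L) {
  if (is.unsorted(grid) || any(grid < 0 | grid >= 1)) {
    stop("grid must be sorted cutoffs in [0, 1)", call. = FALSE)
  }
  base <- hsp_edges(d, s)
  rows <- lapply(grid, function(t) {
    g <- base
    g$edges <- g$edges[g$edges$weight > t, , drop = FALSE]
    g$cutoff <- t
    p <- suppressWarnings(louvain_communities(g, seed = seed))
    network_summary(g, p)
  })
  do.call(rbind, rows)
}

#' Export an HSP network to GraphML
#'
#' Node attributes: community index, the four centralities, and 2-D
#' principal-component coordinates of the descriptor space; edge attribute:
#' similarity weight. The file loads directly into standard graph viewers.
#'
#' @param g An `hsp_network`.
#' @param path Output path.
#' @param partition Optional `community_partition`.
#' @param centralities Optional centrality table from
#'   [compute_centralities()].
#' @param coords Optional data.frame from [pca_coords()].
#' @return `path`, invisibly.
#' @export
write_hspn_graphml <- function(g, path, partition = NULL,
                               centralities = NULL, coords = NULL) {
  ig <- as_igraph(g)
  ids <- igraph::V(ig)$name
  if (!is.null(partition)) {
    igraph::V(ig)$community <- as.integer(partition$membership[ids])
  }
  if (!is.null(centralities)) {
    idx <- match(ids, centralities$node_id)
    for (col in c("degree", "harmonic", "betweenness", "hub_bridge")) {
      ig <- igraph::set_vertex_attr(ig, col, value = centralities[[col]][idx])
    }
  }
  if (!is.null(coords)) {
    idx <- match(ids, coords$id)
    igraph::V(ig)$x <- coords$pc1[idx]
    igraph::V(ig)$y <- coords$pc2[idx]
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
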