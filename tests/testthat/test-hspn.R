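test_that("HSP test on collinear points keeps only consecutive edges", {
  gm <- geom_matrices(cbind(c(0, 1, 3)))
  net <- hsp_edges(gm$d, gm$s)
  expect_identical(edge_matrix_of(net),
                   matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE,
                          dimnames = NULL))
})

test_that("two nodes give a single edge; one node is an error", {
  gm <- geom_matrices(cbind(c(0, 2)))
  net <- hsp_edges(gm$d, gm$s)
  expect_identical(nrow(net$edges), 1L)
  gm1 <- list(
    d = structure(list(ids = "a", values = matrix(0, 1, 1)),
                  class = "distance_matrix"))
  expect_error(hsp_edges(gm1$d, to_similarity(gm1$d)), "at least 2")
})

test_that("hsp_edges matches the brute-force oracle and stays connected", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    gm <- geom_matrices(cbind(runif(n), runif(n)))
    net <- hsp_edges(gm$d, gm$s)
    expect_identical(edge_matrix_of(net), hsp_oracle_edges(gm$d$values))
    expect_true(igraph::is_connected(as_igraph(net)))
  }
})

test_that("edge weights carry similarity and the graph is simple", {
  set.seed(4)
  gm <- geom_matrices(cbind(runif(12), runif(12)))
  net <- hsp_edges(gm$d, gm$s)
  for (k in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[k],
                 gm$s$values[net$edges$from[k], net$edges$to[k]])
  }
  expect_false(any(net$edges$from == net$edges$to))
  expect_identical(anyDuplicated(edge_matrix_of(net)), 0L)
})

test_that("cutoff filtering retains strictly-greater weights only", {
  gm <- geom_matrices(cbind(c(0, 1, 3, 7)))
  net <- hsp_edges(gm$d, gm$s)
  w <- sort(net$edges$weight)
  g1 <- apply_cutoff(net, w[1])          # boundary weight removed
  expect_false(w[1] %in% g1$edges$weight)
  g0 <- apply_cutoff(net, 0)
  expect_identical(nrow(g0$edges), sum(net$edges$weight > 0))
  ghigh <- apply_cutoff(net, max(net$edges$weight) - 1e-12)
  expect_lt(nrow(ghigh$edges), nrow(net$edges))
  expect_error(apply_cutoff(net, 1), "\\[0, 1\\)")
  expect_error(apply_cutoff(net, -0.1), "\\[0, 1\\)")
  expect_error(apply_cutoff(g1, w[1] / 2), "already")
})

test_that("edge sets are nested along an increasing cutoff grid", {
  set.seed(13)
  gm <- geom_matrices(matrix(runif(40), ncol = 2))
  net <- hsp_edges(gm$d, gm$s)
  grid <- c(0, 0.3, 0.5, 0.7, 0.9)
  prev <- NULL
  for (t in grid) {
    g <- apply_cutoff(net, t)
    key <- paste(g$edges$from, g$edges$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("Louvain recovers closed-form modularity on disjoint triangles", {
  tri2 <- structure(list(
    node_ids = letters[1:6],
    edges = data.frame(from = c("a", "b", "c", "d", "e", "f"),
                       to = c("b", "c", "a", "e", "f", "d"),
                       weight = 1),
    cutoff = NA_real_), class = "hsp_network")
  p <- louvain_communities(tri2, seed = 1)
  expect_identical(p$n_communities, 2L)
  expect_equal(p$modularity, 0.5)
  # one triangle: a single community, Q = 0
  tri1 <- tri2; tri1$node_ids <- letters[1:3]
  tri1$edges <- tri1$edges[1:3, ]
  p1 <- louvain_communities(tri1, seed = 1)
  expect_identical(p1$n_communities, 1L)
  expect_equal(p1$modularity, 0)
})

test_that("isolated nodes form their own communities; edgeless graph warns", {
  g <- structure(list(node_ids = paste0("n", 1:20),
                      edges = data.frame(from = character(),
                                         to = character(),
                                         weight = numeric()),
                      cutoff = 0.9), class = "hsp_network")
  expect_warning(p <- louvain_communities(g, seed = 1), "edgeless")
  expect_identical(p$n_communities, 20L)
  expect_equal(p$modularity, 0)
  expect_identical(sort(unique(unname(p$membership))), 0:19)
})

test_that("reported modularity is self-consistent with the partition", {
  set.seed(31)
  for (rep in 1:5) {
    gm <- geom_matrices(matrix(runif(60), ncol = 2))
    net <- apply_cutoff(hsp_edges(gm$d, gm$s), 0.3)
    p <- suppressWarnings(louvain_communities(net, seed = rep))
    ig <- as_igraph(net)
    q <- igraph::modularity(ig, p$membership[igraph::V(ig)$name] + 1,
                            weights = igraph::E(ig)$weight)
    expect_equal(p$modularity, q, tolerance = 1e-9)
  }
})

test_that("network summaries match closed forms on canonical graphs", {
  tri <- structure(list(node_ids = c("a", "b", "c"),
                        edges = data.frame(from = c("a", "b", "c"),
                                           to = c("b", "c", "a"),
                                           weight = 1),
                        cutoff = NA_real_), class = "hsp_network")
  s <- network_summary(tri, louvain_communities(tri, 1))
  expect_equal(s$density, 1)
  expect_equal(s$average_clustering_coefficient, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$average_path_length, 1)
  expect_identical(s$n_singletons, 0L)

  path3 <- structure(list(node_ids = c("a", "b", "c"),
                          edges = data.frame(from = c("a", "b"),
                                             to = c("b", "c"),
                                             weight = 1),
                          cutoff = NA_real_), class = "hsp_network")
  sp <- network_summary(path3, louvain_communities(path3, 1))
  expect_equal(sp$density, 2 / 3)
  expect_equal(sp$average_clustering_coefficient, 0)
  expect_equal(sp$diameter, 2)
  expect_equal(sp$average_path_length, 4 / 3)

  empty5 <- structure(list(node_ids = paste0("n", 1:5),
                           edges = data.frame(from = character(),
                                              to = character(),
                                              weight = numeric()),
                           cutoff = 0.5), class = "hsp_network")
  se <- suppressWarnings(
    network_summary(empty5, louvain_communities(empty5, 1)))
  expect_equal(se$density, 0)
  expect_identical(se$n_singletons, 5L)
  expect_equal(se$diameter, 0)
  expect_false(se$path_stats_defined)
})

test_that("degree histograms are exact and satisfy the handshake lemma", {
  star <- structure(list(node_ids = c("h", "l1", "l2", "l3", "l4"),
                         edges = data.frame(from = "h",
                                            to = c("l1", "l2", "l3", "l4"),
                                            weight = 1),
                         cutoff = NA_real_), class = "hsp_network")
  h <- degree_distribution_table(star)
  expect_identical(h$count[h$degree == 4], 1L)
  expect_identical(h$count[h$degree == 1], 4L)
  expect_identical(sum(h$count), 5L)
  set.seed(6)
  gm <- geom_matrices(matrix(runif(30), ncol = 2))
  net <- hsp_edges(gm$d, gm$s)
  h2 <- degree_distribution_table(net)
  expect_identical(sum(h2$degree * h2$count), 2L * nrow(net$edges))
})

test_that("cutoff_scan emits one row per cutoff with non-increasing density", {
  set.seed(17)
  gm <- geom_matrices(matrix(runif(50), ncol = 2))
  single <- cutoff_scan(gm$d, gm$s, grid = 0, seed = 1)
  expect_identical(nrow(single), 1L)
  net <- hsp_edges(gm$d, gm$s)
  p <- louvain_communities(net, seed = 1)
  expect_equal(single$n_edges, nrow(net$edges))
  expect_equal(single$modularity, p$modularity)

  grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  tab <- cutoff_scan(gm$d, gm$s, grid = grid, seed = 1)
  expect_identical(nrow(tab), length(grid))
  expect_true(all(diff(tab$density) <= 1e-12))
  expect_error(cutoff_scan(gm$d, gm$s, grid = c(0.5, 0.3)), "sorted")
})

test_that("more communities appear at high cutoffs on family-structured data", {
  wins <- 0
  for (seed in 1:10) {
    gen <- generate_families(family_config(n_families = 3, family_size = 5,
                                           n_singletons = 3, seed = seed))
    d <- distance_matrix(minmax_normalize(
      compute_descriptors(gen$peptides)))
    s <- to_similarity(d)
    tab <- cutoff_scan(d, s, grid = c(0, 0.9), seed = seed)
    wins <- wins + (tab$n_communities[2] >= tab$n_communities[1])
  }
  expect_identical(wins, 10)
})

test_that("GraphML export writes node/edge attributes readable by igraph", {
  set.seed(2)
  gen <- generate_families(family_config(n_families = 2, family_size = 3,
                                         n_singletons = 2, seed = 2))
  desc <- minmax_normalize(compute_descriptors(gen$peptides))
  d <- distance_matrix(desc); s <- to_similarity(d)
  net <- hsp_edges(d, s)
  p <- louvain_communities(net, 1)
  cent <- compute_centralities(net, p)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_hspn_graphml(net, path, p, cent, pca_coords(desc))
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, gen$peptides$ids)
  expect_true(all(c("community", "harmonic", "x", "y") %in%
                    igraph::vertex_attr_names(back)))
  expect_true("weight" %in% igraph::edge_attr_names(back))
})
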