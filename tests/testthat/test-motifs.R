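test_that("center-star alignment handles identical and gapped pairs", {
  two <- pset(c("GIGAVLK", "GIGAVLK"))
  block <- center_star_align(two)
  expect_identical(block$rows, c("GIGAVLK", "GIGAVLK"))
  gapped <- center_star_align(pset(c("ACD", "AD")))
  expect_identical(gapped$rows, c("ACD", "A-D"))
  expect_warning(center_star_align(pset("ACDEF")), "single sequence")
})

test_that("de-gapping any alignment row recovers its input sequence", {
  set.seed(81)
  for (rep in 1:5) {
    gen <- generate_families(family_config(n_families = 1, family_size = 5,
                                           n_singletons = 0,
                                           length_range = c(10, 30),
                                           seed = rep))
    block <- center_star_align(gen$peptides)
    expect_identical(unname(nchar(block$rows)),
                     rep(nchar(block$rows[1]), length(block$rows)))
    degapped <- gsub("-", "", block$rows, fixed = TRUE)
    expect_identical(degapped, gen$peptides$sequences)
  }
})

test_that("consensus applies the capital/lowercase/x convention", {
  block <- function(rows) {
    structure(list(ids = paste0("r", seq_along(rows)), rows = rows),
              class = "alignment_block")
  }
  # unanimous column -> capital
  expect_identical(consensus(block(c("K", "K", "K"))), "K")
  # 3/5 K -> capital (f = 0.6 >= 0.5)
  expect_identical(consensus(block(c("K", "K", "R", "R", "K"))), "K")
  # four mutually negative-scoring residues -> x
  expect_identical(consensus(block(c("G", "W", "D", "P"))), "x")
  # plurality below 0.5 but positive-scoring vs half the column -> lowercase
  # column {K, K, R, R, R, E, E}: plurality R (f = 3/7 < 0.5), B62
  # R scores > 0 vs K (2) and R (5): 5/7 >= 0.5 -> "r"
  expect_identical(consensus(block(c("K", "K", "R", "R", "R", "E", "E"))),
                   "r")
  # all-gap column -> x
  expect_identical(consensus(block(c("K-A", "K-A"))), "KxA")
  # invariant to row order
  rows <- c("KWRK", "KWRA", "RWKA")
  expect_identical(consensus(block(rows)), consensus(block(rev(rows))))
})

test_that("a set scanned against itself yields no enriched k-mer", {
  set.seed(83)
  pos <- random_peptide_set(8, c(10, 20))
  rep <- enriched_kmers(pos, scan_params(seed = 1), controls = pos)
  expect_identical(nrow(rep), 0L)
})

test_that("scan p-values equal the Fisher exact test on the same tables", {
  set.seed(84)
  gen <- generate_families(family_config(n_families = 1, family_size = 6,
                                         n_singletons = 0,
                                         motif_length_range = c(4, 4),
                                         length_range = c(12, 20),
                                         seed = 84))
  rep <- enriched_kmers(gen$peptides, scan_params(widths = 3:4, seed = 9))
  expect_gt(nrow(rep), 0)
  npos <- length(gen$peptides)
  nneg <- npos  # one shuffle per positive
  for (i in seq_len(nrow(rep))) {
    tab <- matrix(c(rep$matches_query[i], npos - rep$matches_query[i],
                    rep$matches_control[i], nneg - rep$matches_control[i]),
                  2, 2, byrow = TRUE)
    want <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(rep$p_value[i], want, tolerance = 1e-9)
  }
})

test_that("reporting rule: sites percent at one decimal, threshold filters", {
  # 7 of 15 positives carry the motif; controls carry none
  with_m <- replicate(7, paste0(random_peptide(4), "FWKWA",
                                random_peptide(4)))
  without <- replicate(8, random_peptide(13))
  positives <- pset(c(with_m, without))
  controls <- pset(replicate(15, random_peptide(13)), prefix = "c")
  rep <- enriched_kmers(positives, scan_params(widths = 5, seed = 2),
                        controls = controls)
  row <- rep[rep$motif == "FWKWA", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$matches_query, 7L)
  expect_equal(row$sites_percent, 46.7)
  # 16 of 23 -> 69.6
  with16 <- replicate(16, paste0(random_peptide(3), "MCHNP",
                                 random_peptide(3)))
  pos23 <- pset(c(with16, replicate(7, random_peptide(11))))
  ctl23 <- pset(replicate(23, random_peptide(11)), prefix = "c")
  rep23 <- enriched_kmers(pos23, scan_params(widths = 5, seed = 3),
                          controls = ctl23)
  expect_equal(rep23$sites_percent[rep23$motif == "MCHNP"], 69.6)
})

test_that("a higher-ranked k-mer suppresses substring k-mers below it", {
  set.seed(86)
  pos <- pset(replicate(10, paste0(random_peptide(3), "FWKWA",
                                   random_peptide(3))))
  # controls contain the inner trimer often, the full motif never
  ctl <- pset(c(replicate(5, paste0(random_peptide(4), "FWK",
                                    random_peptide(4))),
                replicate(5, random_peptide(11))), prefix = "c")
  rep <- enriched_kmers(pos, scan_params(widths = 3:5, seed = 4),
                        controls = ctl)
  expect_true("FWKWA" %in% rep$motif)
  expect_false("FWK" %in% rep$motif)   # substring of a better-ranked motif
  expect_false("WKW" %in% rep$motif)
})

test_that("widths longer than the shortest positive are skipped with warning", {
  pos <- pset(c("ACDK", "ACDR", "ACDW"))
  expect_warning(rep <- enriched_kmers(pos, scan_params(widths = 3:5,
                                                        seed = 5)),
                 "skipped")
  expect_true(all(nchar(rep$motif) <= 4))
  expect_error(enriched_kmers(pset("ACDK")), "at least 2")
})

test_that("implanted family motifs are recovered by the width-5 scan", {
  found <- 0
  for (seed in 1:5) {
    gen <- generate_families(family_config(
      n_families = 1, family_size = 10, n_singletons = 0,
      motif_length_range = c(5, 5), length_range = c(15, 30),
      mutation_rate = 0.1, seed = seed))
    motif <- gen$truth$motif[1]
    rep <- enriched_kmers(gen$peptides, scan_params(widths = 5,
                                                    seed = seed))
    if (motif %in% rep$motif &&
        rep$sites_percent[rep$motif == motif] == 100) {
      found <- found + 1
    }
  }
  expect_gte(found, 4)
})

test_that("the enrichment ratio is exact, validated and monotone", {
  expect_equal(enrichment_ratio(0, 0, 9, 9), 1.0)
  expect_equal(enrichment_ratio(9, 0, 9, 9), 10.0)
  expect_equal(enrichment_ratio(6, 1, 13, 13), 3.5)
  expect_error(enrichment_ratio(10, 0, 9, 9), "TP")
  expect_error(enrichment_ratio(0, -1, 9, 9), "FP")
  expect_error(enrichment_ratio(0, 0, 0, 9), "NPOS")
  # strictly increasing in TP, decreasing in FP (spot grid)
  for (npos in c(5, 12)) for (tp in 0:(npos - 1)) {
    expect_lt(enrichment_ratio(tp, 2, npos, 10),
              enrichment_ratio(tp + 1, 2, npos, 10))
  }
  for (fp in 0:9) {
    expect_gt(enrichment_ratio(3, fp, 10, 10),
              enrichment_ratio(3, fp + 1, 10, 10))
  }
})

test_that("sea_scan counts substring matches with bracket alternatives", {
  query <- pset(c("KWRRWVRWI", "AGGGA", "ARGGA", "MMMMM"))
  control <- pset(c("PPPPP", "QQQQQ", "AGGGA", "NNNNN"), prefix = "c")
  res <- sea_scan(c("KWRRWVRWI", "[GR]GG", "YYY"), query, control)
  expect_identical(res$TP[res$motif == "KWRRWVRWI"], 1L)
  expect_identical(res$TP[res$motif == "[GR]GG"], 2L)  # AGGGA + ARGGA
  expect_identical(res$FP[res$motif == "[GR]GG"], 1L)
  # absent motif with equal set sizes -> ratio 1
  expect_equal(res$ratio[res$motif == "YYY"], 1.0)
  # sorted by descending ratio
  expect_true(all(diff(res$ratio) <= 0))
  expect_error(sea_scan("K[Z]G", query, control), "malformed")
  expect_error(sea_scan("k-g", query, control), "malformed")
})

test_that("community_motifs scans communities and pools singletons", {
  gen <- generate_families(family_config(n_families = 2, family_size = 6,
                                         n_singletons = 3,
                                         motif_length_range = c(5, 5),
                                         length_range = c(15, 30),
                                         seed = 91))
  set <- gen$peptides
  d <- distance_matrix(minmax_normalize(compute_descriptors(set)))
  s <- to_similarity(d)
  net <- apply_cutoff(hsp_edges(d, s), 0.65)
  p <- suppressWarnings(louvain_communities(net, 1))
  out <- community_motifs(set, net, p, scan_params(widths = 5, seed = 91))
  expect_true(is.data.frame(out$consensus))
  expect_gt(nrow(out$consensus), 0)
  deg <- igraph::degree(as_igraph(net))
  if (sum(deg == 0) >= 2) {
    expect_true("singletons" %in% out$consensus$cluster)
  }
})
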