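# End-to-end orchestration of the network workflow:
# dedupe -> descriptors -> HSP network -> cutoff scan -> communities and
# centralities at the working cutoff -> scaffold extraction (per metric
# and union) -> metadata networks -> community motif discovery.

#' Pipeline configuration
#'
#' Defaults follow the reference workflow: redundancy removal at 0.98
#' identity, similarity cutoff grid 0 then 0.30..0.95, working cutoff
#' 0.65, scaffold extraction by harmonic and hub-bridge centrality over
#' identity cutoffs 0.9..0.3 with the union taken at 0.40.
#'
#' @param fasta,metadata Input paths (FASTA; optional metadata TSV).
#'   Leave NULL to analyse `synthetic` instead.
#' @param synthetic Optional [family_config()] generating the input.
#' @param dedupe_cutoff Redundancy-removal identity cutoff (default 0.98).
#' @param panel Descriptor panel (default full panel).
#' @param cutoff_grid Similarity cutoffs scanned.
#' @param selected_cutoff Working similarity cutoff (default 0.65).
#' @param metrics Centrality metrics used for extraction.
#' @param identity_cutoffs Scaffold-extraction identity grid.
#' @param union_cutoff Identity cutoff at which the metric union is taken
#'   (default 0.40).
#' @param metn_fields Metadata fields for the bipartite network.
#' @param scan A [scan_params()] for motif discovery.
#' @param alignment An [alignment_params()].
#' @param seed Master seed (Louvain + motif controls).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, metadata = NULL, synthetic = NULL,
                            dedupe_cutoff = 0.98,
                            panel = default_descriptor_panel(),
                            cutoff_grid = default_cutoff_grid(),
                            selected_cutoff = 0.65,
                            metrics = c("harmonic", "hub_bridge"),
                            identity_cutoffs = seq(0.9, 0.3, by = -0.1),
                            union_cutoff = 0.40,
                            metn_fields = c("database", "origin"),
                            scan = NULL, alignment = NULL, seed = 1L) {
  if (is.null(fasta) && is.null(synthetic)) {
    stop("provide either 'fasta' or a 'synthetic' family_config",
         call. = FALSE)
  }
  if (!(selected_cutoff >= 0 && selected_cutoff < 1)) {
    stop("selected_cutoff must lie in [0, 1)", call. = FALSE)
  }
  if (!(dedupe_cutoff > 0 && dedupe_cutoff <= 1)) {
    stop("dedupe_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (!union_cutoff %in% identity_cutoffs) {
    identity_cutoffs <- sort(c(identity_cutoffs, union_cutoff),
                             decreasing = TRUE)
  }
  structure(list(fasta = fasta, metadata = metadata, synthetic = synthetic,
                 dedupe_cutoff = dedupe_cutoff, panel = panel,
                 cutoff_grid = cutoff_grid,
                 selected_cutoff = selected_cutoff, metrics = metrics,
                 identity_cutoffs = identity_cutoffs,
                 union_cutoff = union_cutoff, metn_fields = metn_fields,
                 scan = scan %||% scan_params(seed = seed),
                 alignment = alignment %||% alignment_params(),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full network workflow
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, tables (TSV with a
#'   provenance header), networks (GraphML) and subsets (FASTA) are
#'   written there.
#' @return A list of artifacts: `peptides` (after dedupe), `descriptors`,
#'   `similarity`, `hspn` (unfiltered), `scan` (cutoff-scan table),
#'   `model` (filtered network), `partition`, `centralities`, `summary`,
#'   `atypicals`, `scaffold_report`, `subsets` (per metric),
#'   `union_subset`, `metn`, `metn_betweenness`, `motifs`, `consensus`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      gen <- generate_families(cfg$synthetic)
      gen$peptides
    } else {
      s <- load_peptides(cfg$fasta)
      if (!is.null(cfg$metadata)) {
        s <- attach_metadata(s, read_metadata_tsv(cfg$metadata))
      }
      s
    }
  })
  identities <- stage("identity matrix",
                      sw_identity_matrix(set, cfg$alignment))
  set <- stage("dedupe", dedupe(set, cfg$dedupe_cutoff, cfg$alignment,
                                identities = identities))
  identities <- identities[set$ids, set$ids, drop = FALSE]
  desc <- stage("descriptors",
                minmax_normalize(compute_descriptors(set, cfg$panel)))
  dmat <- stage("distances", distance_matrix(desc))
  smat <- to_similarity(dmat)
  hspn <- stage("hsp network", hsp_edges(dmat, smat))
  scan_tab <- stage("cutoff scan",
                    cutoff_scan(dmat, smat, cfg$cutoff_grid,
                                seed = cfg$seed))
  model <- if (cfg$selected_cutoff > 0) {
    apply_cutoff(hspn, cfg$selected_cutoff)
  } else {
    hspn
  }
  partition <- stage("communities",
                     suppressWarnings(louvain_communities(model,
                                                          seed = cfg$seed)))
  cent <- stage("centralities", compute_centralities(model, partition))
  summ <- network_summary(model, partition)
  atyp <- find_atypicals(model)
  rep_tab <- stage("scaffold report",
                   scaffold_report(set, cent, cfg$metrics,
                                   cfg$identity_cutoffs, cfg$alignment,
                                   identities = identities, graph = model))
  subsets <- stage("scaffold extraction", {
    out <- lapply(cfg$metrics, function(m) {
      extract_scaffolds(set, cent, m, cfg$union_cutoff, cfg$alignment,
                        identities = identities, graph = model)
    })
    names(out) <- cfg$metrics
    out
  })
  union_sub <- if (length(subsets) >= 2) {
    union_subsets(subsets[[1]], subsets[[2]], set, graph = model)
  } else {
    subsets[[1]]
  }
  metn <- NULL; metn_btw <- NULL
  if (nrow(set$metadata) > 0) {
    metn <- stage("metadata network", build_metn(set, cfg$metn_fields))
    metn_btw <- metn_betweenness(metn)
  }
  mot <- stage("motif discovery",
               community_motifs(set, model, partition, cfg$scan))
  artifacts <- list(peptides = set, descriptors = desc, similarity = smat,
                    hspn = hspn, scan = scan_tab, model = model,
                    partition = partition, centralities = cent,
                    summary = summ, atypicals = atyp,
                    scaffold_report = rep_tab, subsets = subsets,
                    union_subset = union_sub, metn = metn,
                    metn_betweenness = metn_btw,
                    motifs = mot$motifs, consensus = mot$consensus,
                    config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(artifacts, out_dir)
  artifacts
}

provenance_header <- function(cfg) {
  hash <- sum(utils::head(utf8ToInt(paste(
    deparse(cfg[setdiff(names(cfg), c("fasta", "metadata"))]),
    collapse = "")), 10000))
  sprintf("# hspnet %s | seed %d | selected_cutoff %.2f | config-sum %d",
          as.character(utils::packageVersion("hspnet")), cfg$seed,
          cfg$selected_cutoff, hash)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

write_pipeline_outputs <- function(art, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(art$config)
  coords <- pca_coords(art$descriptors)
  write_tsv_with_header(art$scan, file.path(out_dir, "cutoff_scan.tsv"), hdr)
  write_tsv_with_header(art$centralities,
                        file.path(out_dir, "centralities.tsv"), hdr)
  write_tsv_with_header(art$scaffold_report,
                        file.path(out_dir, "scaffold_report.tsv"), hdr)
  if (!is.null(art$motifs)) {
    write_tsv_with_header(art$motifs, file.path(out_dir, "motifs.tsv"), hdr)
  }
  if (!is.null(art$consensus)) {
    write_tsv_with_header(art$consensus,
                          file.path(out_dir, "consensus.tsv"), hdr)
  }
  write_hspn_graphml(art$model, file.path(out_dir, "hspn_model.graphml"),
                     art$partition, art$centralities, coords)
  if (!is.null(art$metn)) {
    write_metn_graphml(art$metn, file.path(out_dir, "metn.graphml"))
    write_tsv_with_header(art$metn_betweenness,
                          file.path(out_dir, "metn_betweenness.tsv"), hdr)
  }
  write_peptides(subset_peptides(art$peptides, art$union_subset$member_ids),
                 file.path(out_dir, "representative_subset.fasta"))
  invisible(out_dir)
}
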