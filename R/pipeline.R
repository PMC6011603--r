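# End-to-end orchestration: DEG -> DAP -> concordance -> AS -> miRNA ->
# screening -> network, with every threshold surfaced in one place.

#' Default analysis thresholds
#'
#' All cutoffs of the integrated workflow, at their published defaults:
#' DEGs |log2fc| >= 1 at FDR < 0.001; DAPs mean ratio > 1.2 or < 0.833 at
#' p < 0.05; miRNA eligibility RPM >= 10 (either compared sample) and
#' 6-sample RPM sum > 60, DE at p < 0.05 with |log2fc| > 1; target sites
#' at penalty < 3; screening rule-i margin 0.5; PPI combined score > 160.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(deg_log2fc = 1, deg_fdr = 0.001,
       dap_hi = 1.2, dap_lo = 0.833, dap_p = 0.05,
       mirna_rpm_min = 10, mirna_rpm_sum = 60, mirna_p = 0.05,
       mirna_log2fc = 1,
       target_penalty_max = 3, wobble_penalty = 0.5,
       rule_i_margin = 0.5, ppi_score_min = 160,
       rpkm_floor = 0.01, rpm_floor = 0.01)
}

#' Run the full integration pipeline
#'
#' Executes every stage in order on an in-memory data bundle (as
#' produced by [simulate_multiomics()] or assembled from the TSV/FASTA
#' readers) and returns all intermediate tables plus a report of set
#' sizes and subset correlations.
#'
#' @param data list with `expression`, `proteins`, `mirna`,
#'   `mirna_seqs`, `cds_seqs`, `as_events`, `ortholog_map`, `ppi_edges`
#'   (the last two optional).
#' @param thresholds threshold list, see [default_thresholds()].
#' @param osmotic_genes optional osmotic-stress gene list for candidate
#'   annotation.
#' @param scan_targets if FALSE the sequence scan and chain stages are
#'   skipped (they dominate runtime on large libraries).
#' @return list of stage results and `report`.
#' @export
run_pipeline <- function(data, thresholds = default_thresholds(),
                         osmotic_genes = character(),
                         scan_targets = TRUE) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  degs <- stage("deg", call_degs_all(data$expression,
                                     lfc_min = th$deg_log2fc,
                                     fdr_max = th$deg_fdr,
                                     rpkm_floor = th$rpkm_floor))
  tallies <- stage("dap", tally_identification(data$proteins))
  daps <- stage("dap", call_daps_all(data$proteins, ratio_hi = th$dap_hi,
                                     ratio_lo = th$dap_lo, p_max = th$dap_p))
  map <- unique(data$proteins[, c("protein_id", "gene_id")])
  pairs <- stage("concordance", do.call(rbind, lapply(COMPARISONS, function(cmp)
    classify_pairs(degs[degs$comparison == cmp, ],
                   daps[daps$comparison == cmp, ], map))))
  correlations <- stage("concordance", do.call(rbind, lapply(c(4, 24), function(t) {
    cmps <- c(comparison_for("E", t), comparison_for("N", t))
    res <- correlate_subsets(pairs[pairs$comparison %in% cmps, ])
    res$time <- t
    res
  })))

  as_counts <- stage("as", count_events(data$as_events))
  as_degs <- stage("as", select_as_degs(data$as_events, degs))
  as_candidates <- stage("as", rank_as_candidates(as_degs, degs))

  de_mirnas <- stage("mirna", do.call(rbind, lapply(COMPARISONS, function(cmp)
    filter_and_call_de_mirnas(data$mirna, cmp, rpm_min = th$mirna_rpm_min,
                              rpm_sum_min = th$mirna_rpm_sum,
                              p_max = th$mirna_p, lfc_min = th$mirna_log2fc,
                              rpm_floor = th$rpm_floor))))
  target_hits <- NULL
  gene_chains <- protein_chains <- NULL
  if (isTRUE(scan_targets)) {
    de_ids <- unique(de_mirnas$mirna_id[de_mirnas$status != "ns"])
    target_hits <- stage("mirna", scan_targets_all(
      data$mirna_seqs[de_ids], data$cds_seqs,
      penalty_max = th$target_penalty_max,
      wobble_penalty = th$wobble_penalty))
    gene_chains <- stage("mirna",
                         anticorrelated_pairs(de_mirnas, target_hits, degs))
    protein_chains <- stage("mirna",
                            protein_level_chains(de_mirnas, target_hits, pairs))
  }

  candidates <- stage("screening", do.call(rbind, lapply(c(4, 24), function(t)
    rbind(apply_rules(pairs, degs, daps, t, margin = th$rule_i_margin,
                      lfc_min = th$deg_log2fc),
          protein_only_screen(pairs, daps, t)))))
  candidates <- stage("screening", suppressWarnings(
    annotate_candidates(candidates, as_degs, osmotic_genes, map)))

  network <- hubs <- NULL
  if (!is.null(data$ortholog_map) && !is.null(data$ppi_edges)) {
    network <- stage("network", build_network(unique(candidates$id),
                                              data$ortholog_map,
                                              data$ppi_edges,
                                              score_min = th$ppi_score_min))
    hubs <- stage("network", find_hubs(network))
  }

  report <- list(
    n_genes = length(data$expression$gene_id),
    n_proteins = nrow(data$proteins),
    identification_tiers = tallies,
    n_degs = table(degs$comparison[degs$status != "ns"]),
    n_daps = table(daps$comparison[daps$status != "ns"]),
    category_counts = lapply(stats::setNames(COMPARISONS, COMPARISONS),
                             function(cmp)
                               category_counts(pairs[pairs$comparison == cmp, ])),
    correlations = correlations,
    as_event_counts = as_counts$counts,
    n_as_degs = nrow(as_degs),
    n_as_candidates = nrow(as_candidates),
    n_de_mirnas = length(unique(de_mirnas$mirna_id[de_mirnas$status != "ns"])),
    n_gene_chains = if (is.null(gene_chains)) NA_integer_ else nrow(gene_chains),
    n_protein_chains = if (is.null(protein_chains)) NA_integer_ else
      nrow(protein_chains),
    candidate_counts = table(candidates$rule, candidates$time),
    network_size = if (is.null(network)) NULL else
      c(nodes = igraph::vcount(network), edges = igraph::ecount(network)),
    hubs = if (is.null(hubs)) NULL else hubs$hubs$node)

  list(thresholds = th, degs = degs, tallies = tallies, daps = daps,
       pairs = pairs, correlations = correlations, as_counts = as_counts,
       as_degs = as_degs, as_candidates = as_candidates,
       de_mirnas = de_mirnas, target_hits = target_hits,
       gene_chains = gene_chains, protein_chains = protein_chains,
       candidates = candidates, network = network, hubs = hubs,
       report = report)
}

#' Write / read every pipeline output table
#'
#' Writes the stage tables of a [run_pipeline()] result as TSVs (plus the
#' network in SIF format) under a directory; the reader restores the
#' tables for the roundtrip audit.
#'
#' @param results [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_pipeline_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("degs", "daps", "pairs", "correlations", "as_degs",
            "as_candidates", "de_mirnas", "target_hits", "gene_chains",
            "protein_chains", "candidates")
  written <- character()
  for (tb in tabs) {
    if (is.null(results[[tb]])) next
    path <- file.path(dir, paste0(tb, ".tsv"))
    write_omics_tsv(results[[tb]], path)
    written <- c(written, path)
  }
  if (!is.null(results$network)) {
    path <- file.path(dir, "network.sif")
    write_sif(results$network, path)
    written <- c(written, path)
  }
  invisible(written)
}

#' @rdname write_pipeline_tables
#' @export
read_pipeline_tables <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  stats::setNames(lapply(paths, read_omics_tsv),
                  sub("\\.tsv$", "", basename(paths)))
}
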