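# Gene-protein concordance: six-category classification and subset
# Pearson correlations between mRNA and protein fold changes.

#' Classify gene-protein pairs into concordance categories I-VI
#'
#' For one comparison, every gene or protein with a non-ns status or a
#' quantified partner gets exactly one category:
#' \itemize{
#'   \item I — gene DE and protein DAP, same direction;
#'   \item II — gene DE and protein DAP, opposite direction;
#'   \item III — gene DE, protein quantified but ns;
#'   \item IV — protein DAP, gene detected but ns;
#'   \item V — gene DE, no quantified protein (unquantified or unmapped);
#'   \item VI — protein DAP, gene not detected by mRNA-seq.
#' }
#' Pairs with both levels ns are retained with category NA so that the
#' all-pairs correlation can use them.
#'
#' @param deg_results DEG table from [call_degs()] (one comparison).
#' @param dap_results DAP table from [call_daps()] (same comparison);
#'   quantified proteins only.
#' @param map data.frame with columns `protein_id`, `gene_id` giving the
#'   protein-to-gene mapping (defaults to the gene_id column of
#'   `dap_results`).
#' @return data.frame of pairs: gene_id, protein_id, comparison,
#'   gene_log2fc, gene_status, protein_log2ratio, protein_status,
#'   category.
#' @export
classify_pairs <- function(deg_results, dap_results, map = NULL) {
  comparison <- unique(c(deg_results$comparison, dap_results$comparison))
  if (length(comparison) != 1L)
    stop("deg_results and dap_results must cover one common comparison")
  if (is.null(map))
    map <- unique(dap_results[, c("protein_id", "gene_id")])
  gi <- match(map$gene_id, deg_results$gene_id)
  pi <- match(map$protein_id, dap_results$protein_id)
  pairs <- data.frame(
    gene_id = map$gene_id,
    protein_id = map$protein_id,
    comparison = rep(comparison, nrow(map)),
    gene_detected = !is.na(gi),
    gene_log2fc = ifelse(is.na(gi), NA_real_, deg_results$log2fc[gi]),
    gene_status = ifelse(is.na(gi), NA_character_, deg_results$status[gi]),
    protein_quantified = !is.na(pi),
    protein_log2ratio = ifelse(is.na(pi), NA_real_,
                               log2(dap_results$mean_ratio[pi])),
    protein_status = ifelse(is.na(pi), NA_character_, dap_results$status[pi]),
    stringsAsFactors = FALSE)
  # genes never mapped to any protein form protein-less rows (category V
  # when DE)
  unmapped <- !deg_results$gene_id %in% map$gene_id
  if (any(unmapped)) {
    g <- deg_results[unmapped, , drop = FALSE]
    pairs <- rbind(pairs, data.frame(
      gene_id = g$gene_id, protein_id = NA_character_,
      comparison = comparison, gene_detected = TRUE,
      gene_log2fc = g$log2fc, gene_status = g$status,
      protein_quantified = FALSE, protein_log2ratio = NA_real_,
      protein_status = NA_character_, stringsAsFactors = FALSE))
  }
  g_de <- !is.na(pairs$gene_status) & pairs$gene_status != "ns"
  p_de <- !is.na(pairs$protein_status) & pairs$protein_status != "ns"
  same <- g_de & p_de & pairs$gene_status == pairs$protein_status
  category <- rep(NA_character_, nrow(pairs))
  category[g_de & p_de & same] <- "I"
  category[g_de & p_de & !same] <- "II"
  category[g_de & !p_de & pairs$protein_quantified] <- "III"
  category[!g_de & p_de & pairs$gene_detected] <- "IV"
  category[g_de & !pairs$protein_quantified] <- "V"
  category[p_de & !pairs$gene_detected] <- "VI"
  pairs$category <- category
  rownames(pairs) <- NULL
  pairs
}

#' Pearson correlations over concordance-pair subsets
#'
#' Correlates gene log2 fold change against protein log2 mean ratio for
#' three subsets: all pairs with both values, the same-direction pairs
#' (category I) and the opposite-direction pairs (category II). Subsets
#' with fewer than 3 pairs are reported with `r = NA`.
#'
#' @param pairs pair table from [classify_pairs()] (rows from several
#'   comparisons may be stacked, as in the per-time-point scatterplots).
#' @return data.frame with subset, n, r.
#' @export
correlate_subsets <- function(pairs) {
  both <- !is.na(pairs$gene_log2fc) & !is.na(pairs$protein_log2ratio)
  subsets <- list(
    all = both,
    same_direction = both & !is.na(pairs$category) & pairs$category == "I",
    opposite_direction = both & !is.na(pairs$category) & pairs$category == "II")
  do.call(rbind, lapply(names(subsets), function(s) {
    idx <- subsets[[s]]
    n <- sum(idx)
    r <- if (n >= 3)
      stats::cor(pairs$gene_log2fc[idx], pairs$protein_log2ratio[idx],
                 method = "pearson")
    else NA_real_
    data.frame(subset = s, n = n, r = r, stringsAsFactors = FALSE)
  }))
}

#' Category counts for a pair table
#'
#' @param pairs pair table from [classify_pairs()].
#' @return named integer vector over I-VI plus `both_ns`.
#' @export
category_counts <- function(pairs) {
  counts <- table(factor(pairs$category, levels = c("I", "II", "III", "IV", "V", "VI")))
  c(as.integer(counts), both_ns = sum(is.na(pairs$category))) |>
    stats::setNames(c(names(counts), "both_ns"))
}
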