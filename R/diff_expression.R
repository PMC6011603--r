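# Replicate-free differential expression: RPKM normalisation plus a
# conditional exact binomial test between two libraries.

#' RPKM normalisation
#'
#' RPKM = 1e9 * C / (N * L) for a gene with C mapped reads and exon-model
#' length L nt in a library of N mapped reads.
#'
#' @param counts numeric matrix (genes x samples) of non-negative counts.
#' @param lengths numeric vector of gene lengths in nt (> 0), one per row.
#' @param library_totals numeric vector of mapped-read totals (> 0), one
#'   per column; defaults to the column sums of `counts`.
#' @return matrix of RPKM values, same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, lengths,
                         library_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per gene")
  bad <- which(!is.finite(lengths) | lengths <= 0)
  if (length(bad))
    stop("non-positive length for gene ",
         paste(rownames(counts)[bad[1L]], collapse = ""), " (row ", bad[1L], ")")
  bad <- which(!is.finite(library_totals) | library_totals <= 0)
  if (length(bad))
    stop("non-positive library total for sample ",
         paste(colnames(counts)[bad[1L]], collapse = ""), " (column ", bad[1L], ")")
  1e9 * sweep(counts, 2L, library_totals, "/") / lengths
}

#' Exact two-library test for equal relative abundance
#'
#' Conditional on the total n = x + y, x is binomial with success
#' probability N1 / (N1 + N2) under the null of equal relative abundance
#' (the Audic-Claverie conditional test). The two-sided p-value doubles
#' the smaller tail and is capped at 1. Vectorised over genes.
#'
#' @param x,y counts in library 1 and 2 (non-negative).
#' @param N1,N2 library totals (> 0).
#' @return two-sided p-values in (0, 1].
#' @export
two_library_test <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("negative counts rejected")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  n <- x + y
  p0 <- N1 / (N1 + N2)
  lower <- stats::pbinom(x, n, p0)
  upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Call differentially expressed genes for one comparison
#'
#' log2 fold change is computed on RPKM with a floor (so genes absent in
#' one library stay finite); the p-value comes from [two_library_test()]
#' on raw counts; FDR is Benjamini-Hochberg across all genes of the
#' comparison. A gene is `up` when log2fc >= lfc_min and fdr < fdr_max,
#' `down` when log2fc <= -lfc_min and fdr < fdr_max, else `ns`.
#'
#' @param expr expression object from [simulate_counts()] or
#'   [read_expression_tsv()]: list with `counts`, `lengths`, `gene_id`.
#' @param comparison comparison label, see [parse_comparison()].
#' @param lfc_min,fdr_max DEG thresholds (defaults |log2| >= 1,
#'   FDR < 0.001).
#' @param rpkm_floor floor applied to RPKM before forming the ratio.
#' @return data.frame with gene_id, comparison, log2fc, p, fdr, status.
#' @export
call_degs <- function(expr, comparison, lfc_min = 1, fdr_max = 0.001,
                      rpkm_floor = 0.01) {
  cmp <- parse_comparison(comparison)
  counts <- expr$counts
  for (s in c(cmp$treated, cmp$control)) {
    if (!s %in% colnames(counts)) stop("missing sample: ", s)
  }
  totals <- colSums(counts)
  rpkm <- compute_rpkm(counts[, c(cmp$treated, cmp$control), drop = FALSE],
                       expr$lengths,
                       totals[c(cmp$treated, cmp$control)])
  log2fc <- log2(pmax(rpkm[, 1L], rpkm_floor) / pmax(rpkm[, 2L], rpkm_floor))
  p <- two_library_test(counts[, cmp$treated], counts[, cmp$control],
                        totals[cmp$treated], totals[cmp$control])
  ord <- order(expr$gene_id)  # tie-stable, reproducible BH input order
  fdr <- numeric(length(p))
  fdr[ord] <- stats::p.adjust(p[ord], method = "BH")
  status <- rep("ns", length(p))
  status[log2fc >= lfc_min & fdr < fdr_max] <- "up"
  status[log2fc <= -lfc_min & fdr < fdr_max] <- "down"
  data.frame(gene_id = expr$gene_id, comparison = comparison,
             log2fc = unname(log2fc), p = unname(p), fdr = unname(fdr),
             status = status, stringsAsFactors = FALSE)
}

#' Call DEGs for every comparison
#'
#' @inheritParams call_degs
#' @param comparisons comparison labels (default all four).
#' @return single stacked data.frame.
#' @export
call_degs_all <- function(expr, comparisons = COMPARISONS, lfc_min = 1,
                          fdr_max = 0.001, rpkm_floor = 0.01) {
  do.call(rbind, lapply(comparisons, call_degs, expr = expr,
                        lfc_min = lfc_min, fdr_max = fdr_max,
                        rpkm_floor = rpkm_floor))
}
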