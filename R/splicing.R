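# Alternative-splicing event accounting: per-sample event/type counts,
# salt-induced AS gene sets, AS-DEGs and tolerance candidates.

AS_TYPES <- c("IR", "ES", "A5SS", "A3SS")

#' Count AS events per sample and type
#'
#' @param events AS event table: data.frame with columns gene_id, sample,
#'   type (IR/ES/A5SS/A3SS), start, end.
#' @return list with `counts` (sample x type matrix), `fractions`
#'   (per-type fraction within each sample) and `as_genes` (named list of
#'   per-sample gene sets with >= 1 event).
#' @export
count_events <- function(events) {
  bad <- which(!events$type %in% AS_TYPES)
  if (length(bad))
    stop("unknown AS event type '", events$type[bad[1L]], "' at row ", bad[1L])
  samples <- SAMPLES[SAMPLES %in% unique(events$sample)]
  if (nrow(events) == 0L) samples <- SAMPLES
  counts <- table(factor(events$sample, levels = samples),
                  factor(events$type, levels = AS_TYPES))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(samples, AS_TYPES))
  totals <- rowSums(counts)
  fractions <- counts / ifelse(totals == 0, NA_real_, totals)
  as_genes <- lapply(stats::setNames(samples, samples), function(s)
    sort(unique(events$gene_id[events$sample == s])))
  list(counts = counts, fractions = fractions, as_genes = as_genes)
}

#' Salt-specific AS gene sets for a genotype/time
#'
#' A gene is "induced" when it has >= 1 AS event in the treated sample
#' but none in the genotype's 0 h control; "lost" is the reverse.
#'
#' @param events AS event table.
#' @param genotype "E" (tolerant) or "N" (sensitive).
#' @param time 4 or 24 (hours).
#' @return list with `induced` and `lost` gene-id vectors.
#' @export
salt_specific_as_genes <- function(events, genotype, time) {
  stopifnot(genotype %in% c("E", "N"), time %in% c(4, 24))
  control <- paste0(genotype, "0")
  treated <- paste0(genotype, time)
  # a treated sample without any control rows means the 0 h library is
  # absent (an event-free control would still be representable upstream)
  if (treated %in% events$sample && !control %in% events$sample)
    stop("missing control sample ", control, " for genotype ", genotype)
  g_ctrl <- unique(events$gene_id[events$sample == control])
  g_trt <- unique(events$gene_id[events$sample == treated])
  list(induced = sort(setdiff(g_trt, g_ctrl)),
       lost = sort(setdiff(g_ctrl, g_trt)))
}

#' AS-DEGs: DEGs that undergo salt-induced AS
#'
#' Intersects the salt-specifically induced AS gene set of a genotype and
#' time with the DEGs of the matching comparison.
#'
#' @param events AS event table.
#' @param deg_results stacked DEG table from [call_degs_all()].
#' @return data.frame with gene_id, genotype, time, comparison, log2fc,
#'   status.
#' @export
select_as_degs <- function(events, deg_results) {
  out <- list()
  for (genotype in c("E", "N")) for (time in c(4, 24)) {
    cmp <- comparison_for(genotype, time)
    deg <- deg_results[deg_results$comparison == cmp &
                         deg_results$status != "ns", , drop = FALSE]
    induced <- salt_specific_as_genes(events, genotype, time)$induced
    hit <- deg[deg$gene_id %in% induced, , drop = FALSE]
    if (nrow(hit))
      out[[cmp]] <- data.frame(gene_id = hit$gene_id, genotype = genotype,
                               time = time, comparison = cmp,
                               log2fc = hit$log2fc, status = hit$status,
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), genotype = character(),
                      time = integer(), comparison = character(),
                      log2fc = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank AS tolerance candidates
#'
#' Among the tolerant genotype's AS-DEGs, a gene is a candidate when the
#' magnitude of its response in the tolerant comparison exceeds that in
#' the sensitive comparison at the same time point
#' (|log2 E/E0| > |log2 N/N0|).
#'
#' @param as_degs AS-DEG table from [select_as_degs()].
#' @param deg_results stacked DEG table from [call_degs_all()].
#' @param require_tolerant_as if TRUE (default) only AS-DEGs of the
#'   tolerant genotype are considered.
#' @return candidate data.frame sorted by decreasing margin, with columns
#'   gene_id, time, log2fc_E, log2fc_N, margin.
#' @export
rank_as_candidates <- function(as_degs, deg_results,
                               require_tolerant_as = TRUE) {
  pool <- if (require_tolerant_as)
    as_degs[as_degs$genotype == "E", , drop = FALSE] else as_degs
  out <- list()
  for (time in c(4, 24)) {
    genes <- unique(pool$gene_id[pool$time == time])
    if (!length(genes)) next
    e <- deg_results[deg_results$comparison == comparison_for("E", time), ]
    n <- deg_results[deg_results$comparison == comparison_for("N", time), ]
    lfc_e <- e$log2fc[match(genes, e$gene_id)]
    lfc_n <- n$log2fc[match(genes, n$gene_id)]
    keep <- !is.na(lfc_e) & (is.na(lfc_n) | abs(lfc_e) > abs(lfc_n))
    lfc_n[is.na(lfc_n)] <- 0
    if (any(keep))
      out[[as.character(time)]] <- data.frame(
        gene_id = genes[keep], time = time, log2fc_E = lfc_e[keep],
        log2fc_N = lfc_n[keep], margin = abs(lfc_e[keep]) - abs(lfc_n[keep]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), time = integer(),
                      log2fc_E = numeric(), log2fc_N = numeric(),
                      margin = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$time, -res$margin, res$gene_id), ]
  rownames(res) <- NULL
  res
}
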