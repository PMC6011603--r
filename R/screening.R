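# Stringent screening of salt-tolerance candidates: five rules over the
# genotype contrast, plus a proteome-only screen, plus AS/osmotic
# annotation flags.

RULES <- c("i", "ii", "iii", "iv", "v")

#' Apply the five stringent screening rules at one time point
#'
#' Candidates contrast the tolerant (E) and sensitive (N) genotype
#' responses at the same time point:
#' \itemize{
#'   \item i — gene-level pairs of category I or III ("diff.same" /
#'     "DEGs & protein ns"), DE in the same direction in both genotypes,
#'     with |log2 E/E0| - |log2 N/N0| >= margin (default 0.5);
#'   \item ii — category III with opposite responses:
#'     log2 E/E0 >= 1 and log2 N/N0 <= -1, or vice versa;
#'   \item iii — category I or III, DE only in the tolerant genotype;
#'   \item iv — category IV ("DAP & gene ns"), DAP in the same direction
#'     in both genotypes with |log2 Q(E)| > |log2 Q(N)|;
#'   \item v — category IV, DAP only in the tolerant genotype.
#' }
#' A record keeps the first rule (order i to v) it satisfies.
#'
#' @param pairs stacked concordance pair table over all comparisons.
#' @param deg_results stacked DEG table.
#' @param dap_results stacked DAP table.
#' @param time 4 or 24 (hours).
#' @param margin rule-i margin on |log2fc| differences (default 0.5).
#' @param lfc_min rule-ii per-genotype log2fc bound (default 1).
#' @return data.frame of candidate records: id, level, time, rule,
#'   effect_E, effect_N (log2 scale).
#' @export
apply_rules <- function(pairs, deg_results, dap_results, time,
                        margin = 0.5, lfc_min = 1) {
  stopifnot(time %in% c(4, 24))
  cmp_e <- comparison_for("E", time)
  cmp_n <- comparison_for("N", time)
  pe <- pairs[pairs$comparison == cmp_e, , drop = FALSE]
  deg_e <- deg_results[deg_results$comparison == cmp_e, ]
  deg_n <- deg_results[deg_results$comparison == cmp_n, ]
  dap_e <- dap_results[dap_results$comparison == cmp_e, ]
  dap_n <- dap_results[dap_results$comparison == cmp_n, ]
  recs <- list()
  add <- function(id, level, rule, eff_e, eff_n) {
    recs[[length(recs) + 1L]] <<- data.frame(
      id = id, level = level, time = time, rule = rule,
      effect_E = eff_e, effect_N = eff_n, stringsAsFactors = FALSE)
  }

  # gene-level rules (i-iii) over category I / III pairs of the E comparison
  gp <- pe[!is.na(pe$category) & pe$category %in% c("I", "III"), , drop = FALSE]
  gp <- gp[!duplicated(gp$gene_id), , drop = FALSE]
  for (k in seq_len(nrow(gp))) {
    g <- gp$gene_id[k]
    e <- deg_e[match(g, deg_e$gene_id), ]
    n <- deg_n[match(g, deg_n$gene_id), ]
    if (is.na(e$gene_id[1L])) next
    n_de <- !is.na(n$gene_id[1L]) && n$status != "ns"
    lfc_n <- if (is.na(n$gene_id[1L])) 0 else n$log2fc
    if (n_de && e$status == n$status &&
        abs(e$log2fc) - abs(n$log2fc) >= margin) {
      add(g, "gene", "i", e$log2fc, lfc_n)
    } else if (gp$category[k] == "III" && n_de &&
               ((e$log2fc >= lfc_min && n$log2fc <= -lfc_min) ||
                (e$log2fc <= -lfc_min && n$log2fc >= lfc_min))) {
      add(g, "gene", "ii", e$log2fc, lfc_n)
    } else if (!n_de) {
      add(g, "gene", "iii", e$log2fc, lfc_n)
    }
  }

  # protein-level rules (iv, v) over category IV pairs of the E comparison
  pp <- pe[!is.na(pe$category) & pe$category == "IV", , drop = FALSE]
  pp <- pp[!duplicated(pp$protein_id), , drop = FALSE]
  for (k in seq_len(nrow(pp))) {
    pr <- pp$protein_id[k]
    e <- dap_e[match(pr, dap_e$protein_id), ]
    n <- dap_n[match(pr, dap_n$protein_id), ]
    n_dap <- !is.na(n$protein_id[1L]) && n$status != "ns"
    l2r_n <- if (is.na(n$protein_id[1L])) 0 else log2(n$mean_ratio)
    if (n_dap && e$status == n$status &&
        abs(log2(e$mean_ratio)) > abs(log2(n$mean_ratio))) {
      add(pr, "protein", "iv", log2(e$mean_ratio), l2r_n)
    } else if (!n_dap) {
      add(pr, "protein", "v", log2(e$mean_ratio), l2r_n)
    }
  }

  if (!length(recs))
    return(data.frame(id = character(), level = character(), time = integer(),
                      rule = character(), effect_E = numeric(),
                      effect_N = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, recs)
  res <- res[order(match(res$rule, RULES), res$id), ]
  res <- res[!duplicated(paste(res$id, res$level)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Proteome-only candidate screen (category VI)
#'
#' Without using the mRNA-seq data: category VI proteins (DAP with no
#' detected transcript) that are DAP only in the tolerant genotype at the
#' given time point.
#'
#' @param pairs stacked concordance pair table.
#' @param dap_results stacked DAP table.
#' @param time 4 or 24 (hours).
#' @return candidate data.frame: id, level = "protein", time,
#'   rule = "protein_only", effect_E, effect_N.
#' @export
protein_only_screen <- function(pairs, dap_results, time) {
  stopifnot(time %in% c(4, 24))
  cmp_e <- comparison_for("E", time)
  cmp_n <- comparison_for("N", time)
  pe <- pairs[pairs$comparison == cmp_e & !is.na(pairs$category) &
                pairs$category == "VI", , drop = FALSE]
  dap_e <- dap_results[dap_results$comparison == cmp_e, ]
  dap_n <- dap_results[dap_results$comparison == cmp_n, ]
  out <- list()
  for (pr in unique(pe$protein_id)) {
    e <- dap_e[match(pr, dap_e$protein_id), ]
    n <- dap_n[match(pr, dap_n$protein_id), ]
    n_dap <- !is.na(n$protein_id[1L]) && n$status != "ns"
    if (!n_dap)
      out[[length(out) + 1L]] <- data.frame(
        id = pr, level = "protein", time = time, rule = "protein_only",
        effect_E = log2(e$mean_ratio),
        effect_N = if (is.na(n$protein_id[1L])) 0 else log2(n$mean_ratio),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(), level = character(), time = integer(),
                      rule = character(), effect_E = numeric(),
                      effect_N = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$id), ]
  rownames(res) <- NULL
  res
}

#' Annotate candidates with AS and osmotic-stress flags
#'
#' @param candidates candidate table from [apply_rules()] /
#'   [protein_only_screen()] (stacked).
#' @param as_degs AS-DEG table from [select_as_degs()]; `as_flag` is set
#'   when the candidate's gene is an AS-DEG of the tolerant genotype at
#'   the matching time.
#' @param osmotic_genes character vector of osmotic-stress-annotated gene
#'   ids (user-supplied homology list); missing/empty leaves the flag
#'   FALSE with a warning.
#' @param map optional protein-to-gene map (protein_id, gene_id) used to
#'   resolve protein-level candidate ids to genes.
#' @return `candidates` with gene_id, as_flag and osmotic_flag columns.
#' @export
annotate_candidates <- function(candidates, as_degs,
                                osmotic_genes = NULL, map = NULL) {
  gene_of <- candidates$id
  if (!is.null(map)) {
    is_prot <- candidates$level == "protein"
    m <- match(candidates$id[is_prot], map$protein_id)
    gene_of[is_prot] <- ifelse(is.na(m), NA_character_, map$gene_id[m])
  }
  candidates$gene_id <- gene_of
  as_flag <- rep(FALSE, nrow(candidates))
  for (t in unique(candidates$time)) {
    set <- unique(as_degs$gene_id[as_degs$genotype == "E" & as_degs$time == t])
    idx <- candidates$time == t
    as_flag[idx] <- !is.na(gene_of[idx]) & gene_of[idx] %in% set
  }
  candidates$as_flag <- as_flag
  if (is.null(osmotic_genes)) {
    warning("no osmotic-stress gene list supplied; osmotic_flag left FALSE")
    osmotic_genes <- character()
  }
  candidates$osmotic_flag <- !is.na(gene_of) & gene_of %in% osmotic_genes
  candidates
}
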