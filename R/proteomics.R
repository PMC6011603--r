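# iTRAQ proteomics: identification tiers and differential abundance from
# replicate treated/control ratios.

ratio_cols <- function(comparison) {
  cmp <- parse_comparison(comparison)
  paste0("ratio_", cmp$genotype, cmp$time, "_r", 1:3)
}

#' Identification-filter tier tallies
#'
#' Four nested-ish tiers used to describe an iTRAQ run:
#' `identified` (>= 1 peptide in >= 1 replicate), `robust` (>= 2 peptides
#' in total and present in >= 2 replicates), `quantified` (>= 1 reporter
#' ratio present) and `quantified_all3` (a ratio in all three replicates).
#'
#' @param quants protein quantification data.frame with columns
#'   `pep_r1..pep_r3` and ratio columns `ratio_<cmp>_r1..r3` (NA =
#'   missing), as produced by [simulate_proteome()].
#' @return named integer vector of the four tallies.
#' @export
tally_identification <- function(quants) {
  pep <- as.matrix(quants[, paste0("pep_r", 1:3)])
  rc <- grep("^ratio_", names(quants), value = TRUE)
  ratio_present <- rowSums(!is.na(as.matrix(quants[, rc, drop = FALSE]))) > 0
  # replicate-level quantification: any comparison's ratio in replicate r
  rep_has_ratio <- sapply(1:3, function(r) {
    cols <- grep(sprintf("_r%d$", r), rc, value = TRUE)
    rowSums(!is.na(as.matrix(quants[, cols, drop = FALSE]))) > 0
  })
  c(identified = sum(rowSums(pep >= 1) >= 1),
    robust = sum(rowSums(pep) >= 2 & rowSums(pep >= 1) >= 2),
    quantified = sum(ratio_present),
    quantified_all3 = sum(rowSums(rep_has_ratio) == 3))
}

#' Differential-abundance statistic for one protein
#'
#' Geometric mean of the replicate ratios ("average ratio" on the
#' multiplicative scale) and a two-sided one-sample t-test of the log2
#' ratios against 0. With fewer than two ratios, or a zero-variance
#' replicate vector, the p-value is missing (such proteins can never be
#' called differentially abundant).
#'
#' @param ratios numeric vector of replicate treated/control ratios; NA =
#'   missing replicate.
#' @return list with `mean_ratio` and `p`.
#' @export
dap_test <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0L) stop("all replicate ratios missing")
  if (any(r <= 0)) stop("ratios must be positive")
  lr <- log2(r)
  mean_ratio <- 2^mean(lr)
  p <- NA_real_
  if (length(lr) >= 2L && stats::sd(lr) > 0)
    p <- stats::t.test(lr, mu = 0)$p.value
  list(mean_ratio = mean_ratio, p = p)
}

#' Call differentially abundant proteins for one comparison
#'
#' Eligibility follows the identification rule: at least one peptide
#' among the three biological replicates, and at least one ratio for the
#' comparison. A protein is `up` when mean_ratio > ratio_hi and
#' p < p_max, `down` when mean_ratio < ratio_lo and p < p_max
#' (both ratio bounds exclusive), else `ns`.
#'
#' @inheritParams tally_identification
#' @param comparison comparison label.
#' @param ratio_hi,ratio_lo,p_max DAP thresholds (defaults 1.2, 0.833,
#'   0.05).
#' @return data.frame with protein_id, gene_id, comparison, n_ratios,
#'   mean_ratio, p, status — quantified proteins only.
#' @export
call_daps <- function(quants, comparison, ratio_hi = 1.2,
                      ratio_lo = 0.833, p_max = 0.05) {
  cols <- ratio_cols(comparison)
  pep <- as.matrix(quants[, paste0("pep_r", 1:3)])
  ratios <- as.matrix(quants[, cols])
  keep <- rowSums(pep) >= 1 & rowSums(!is.na(ratios)) >= 1
  q <- quants[keep, , drop = FALSE]
  ratios <- ratios[keep, , drop = FALSE]
  if (nrow(q) == 0L)
    return(data.frame(protein_id = character(), gene_id = character(),
                      comparison = character(), n_ratios = integer(),
                      mean_ratio = numeric(), p = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(ratios)), function(i) dap_test(ratios[i, ]))
  mean_ratio <- vapply(res, `[[`, numeric(1), "mean_ratio")
  p <- vapply(res, `[[`, numeric(1), "p")
  status <- rep("ns", length(p))
  ok <- !is.na(p) & p < p_max
  status[ok & mean_ratio > ratio_hi] <- "up"
  status[ok & mean_ratio < ratio_lo] <- "down"
  data.frame(protein_id = q$protein_id, gene_id = q$gene_id,
             comparison = comparison,
             n_ratios = rowSums(!is.na(ratios)),
             mean_ratio = mean_ratio, p = p, status = status,
             stringsAsFactors = FALSE)
}

#' Call DAPs for every comparison
#'
#' @inheritParams call_daps
#' @param comparisons comparison labels (default all four).
#' @export
call_daps_all <- function(quants, comparisons = COMPARISONS,
                          ratio_hi = 1.2, ratio_lo = 0.833, p_max = 0.05) {
  do.call(rbind, lapply(comparisons, call_daps, quants = quants,
                        ratio_hi = ratio_hi, ratio_lo = ratio_lo,
                        p_max = p_max))
}
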