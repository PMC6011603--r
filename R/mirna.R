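# Small-RNA side: RPM filtering + DE calling, plant-style miRNA-target
# complementarity scanning, and anticorrelated miRNA->mRNA(->protein)
# chains.

#' Reads-per-million normalisation
#'
#' RPM = count / library_total * 1e6.
#'
#' @param counts matrix (miRNA x sample) of non-negative counts.
#' @param library_totals per-sample totals (> 0); default column sums.
#' @return RPM matrix.
#' @export
compute_rpm <- function(counts, library_totals = colSums(counts)) {
  if (any(counts < 0)) stop("negative counts")
  if (any(library_totals <= 0)) stop("library totals must be positive")
  sweep(counts, 2L, library_totals, "/") * 1e6
}

#' Filter and call differentially expressed miRNAs
#'
#' Eligibility requires an RPM >= rpm_min in at least one of the two
#' compared samples and an RPM sum over all 6 samples strictly greater
#' than rpm_sum_min. The p-value is the exact two-library test on raw
#' counts; a miRNA is DE when p < p_max and |log2 RPM ratio| > lfc_min
#' (strict, per the stated criteria).
#'
#' @param profiles list with `mirna_id`, `class` and a 6-column `counts`
#'   matrix, as from [simulate_mirnas_and_targets()].
#' @param comparison comparison label.
#' @param rpm_min,rpm_sum_min,p_max,lfc_min thresholds (defaults 10, 60,
#'   0.05, 1).
#' @param rpm_floor floor applied to RPM before forming the ratio.
#' @param rpm_min_rule `"either"` (default) requires rpm_min in at least
#'   one compared sample; `"both"` requires it in both.
#' @return data.frame with mirna_id, class, comparison, eligible, rpm sums,
#'   log2fc, p, status.
#' @export
filter_and_call_de_mirnas <- function(profiles, comparison, rpm_min = 10,
                                      rpm_sum_min = 60, p_max = 0.05,
                                      lfc_min = 1, rpm_floor = 0.01,
                                      rpm_min_rule = c("either", "both")) {
  rpm_min_rule <- match.arg(rpm_min_rule)
  cmp <- parse_comparison(comparison)
  counts <- profiles$counts
  totals <- colSums(counts)
  rpm <- compute_rpm(counts, totals)
  pairmax <- if (rpm_min_rule == "either")
    pmax(rpm[, cmp$treated], rpm[, cmp$control])
  else pmin(rpm[, cmp$treated], rpm[, cmp$control])
  rpm_sum <- rowSums(rpm)
  eligible <- pairmax >= rpm_min & rpm_sum > rpm_sum_min
  log2fc <- log2(pmax(rpm[, cmp$treated], rpm_floor) /
                   pmax(rpm[, cmp$control], rpm_floor))
  p <- two_library_test(counts[, cmp$treated], counts[, cmp$control],
                        totals[cmp$treated], totals[cmp$control])
  status <- rep("ns", length(p))
  de <- eligible & p < p_max & abs(log2fc) > lfc_min
  status[de & log2fc > 0] <- "up"
  status[de & log2fc < 0] <- "down"
  data.frame(mirna_id = profiles$mirna_id, class = profiles$class,
             comparison = comparison, eligible = eligible,
             rpm_sum = unname(rpm_sum), log2fc = unname(log2fc),
             p = unname(p), status = status, stringsAsFactors = FALSE)
}

# nucleotide coding: A=1 C=2 G=3 T/U=4; anything else errors
.nt_code <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("U")] <- 4L
  tab[utf8ToInt("a")] <- 1L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("g")] <- 3L; tab[utf8ToInt("t")] <- 4L
  tab[utf8ToInt("u")] <- 4L
  tab
})

encode_nt <- function(x, label = "sequence") {
  ints <- utf8ToInt(x)
  code <- ifelse(ints <= 127L, .nt_code[ints], NA_integer_)
  if (anyNA(code)) {
    pos <- which(is.na(code))[1L]
    stop("non-nucleotide character '", substr(x, pos, pos), "' at position ",
         pos, " of ", label)
  }
  code
}

# pairing penalty between a miRNA base (row) and the target base (col) it
# faces in the antiparallel duplex: Watson-Crick 0, G:U wobble wobble_pen,
# anything else 1. Fifth column is a sentinel for record separators.
pair_penalty_matrix <- function(wobble_pen = 0.5) {
  w <- matrix(1, 5, 5)
  w[1, 4] <- 0  # A:U
  w[4, 1] <- 0  # U:A
  w[3, 2] <- 0  # G:C
  w[2, 3] <- 0  # C:G
  w[3, 4] <- wobble_pen  # G:U wobble
  w[4, 3] <- wobble_pen  # U:G wobble
  w[5, ] <- 1e9
  w[, 5] <- 1e9
  w
}

#' Scan a miRNA against a CDS library for complementary target sites
#'
#' Slides the miRNA along every transcript (no gaps) in antiparallel
#' orientation and scores each offset as
#' penalty = #non-complementary positions + wobble_penalty * #G:U pairs.
#' Offsets with penalty < penalty_max are reported, implementing the
#' "< 3-nt mismatches" target-selection rule with the psRNATarget-style
#' half-weight wobble.
#'
#' @param mirna_seq miRNA sequence (19-24 nt, A/C/G/U or T).
#' @param cds_set named character vector, `DNAStringSet` or
#'   `RNAStringSet` of coding sequences.
#' @param penalty_max report offsets with penalty strictly below this
#'   value (default 3).
#' @param wobble_penalty weight of a G:U pair (default 0.5; set 1 to
#'   count wobbles as plain mismatches).
#' @param mirna_id id recorded in the result (default "mirna").
#' @return data.frame with mirna_id, transcript_id, offset (1-based start
#'   of the site on the transcript), penalty.
#' @export
scan_targets <- function(mirna_seq, cds_set, penalty_max = 3,
                         wobble_penalty = 0.5, mirna_id = "mirna") {
  if (inherits(cds_set, "XStringSet"))
    cds_set <- stats::setNames(as.character(cds_set), names(cds_set))
  if (is.null(names(cds_set)))
    names(cds_set) <- paste0("cds_", seq_along(cds_set))
  L <- nchar(as.character(mirna_seq))
  if (L < 19L || L > 24L) stop("miRNA length must be 19-24 nt, got ", L)
  m <- encode_nt(as.character(mirna_seq), "miRNA")
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      offset = integer(), penalty = numeric(),
                      stringsAsFactors = FALSE)
  if (length(cds_set) == 0L) return(empty)
  codes <- lapply(seq_along(cds_set), function(i)
    encode_nt(cds_set[[i]], paste0("transcript ", names(cds_set)[i])))
  lens <- lengths(codes)
  # concatenate with sentinel separators so one vectorised pass covers
  # the whole library
  s <- unlist(lapply(codes, function(v) c(v, 5L)), use.names = FALSE)
  n_off <- length(s) - L + 1L
  if (n_off < 1L) return(empty)
  w <- pair_penalty_matrix(wobble_penalty)
  mrev <- rev(m)  # position j of the site faces miRNA base L + 1 - j
  pen <- numeric(n_off)
  for (j in seq_len(L)) pen <- pen + w[mrev[j], s[j:(j + n_off - 1L)]]
  hit <- which(pen < penalty_max)
  if (!length(hit)) return(empty)
  starts <- cumsum(c(0L, lens[-length(lens)] + 1L))  # global offset of base 1
  idx <- findInterval(hit, starts + 1L)
  local <- hit - starts[idx]
  keep <- local + L - 1L <= lens[idx]  # cannot cross a separator anyway
  data.frame(mirna_id = mirna_id, transcript_id = names(cds_set)[idx[keep]],
             offset = as.integer(local[keep]), penalty = pen[hit][keep],
             stringsAsFactors = FALSE)
}

#' Scan several miRNAs against a CDS library
#'
#' @param mirna_seqs named character vector or `RNAStringSet` of miRNA
#'   sequences.
#' @inheritParams scan_targets
#' @return stacked [scan_targets()] result.
#' @export
scan_targets_all <- function(mirna_seqs, cds_set, penalty_max = 3,
                             wobble_penalty = 0.5) {
  if (inherits(mirna_seqs, "XStringSet"))
    mirna_seqs <- stats::setNames(as.character(mirna_seqs), names(mirna_seqs))
  do.call(rbind, lapply(names(mirna_seqs), function(id)
    scan_targets(mirna_seqs[[id]], cds_set, penalty_max = penalty_max,
                 wobble_penalty = wobble_penalty, mirna_id = id)))
}

tolerant_de_mirnas <- function(de_mirnas) {
  de <- de_mirnas[de_mirnas$status != "ns", , drop = FALSE]
  in_e <- unique(de$mirna_id[grepl("^E", de$comparison)])
  de[de$mirna_id %in% in_e, , drop = FALSE]
}

#' Gene-level anticorrelated miRNA-target chains
#'
#' Keeps miRNAs that are DE in the tolerant genotype (miRNAs DE only in
#' the sensitive genotype are removed) and emits a chain for every
#' sequence-level target whose gene is DE in the opposite direction in
#' the same comparison.
#'
#' @param de_mirnas stacked [filter_and_call_de_mirnas()] results.
#' @param target_hits [scan_targets_all()] result; transcript ids are
#'   gene ids.
#' @param deg_results stacked DEG table.
#' @return data.frame with mirna_id, gene_id, comparison,
#'   mirna_direction, gene_direction, level = "gene".
#' @export
anticorrelated_pairs <- function(de_mirnas, target_hits, deg_results) {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      comparison = character(), mirna_direction = character(),
                      gene_direction = character(), level = character(),
                      stringsAsFactors = FALSE)
  de <- tolerant_de_mirnas(de_mirnas)
  de <- de[de$status != "ns", , drop = FALSE]
  if (nrow(de) == 0L || is.null(target_hits) || nrow(target_hits) == 0L)
    return(empty)
  out <- list()
  for (i in seq_len(nrow(de))) {
    targets <- unique(target_hits$transcript_id[
      target_hits$mirna_id == de$mirna_id[i]])
    if (!length(targets)) next
    deg <- deg_results[deg_results$comparison == de$comparison[i] &
                         deg_results$gene_id %in% targets &
                         deg_results$status != "ns", , drop = FALSE]
    opp <- deg[deg$status != de$status[i], , drop = FALSE]
    if (nrow(opp))
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = de$mirna_id[i], gene_id = opp$gene_id,
        comparison = de$comparison[i], mirna_direction = de$status[i],
        gene_direction = opp$status, level = "gene",
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Protein-level anticorrelated chains (candidate translational repression)
#'
#' Chains where a tolerant-genotype DE miRNA targets a gene whose protein
#' moved in the opposite direction while the transcript itself did not
#' (concordance categories IV or VI). Triples that already form a
#' gene-level chain cannot appear here because categories IV/VI require a
#' non-DE (or undetected) transcript.
#'
#' @param de_mirnas stacked [filter_and_call_de_mirnas()] results.
#' @param target_hits [scan_targets_all()] result.
#' @param pairs stacked concordance pair table (with `comparison`).
#' @return data.frame with mirna_id, gene_id, protein_id, comparison,
#'   mirna_direction, protein_direction, category, level = "protein".
#' @export
protein_level_chains <- function(de_mirnas, target_hits, pairs) {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      protein_id = character(), comparison = character(),
                      mirna_direction = character(),
                      protein_direction = character(), category = character(),
                      level = character(), stringsAsFactors = FALSE)
  de <- tolerant_de_mirnas(de_mirnas)
  de <- de[de$status != "ns", , drop = FALSE]
  if (nrow(de) == 0L || is.null(target_hits) || nrow(target_hits) == 0L)
    return(empty)
  cand <- pairs[!is.na(pairs$category) & pairs$category %in% c("IV", "VI") &
                  !is.na(pairs$protein_status), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(de))) {
    targets <- unique(target_hits$transcript_id[
      target_hits$mirna_id == de$mirna_id[i]])
    if (!length(targets)) next
    hit <- cand[cand$comparison == de$comparison[i] &
                  cand$gene_id %in% targets &
                  cand$protein_status != "ns" &
                  cand$protein_status != de$status[i], , drop = FALSE]
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = de$mirna_id[i], gene_id = hit$gene_id,
        protein_id = hit$protein_id, comparison = de$comparison[i],
        mirna_direction = de$status[i],
        protein_direction = hit$protein_status,
        category = hit$category, level = "protein",
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
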