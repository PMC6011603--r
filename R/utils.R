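#' @keywords internal
"_PACKAGE"

SAMPLES <- c("E0", "E4", "E24", "N0", "N4", "N24")
COMPARISONS <- c("E4/E0", "E24/E0", "N4/N0", "N24/N0")

#' Parse a comparison label
#'
#' Comparisons are written `treated/control`, e.g. `"E4/E0"`: genotype E
#' (salt tolerant) at 4 h versus its 0 h control.
#'
#' @param comparison one of `"E4/E0"`, `"E24/E0"`, `"N4/N0"`, `"N24/N0"`.
#' @return list with `treated`, `control`, `genotype` ("E" or "N") and
#'   `time` (4 or 24, hours).
#' @export
parse_comparison <- function(comparison) {
  if (!is.character(comparison) || length(comparison) != 1L ||
      !comparison %in% COMPARISONS) {
    stop("unknown comparison: ", paste(comparison, collapse = ", "),
         " (expected one of ", paste(COMPARISONS, collapse = ", "), ")")
  }
  parts <- strsplit(comparison, "/", fixed = TRUE)[[1L]]
  genotype <- substr(parts[1L], 1L, 1L)
  list(treated = parts[1L], control = parts[2L], genotype = genotype,
       time = as.integer(sub("^[EN]", "", parts[1L])))
}

comparison_for <- function(genotype, time) sprintf("%s%d/%s0", genotype, time, genotype)

#' Recovery metrics against a planted truth set
#'
#' @param called character vector of ids called by the pipeline.
#' @param truth character vector of planted ids.
#' @return named numeric vector with `sensitivity` (fraction of `truth`
#'   recovered) and `fdr` (fraction of `called` not in `truth`).
#' @export
recovery <- function(called, truth) {
  called <- unique(called)
  truth <- unique(truth)
  sens <- if (length(truth) == 0L) NA_real_ else mean(truth %in% called)
  fdr <- if (length(called) == 0L) 0 else mean(!called %in% truth)
  c(sensitivity = sens, fdr = fdr)
}

#' Fraction of a proteome also detected at the mRNA level
#'
#' The congruency figure between the two detection universes: the number
#' of proteins whose genes were also detected by mRNA-seq, as a
#' percentage of all identified proteins.
#'
#' @param n_shared count of proteins with a detected transcript.
#' @param n_proteome count of identified proteins.
#' @param digits decimal places of the printed percentage (default 2).
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' overlap_percentage(3162, 4004)  # 78.97
overlap_percentage <- function(n_shared, n_proteome, digits = 2) {
  stopifnot(is.numeric(n_shared), is.numeric(n_proteome), n_proteome > 0,
            n_shared >= 0, n_shared <= n_proteome)
  round(100 * n_shared / n_proteome, digits)
}
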