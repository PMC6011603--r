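# Configuration of the synthetic multi-omics generator.

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults emulate the study design being modelled: 2 genotypes
#' (tolerant E, sensitive N) x 3 time points (0/4/24 h), one mRNA and one
#' small-RNA library per sample, three proteomic replicates per sample,
#' and planted differential structure at every molecular level. All
#' noise models are generator choices (the upstream tools report only
#' processed tables): Poisson count noise per library, log-normal
#' multiplicative noise on iTRAQ replicate ratios.
#'
#' @param n_genes number of genes in the expression matrix.
#' @param n_proteins number of protein-mapped genes (quantified proteome).
#' @param n_mirnas number of miRNAs.
#' @param frac_deg fraction of entities planted differential per
#'   comparison.
#' @param category_probs probability vector over concordance categories
#'   I-VI for the protein-mapped differential pairs (must sum to 1).
#' @param effect_log2fc_range interval of planted |log2 fold change| for
#'   mRNA effects.
#' @param mrna_library_size expected mRNA reads per library.
#' @param protein_replicates number of proteomic replicates (3).
#' @param protein_cv standard deviation of replicate log2 ratios around
#'   the true log2 ratio.
#' @param mirna_library_size expected small-RNA reads per library.
#' @param frac_planted_targets fraction of tolerant-genotype DE miRNAs
#'   given an anticorrelated planted target gene.
#' @param n_planted_protein_chains number of planted miRNA-up /
#'   protein-down / gene-ns translational-repression triples.
#' @param as_event_rate_control,as_event_rate_treated_tolerant,as_event_rate_treated_sensitive
#'   per-gene Bernoulli AS event rates; defaults mirror the observed
#'   direction (tolerant gains events under salt, sensitive loses them).
#' @param as_type_probs event-type probabilities over IR/ES/A5SS/A3SS
#'   (IR-dominant by default).
#' @param n_planted_rule_hits named integer vector of planted screening
#'   rule hits for rules i-v.
#' @param count_model `"poisson"` (default) or `"none"` (deterministic
#'   expected counts, the zero-count-noise limit).
#' @param seed master seed; every sub-generator derives its own stream.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 6000,
                       n_proteins = 1500,
                       n_mirnas = 200,
                       frac_deg = 0.1,
                       category_probs = c(I = 0.10, II = 0.05, III = 0.40,
                                          IV = 0.15, V = 0.25, VI = 0.05),
                       effect_log2fc_range = c(2, 4),
                       mrna_library_size = 5e6,
                       protein_replicates = 3,
                       protein_cv = 0.25,
                       mirna_library_size = 1e6,
                       frac_planted_targets = 0.5,
                       n_planted_protein_chains = 3,
                       as_event_rate_control = 0.05,
                       as_event_rate_treated_tolerant = 0.08,
                       as_event_rate_treated_sensitive = 0.03,
                       as_type_probs = c(IR = 0.55, ES = 0.20,
                                         A5SS = 0.15, A3SS = 0.10),
                       n_planted_rule_hits = c(i = 4, ii = 4, iii = 4,
                                               iv = 4, v = 4),
                       count_model = c("poisson", "none"),
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_proteins = n_proteins,
              n_mirnas = n_mirnas, frac_deg = frac_deg,
              category_probs = category_probs,
              effect_log2fc_range = effect_log2fc_range,
              mrna_library_size = mrna_library_size,
              protein_replicates = protein_replicates,
              protein_cv = protein_cv,
              mirna_library_size = mirna_library_size,
              frac_planted_targets = frac_planted_targets,
              n_planted_protein_chains = n_planted_protein_chains,
              as_event_rate_control = as_event_rate_control,
              as_event_rate_treated_tolerant = as_event_rate_treated_tolerant,
              as_event_rate_treated_sensitive = as_event_rate_treated_sensitive,
              as_type_probs = as_type_probs,
              n_planted_rule_hits = n_planted_rule_hits,
              count_model = match.arg(count_model),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v))
      stop("invalid config field '", field, "': must be a positive count")
  }
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1))
      stop("invalid config field '", field, "': must lie in [0, 1]")
  }
  for (f in c("n_genes", "n_proteins", "n_mirnas", "protein_replicates",
              "mrna_library_size", "mirna_library_size"))
    chk_count(f)
  for (f in c("frac_deg", "frac_planted_targets", "as_event_rate_control",
              "as_event_rate_treated_tolerant",
              "as_event_rate_treated_sensitive"))
    chk_frac(f)
  if (cfg$n_proteins > cfg$n_genes)
    stop("invalid config field 'n_proteins': exceeds n_genes")
  cp <- cfg$category_probs
  if (length(cp) != 6L || !identical(names(cp), c("I", "II", "III", "IV", "V", "VI")))
    stop("invalid config field 'category_probs': need named probs for I-VI")
  if (any(cp < 0) || abs(sum(cp) - 1) > 1e-9)
    stop("invalid config field 'category_probs': must be non-negative and sum to 1")
  tp <- cfg$as_type_probs
  if (length(tp) != 4L || any(tp < 0) || abs(sum(tp) - 1) > 1e-9)
    stop("invalid config field 'as_type_probs': must be 4 non-negative probs summing to 1")
  r <- cfg$effect_log2fc_range
  if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
    stop("invalid config field 'effect_log2fc_range': need 0 < lo <= hi")
  if (cfg$protein_cv < 0)
    stop("invalid config field 'protein_cv': must be >= 0")
  h <- cfg$n_planted_rule_hits
  if (!identical(names(h), c("i", "ii", "iii", "iv", "v")) || any(h < 0))
    stop("invalid config field 'n_planted_rule_hits': need non-negative counts named i-v")
  if (cfg$n_planted_protein_chains < 0)
    stop("invalid config field 'n_planted_protein_chains': must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic multi-omics config:",
      x$n_genes, "genes,", x$n_proteins, "proteins,",
      x$n_mirnas, "miRNAs; frac_deg =", x$frac_deg,
      "; count model:", x$count_model, "; seed", x$seed, "\n")
  invisible(x)
}

# one master seed, independent derived streams per sub-generator
derive_seed <- function(seed, stream) {
  offs <- c(counts = 101L, proteome = 211L, mirna = 307L, as = 401L,
            ppi = 503L)
  (as.integer(seed) * 7919L + offs[[stream]]) %% 2147483647L
}
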