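# Synthetic multi-omics generator with planted ground truth. Every
# downstream stage is testable by recovery against the truth tables,
# without any external download.

RANDOM_CATEGORIES <- c("I", "II", "III", "IV", "V", "VI")

# per-pair effect pattern: gene log2fc and protein log2 ratio for the
# four comparisons (E4, E24, N4, N24), plus whether the protein is
# quantified at all
pair_pattern <- function(cat, s, u_g, u_p) {
  g <- c(0, 0, 0, 0)
  p <- c(0, 0, 0, 0)
  quantified <- TRUE
  # for unplanted differential pairs the N-side magnitude is strictly
  # larger than the E side, so neither measurement noise nor library-
  # composition shifts can push them over the tolerant-dominance
  # predicates (|log2 E| > |log2 N|) used by screening and AS ranking
  g_en <- function(v) { g[1:2] <<- v; g[3:4] <<- v + sign(v) * 0.3 }
  switch(cat,
         I = { g_en(s * u_g); p[] <- s * u_p },
         II = { g_en(s * u_g); p[] <- -s * u_p },
         III = g_en(s * u_g),
         IV = { p[1:2] <- s * u_p; p[3:4] <- s * (u_p + 0.5) },
         V = { g_en(s * u_g); quantified <- FALSE },
         VI = { p[1:2] <- s * u_p },
         rule_i = { g[1:2] <- s * 3; g[3:4] <- s * 1.5 },
         rule_ii = { g[1:2] <- s * 2; g[3:4] <- -s * 2 },
         rule_iii = { g[1:2] <- s * 3 },
         rule_iv = { p[1:2] <- s * 1.5; p[3:4] <- s * 0.8 },
         rule_v = { p[1:2] <- s * 1.5 },
         chainIV = { p[1:2] <- -1.2; p[3:4] <- -1.8 },
         null = { },
         stop("unknown pair pattern: ", cat))
  list(g = g, p = p, quantified = quantified)
}

#' Simulate the mRNA count matrix and initialise the truth tables
#'
#' Draws per-gene expected abundances (log-normal relative weights scaled
#' to the library size), plants differential effects and the
#' gene-protein category structure, then draws independent Poisson counts
#' per library (one library per condition; no replicate dispersion is
#' identifiable with this design). Planted differential genes get an
#' expected-count floor of 50 so their effects are detectable by design.
#'
#' @param cfg a [sim_config()].
#' @return list with `expression` (list: gene_id, lengths, counts — a
#'   genes x 6 matrix with columns E0/E4/E24/N0/N4/N24) and `truth`.
#' @export
simulate_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "counts"))
  n <- cfg$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  lengths <- sample(600:3000, n, replace = TRUE)

  n_rules <- sum(cfg$n_planted_rule_hits)
  n_pc <- cfg$n_planted_protein_chains
  if (n_rules + n_pc > cfg$n_proteins)
    stop("truth/config mismatch: planted rule hits plus protein chains ",
         "exceed n_proteins")

  # pair design: which category each protein-mapped slot realises
  pair_cat <- rep("null", cfg$n_proteins)
  pair_cat[seq_len(n_rules)] <-
    rep(paste0("rule_", names(cfg$n_planted_rule_hits)),
        cfg$n_planted_rule_hits)
  if (n_pc > 0) pair_cat[n_rules + seq_len(n_pc)] <- "chainIV"
  free <- which(pair_cat == "null")
  is_de_pair <- stats::runif(length(free)) < cfg$frac_deg
  pair_cat[free[is_de_pair]] <- sample(RANDOM_CATEGORIES, sum(is_de_pair),
                                       replace = TRUE,
                                       prob = cfg$category_probs)

  lfc <- matrix(0, n, 4L, dimnames = list(gene_id, COMPARISONS))
  protein_id <- sprintf("prot_%05d", seq_len(cfg$n_proteins))
  prot_gene <- gene_id[seq_len(cfg$n_proteins)]
  ghost <- pair_cat == "VI"
  prot_gene[ghost] <- sprintf("gene_ghost_%04d", seq_len(sum(ghost)))
  l2r <- matrix(0, cfg$n_proteins, 4L,
                dimnames = list(protein_id, COMPARISONS))
  quantified <- rep(TRUE, cfg$n_proteins)
  s_pair <- sample(c(-1, 1), cfg$n_proteins, replace = TRUE)
  u_g <- stats::runif(cfg$n_proteins, cfg$effect_log2fc_range[1L],
                      cfg$effect_log2fc_range[2L])
  u_p <- stats::runif(cfg$n_proteins, 1, 2)
  for (j in seq_len(cfg$n_proteins)) {
    pat <- pair_pattern(pair_cat[j], s_pair[j], u_g[j], u_p[j])
    if (!ghost[j]) lfc[j, ] <- pat$g
    l2r[j, ] <- pat$p
    quantified[j] <- pat$quantified
  }

  # background (unmapped) genes: persistent per-genotype response so a
  # gene differential at 4 h keeps its effect at 24 h
  bg <- setdiff(seq_len(n), seq_len(cfg$n_proteins))
  for (block in list(1:2, 3:4)) {
    de <- bg[stats::runif(length(bg)) < cfg$frac_deg]
    eff <- sample(c(-1, 1), length(de), replace = TRUE) *
      stats::runif(length(de), cfg$effect_log2fc_range[1L],
                   cfg$effect_log2fc_range[2L])
    lfc[de, block] <- eff
  }

  w <- stats::rlnorm(n, 0, 1)
  lambda0 <- w / sum(w) * cfg$mrna_library_size
  planted <- rowSums(lfc != 0) > 0
  lambda0[planted] <- pmax(lambda0[planted], 50)

  mu <- cbind(E0 = lambda0,
              E4 = lambda0 * 2^lfc[, "E4/E0"],
              E24 = lambda0 * 2^lfc[, "E24/E0"],
              N0 = lambda0,
              N4 = lambda0 * 2^lfc[, "N4/N0"],
              N24 = lambda0 * 2^lfc[, "N24/N0"])
  counts <- if (cfg$count_model == "poisson")
    matrix(stats::rpois(length(mu), mu), n, 6L) else round(mu)
  dimnames(counts) <- list(gene_id, SAMPLES)

  truth <- list(
    genes = data.frame(gene_id = gene_id, length = lengths,
                       lambda0 = lambda0,
                       lfc_E4 = lfc[, 1L], lfc_E24 = lfc[, 2L],
                       lfc_N4 = lfc[, 3L], lfc_N24 = lfc[, 4L],
                       row.names = NULL, stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = protein_id, gene_id = prot_gene,
                          pattern = pair_cat, quantified = quantified,
                          l2r_E4 = l2r[, 1L], l2r_E24 = l2r[, 2L],
                          l2r_N4 = l2r[, 3L], l2r_N24 = l2r[, 4L],
                          row.names = NULL, stringsAsFactors = FALSE),
    rule_hits = local({
      idx <- which(startsWith(pair_cat, "rule_"))
      if (!length(idx))
        data.frame(id = character(), level = character(), rule = character(),
                   stringsAsFactors = FALSE)
      else {
        rule <- sub("^rule_", "", pair_cat[idx])
        level <- ifelse(rule %in% c("i", "ii", "iii"), "gene", "protein")
        data.frame(id = ifelse(level == "gene", prot_gene[idx],
                               protein_id[idx]),
                   level = level, rule = rule, stringsAsFactors = FALSE)
      }
    }))
  list(expression = list(gene_id = gene_id, lengths = lengths,
                         counts = counts),
       truth = truth)
}

#' Simulate replicate iTRAQ quantification around the planted truth
#'
#' Peptide tallies are drawn from a small discrete distribution so all
#' four identification tiers are populated; planted differential
#' proteins are well-sampled (>= 1 peptide in every replicate). Replicate
#' ratios scatter log-normally around the category-implied true ratio;
#' a ratio is present in a replicate when that replicate saw a peptide
#' (unquantified-truth proteins never get ratios).
#'
#' @param cfg a [sim_config()].
#' @param truth truth list from [simulate_counts()].
#' @return data.frame with protein_id, gene_id, pep_r1..3 and
#'   ratio_<E4|E24|N4|N24>_r1..3 columns (NA = missing).
#' @export
simulate_proteome <- function(cfg, truth) {
  validate_sim_config(cfg)
  pr <- truth$proteins
  if (is.null(pr) || nrow(pr) != cfg$n_proteins)
    stop("truth/config mismatch: protein truth does not match n_proteins")
  set.seed(derive_seed(cfg$seed, "proteome"))
  np <- nrow(pr)
  nonnull <- rowSums(abs(pr[, c("l2r_E4", "l2r_E24", "l2r_N4", "l2r_N24")])) > 0
  pep <- matrix(sample(0:4, 3L * np, replace = TRUE,
                       prob = c(0.15, 0.35, 0.25, 0.15, 0.10)), np, 3L)
  pep[nonnull, ] <- matrix(sample(1:4, 3L * sum(nonnull), replace = TRUE),
                           sum(nonnull), 3L)
  none <- rowSums(pep) == 0
  pep[none, 1L] <- 1L  # the table only lists identified proteins
  out <- data.frame(protein_id = pr$protein_id, gene_id = pr$gene_id,
                    pep_r1 = pep[, 1L], pep_r2 = pep[, 2L],
                    pep_r3 = pep[, 3L], stringsAsFactors = FALSE)
  for (cmp in COMPARISONS) {
    l2r <- pr[[paste0("l2r_", sub("/.*", "", cmp))]]
    for (r in 1:3) {
      present <- pr$quantified & pep[, r] >= 1
      val <- 2^(l2r + stats::rnorm(np, 0, cfg$protein_cv))
      val[!present] <- NA_real_
      out[[sprintf("ratio_%s_r%d", sub("/.*", "", cmp), r)]] <- val
    }
  }
  out
}

random_nt <- function(n_len) {
  vapply(n_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(lapply(strsplit(x, ""), rev), paste,
                                character(1), collapse = ""))
}

inject_site <- function(cds, mirna_dna, offset, n_mismatch) {
  site <- revcomp_chr(mirna_dna)
  if (n_mismatch > 0) {
    pos <- sample(nchar(site), n_mismatch)
    sv <- strsplit(site, "")[[1L]]
    for (p in pos) sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1L)
    site <- paste(sv, collapse = "")
  }
  paste0(substr(cds, 1L, offset - 1L), site,
         substr(cds, offset + nchar(site), nchar(cds)))
}

#' Simulate miRNA profiles, sequences, CDS library and planted targets
#'
#' 21-nt miRNAs with differential expression planted per genotype; a
#' fraction of the tolerant-genotype DE miRNAs receive an anticorrelated
#' planted target gene whose CDS carries the reverse complement of the
#' miRNA with 0-2 injected mismatches. Additional planted triples pair an
#' up-regulated miRNA with a protein-down / gene-ns pair (candidate
#' translational repression).
#'
#' @param cfg a [sim_config()].
#' @param truth truth list from [simulate_counts()].
#' @return list with `profiles` (mirna_id, class, counts matrix),
#'   `mirna_seqs`, `cds_seqs` (named character vectors, DNA alphabet) and
#'   the updated `truth` (adds `mirnas`, `targets`, `chains`).
#' @export
simulate_mirnas_and_targets <- function(cfg, truth) {
  validate_sim_config(cfg)
  if (is.null(truth$genes)) stop("truth/config mismatch: no gene truth")
  set.seed(derive_seed(cfg$seed, "mirna"))
  nm <- cfg$n_mirnas
  n_known <- max(1L, round(0.2 * nm))
  mirna_id <- c(sprintf("ghr-miR%03d", seq_len(n_known)),
                sprintf("novel_mir_%03d", seq_len(nm - n_known)))
  class <- rep(c("known", "novel"), c(n_known, nm - n_known))

  # small-RNA libraries are few-species and heavy-tailed, so RPM ratios
  # suffer composition bias when abundant species shift. Plant effects
  # only on miRNAs holding a modest library share, with balanced signs,
  # to keep measured fold changes close to the planted ones.
  w <- stats::rlnorm(nm, 0, 1)
  share <- w / sum(w)
  lfc <- matrix(0, nm, 4L, dimnames = list(mirna_id, COMPARISONS))
  n_de <- round(cfg$frac_deg * nm)
  modest <- which(share < 0.05)
  de_idx <- sample(modest, min(n_de, length(modest)))
  n_de <- length(de_idx)
  pattern <- sample(c("E", "N", "EN"), n_de, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
  sgn <- sample(rep_len(c(-1, 1), n_de))
  mag <- stats::runif(n_de, 2, 3)
  for (k in seq_len(n_de)) {
    i <- de_idx[k]
    if (pattern[k] %in% c("E", "EN")) lfc[i, 1:2] <- sgn[k] * mag[k]
    if (pattern[k] %in% c("N", "EN")) lfc[i, 3:4] <- sgn[k] * mag[k]
  }

  genes <- truth$genes
  mapped <- genes$gene_id %in% truth$proteins$gene_id
  # persistent tolerant-genotype DE genes, free for target planting
  bg_de <- which(!mapped & genes$lfc_E4 != 0 & genes$lfc_E4 == genes$lfc_E24)
  e_de <- which(lfc[, 1L] != 0)
  n_targets <- round(cfg$frac_planted_targets * length(e_de))
  n_targets <- min(n_targets, length(bg_de))
  target_mirna <- if (n_targets) sample(e_de, n_targets) else integer()
  target_gene <- if (n_targets) sample(bg_de, n_targets) else integer()
  # anticorrelation: flip the miRNA's sign against its target's response
  for (k in seq_along(target_mirna)) {
    i <- target_mirna[k]
    lfc[i, 1:2] <- -sign(genes$lfc_E4[target_gene[k]]) * abs(lfc[i, 1:2])
  }

  # translational-repression triples: up miRNA vs protein-down/gene-ns pair
  chain_pairs <- which(truth$proteins$pattern == "chainIV")
  n_pc <- min(cfg$n_planted_protein_chains, length(chain_pairs))
  pc_mirna <- integer()
  if (n_pc > 0) {
    # undisturbed modest-share miRNAs only, so the forced up-in-E effect
    # is the triple's sole differential signal
    avail <- setdiff(intersect(which(rowSums(lfc != 0) == 0), modest),
                     target_mirna)
    pc_mirna <- sample(avail, n_pc)
    for (i in pc_mirna) lfc[i, 1:2] <- stats::runif(1, 2, 3)  # force up in E
  }

  mirna_seqs <- stats::setNames(random_nt(rep(21L, nm)), mirna_id)
  cds_len <- sample(300:1500, nrow(genes), replace = TRUE)
  cds_seqs <- stats::setNames(random_nt(cds_len), genes$gene_id)

  targets <- data.frame(mirna_id = character(), gene_id = character(),
                        offset = integer(), mismatches = integer(),
                        stringsAsFactors = FALSE)
  plant <- function(mi, gi, targets) {
    g <- genes$gene_id[gi]
    mm <- sample(0:2, 1L)
    off <- sample(nchar(cds_seqs[[g]]) - 21L, 1L)
    cds_seqs[[g]] <<- inject_site(cds_seqs[[g]], mirna_seqs[[mirna_id[mi]]],
                                  off, mm)
    rbind(targets, data.frame(mirna_id = mirna_id[mi], gene_id = g,
                              offset = off, mismatches = mm,
                              stringsAsFactors = FALSE))
  }
  for (k in seq_along(target_mirna))
    targets <- plant(target_mirna[k], target_gene[k], targets)
  chains <- list()
  for (k in seq_along(target_mirna)) {
    i <- target_mirna[k]; g <- genes$gene_id[target_gene[k]]
    for (cmp in COMPARISONS[1:2])
      chains[[length(chains) + 1L]] <- data.frame(
        mirna_id = mirna_id[i], gene_id = g, protein_id = NA_character_,
        comparison = cmp,
        mirna_direction = ifelse(lfc[i, cmp] > 0, "up", "down"),
        level = "gene", stringsAsFactors = FALSE)
  }
  if (n_pc > 0) {
    pg <- match(truth$proteins$gene_id[chain_pairs[seq_len(n_pc)]],
                genes$gene_id)
    for (k in seq_len(n_pc)) {
      targets <- plant(pc_mirna[k], pg[k], targets)
      for (cmp in COMPARISONS[1:2])
        chains[[length(chains) + 1L]] <- data.frame(
          mirna_id = mirna_id[pc_mirna[k]], gene_id = genes$gene_id[pg[k]],
          protein_id = truth$proteins$protein_id[chain_pairs[k]],
          comparison = cmp, mirna_direction = "up", level = "protein",
          stringsAsFactors = FALSE)
    }
  }

  lambda0 <- share * cfg$mirna_library_size
  mu <- cbind(E0 = lambda0, E4 = lambda0 * 2^lfc[, 1L],
              E24 = lambda0 * 2^lfc[, 2L], N0 = lambda0,
              N4 = lambda0 * 2^lfc[, 3L], N24 = lambda0 * 2^lfc[, 4L])
  counts <- if (cfg$count_model == "poisson")
    matrix(stats::rpois(length(mu), mu), nm, 6L) else round(mu)
  dimnames(counts) <- list(mirna_id, SAMPLES)

  truth$mirnas <- data.frame(mirna_id = mirna_id, class = class,
                             lfc_E4 = lfc[, 1L], lfc_E24 = lfc[, 2L],
                             lfc_N4 = lfc[, 3L], lfc_N24 = lfc[, 4L],
                             row.names = NULL, stringsAsFactors = FALSE)
  truth$targets <- targets
  truth$chains <- if (length(chains)) do.call(rbind, chains) else
    data.frame(mirna_id = character(), gene_id = character(),
               protein_id = character(), comparison = character(),
               mirna_direction = character(), level = character(),
               stringsAsFactors = FALSE)
  list(profiles = list(mirna_id = mirna_id, class = class, counts = counts),
       mirna_seqs = mirna_seqs, cds_seqs = cds_seqs, truth = truth)
}

#' Simulate alternative-splicing events
#'
#' Per sample and gene, an event occurs with a class-specific Bernoulli
#' rate: `as_event_rate_control` at 0 h, the treated-tolerant rate for
#' salt-treated E samples (above control by default) and the
#' treated-sensitive rate for salt-treated N samples (below control).
#' Event types are drawn from `as_type_probs` (IR-dominant).
#'
#' @param cfg a [sim_config()].
#' @param truth truth list from [simulate_counts()].
#' @return AS event data.frame (gene_id, sample, type, start, end). The
#'   event table is its own truth.
#' @export
simulate_as_events <- function(cfg, truth) {
  validate_sim_config(cfg)
  if (is.null(truth$genes)) stop("truth/config mismatch: no gene truth")
  set.seed(derive_seed(cfg$seed, "as"))
  genes <- truth$genes
  rate_of <- c(E0 = cfg$as_event_rate_control,
               E4 = cfg$as_event_rate_treated_tolerant,
               E24 = cfg$as_event_rate_treated_tolerant,
               N0 = cfg$as_event_rate_control,
               N4 = cfg$as_event_rate_treated_sensitive,
               N24 = cfg$as_event_rate_treated_sensitive)
  out <- list()
  for (s in SAMPLES) {
    hit <- which(stats::runif(nrow(genes)) < rate_of[[s]])
    if (!length(hit)) next
    len <- genes$length[hit]
    start <- 1L + floor(stats::runif(length(hit)) * pmax(1, len - 220))
    end <- pmin(len, start + sample(30:200, length(hit), replace = TRUE))
    out[[s]] <- data.frame(
      gene_id = genes$gene_id[hit], sample = s,
      type = sample(AS_TYPES, length(hit), replace = TRUE,
                    prob = cfg$as_type_probs),
      start = start, end = end, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), sample = character(),
                      type = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the ortholog map and scored PPI edge table
#'
#' Two planted hub nodes are wired to the planted screening candidates'
#' orthologs with combined scores above the retention threshold;
#' background edges carry scores straddling the threshold, and a few
#' low-scoring candidate-candidate edges exercise the filter.
#'
#' @param cfg a [sim_config()].
#' @param truth truth list after [simulate_counts()] (uses the planted
#'   rule hits and proteome-only candidates).
#' @return list with `ortholog_map` (id, ortholog), `edges` (node_a,
#'   node_b, combined_score) and updated `truth` (adds `hubs`).
#' @export
simulate_ppi <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "ppi"))
  genes <- truth$genes$gene_id
  ghosts <- setdiff(truth$proteins$gene_id, genes)
  all_genes <- c(genes, ghosts)
  orth <- sprintf("AT1G%05d", seq_along(all_genes) * 10L)
  map <- data.frame(id = all_genes, ortholog = orth,
                    stringsAsFactors = FALSE)
  pmap <- data.frame(id = truth$proteins$protein_id,
                     ortholog = orth[match(truth$proteins$gene_id, all_genes)],
                     stringsAsFactors = FALSE)
  ortholog_map <- rbind(map, pmap)

  cand <- unique(c(truth$rule_hits$id,
                   truth$proteins$protein_id[truth$proteins$pattern == "VI"]))
  cand_orth <- unique(ortholog_map$ortholog[match(cand, ortholog_map$id)])
  hubs <- c("ATMG01190", "ATMG00160")  # ATP synthase / cytochrome oxidase
  assign_hub <- rep_len(hubs, length(cand_orth))
  hub_edges <- data.frame(node_a = assign_hub, node_b = cand_orth,
                          combined_score = sample(200:900, length(cand_orth),
                                                  replace = TRUE),
                          stringsAsFactors = FALSE)
  bg_nodes <- sprintf("AT5G%05d", 90000 + seq_len(80))
  bg_edges <- data.frame(node_a = sample(bg_nodes, 150, replace = TRUE),
                         node_b = sample(bg_nodes, 150, replace = TRUE),
                         combined_score = sample(80:320, 150, replace = TRUE),
                         stringsAsFactors = FALSE)
  low_cand <- if (length(cand_orth) >= 2)
    data.frame(node_a = sample(cand_orth, 10, replace = TRUE),
               node_b = sample(cand_orth, 10, replace = TRUE),
               combined_score = sample(80:159, 10, replace = TRUE),
               stringsAsFactors = FALSE)
  else NULL
  edges <- rbind(hub_edges, bg_edges, low_cand)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  rownames(edges) <- NULL
  truth$hubs <- hubs
  truth$ortholog_map <- ortholog_map
  list(ortholog_map = ortholog_map, edges = edges, truth = truth)
}

#' Run the whole generator
#'
#' @param cfg a [sim_config()].
#' @return list with `expression`, `proteins`, `mirna` (profiles),
#'   `mirna_seqs`, `cds_seqs`, `as_events`, `ortholog_map`, `ppi_edges`
#'   and `truth`.
#' @export
simulate_multiomics <- function(cfg = sim_config()) {
  base <- simulate_counts(cfg)
  proteins <- simulate_proteome(cfg, base$truth)
  mir <- simulate_mirnas_and_targets(cfg, base$truth)
  as_events <- simulate_as_events(cfg, mir$truth)
  ppi <- simulate_ppi(cfg, mir$truth)
  list(expression = base$expression, proteins = proteins,
       mirna = mir$profiles, mirna_seqs = mir$mirna_seqs,
       cds_seqs = mir$cds_seqs, as_events = as_events,
       ortholog_map = ppi$ortholog_map, ppi_edges = ppi$edges,
       truth = ppi$truth)
}

# ---- truth accessors -------------------------------------------------

lfc_col <- function(comparison) paste0("lfc_", sub("/.*", "", comparison))
l2r_col <- function(comparison) paste0("l2r_", sub("/.*", "", comparison))

#' Planted DEGs / DAPs / DE miRNAs for a comparison
#'
#' @param truth truth list from the generator.
#' @param comparison comparison label.
#' @return character vector of planted ids.
#' @export
true_degs <- function(truth, comparison) {
  truth$genes$gene_id[truth$genes[[lfc_col(comparison)]] != 0]
}

#' @rdname true_degs
#' @export
true_daps <- function(truth, comparison) {
  pr <- truth$proteins
  pr$protein_id[pr$quantified & pr[[l2r_col(comparison)]] != 0]
}

#' @rdname true_degs
#' @export
true_de_mirnas <- function(truth, comparison) {
  truth$mirnas$mirna_id[truth$mirnas[[lfc_col(comparison)]] != 0]
}

#' Concordance categories implied by the planted truth
#'
#' Applies the category definitions to the noise-free effect tables: the
#' reference against which the pipeline's classification is scored.
#'
#' @param truth truth list from the generator.
#' @param comparison comparison label.
#' @return data.frame with id (protein or gene), gene_id, category.
#' @export
true_categories <- function(truth, comparison) {
  pr <- truth$proteins
  genes <- truth$genes
  g_lfc <- genes[[lfc_col(comparison)]][match(pr$gene_id, genes$gene_id)]
  detected <- pr$gene_id %in% genes$gene_id
  g_de <- !is.na(g_lfc) & g_lfc != 0
  p_eff <- pr[[l2r_col(comparison)]]
  p_de <- pr$quantified & p_eff != 0
  cat <- rep(NA_character_, nrow(pr))
  cat[detected & g_de & p_de & sign(g_lfc) == sign(p_eff)] <- "I"
  cat[detected & g_de & p_de & sign(g_lfc) != sign(p_eff)] <- "II"
  cat[detected & g_de & !p_de & pr$quantified] <- "III"
  cat[detected & !g_de & p_de] <- "IV"
  cat[detected & g_de & !pr$quantified] <- "V"
  cat[!detected & p_de] <- "VI"
  prot <- data.frame(id = pr$protein_id, gene_id = pr$gene_id,
                     category = cat, stringsAsFactors = FALSE)
  unmapped <- genes[!genes$gene_id %in% pr$gene_id, , drop = FALSE]
  u_de <- unmapped[[lfc_col(comparison)]] != 0
  rbind(prot,
        data.frame(id = unmapped$gene_id[u_de],
                   gene_id = unmapped$gene_id[u_de],
                   category = "V", stringsAsFactors = FALSE))
}

#' Planted screening candidates (rules i-v and proteome-only)
#'
#' @param truth truth list from the generator.
#' @return data.frame with id, level, rule (the planted sets are
#'   identical at both time points by construction).
#' @export
true_candidates <- function(truth) {
  vi <- truth$proteins$protein_id[truth$proteins$pattern == "VI"]
  rbind(truth$rule_hits,
        if (length(vi)) data.frame(id = vi, level = "protein",
                                   rule = "protein_only",
                                   stringsAsFactors = FALSE))
}
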