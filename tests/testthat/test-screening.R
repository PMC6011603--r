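pair_row <- function(gene, prot, cat, cmp) data.frame(
  gene_id = gene, protein_id = prot, comparison = cmp,
  gene_detected = TRUE, gene_log2fc = NA_real_, gene_status = NA_character_,
  protein_quantified = !is.na(prot), protein_log2ratio = NA_real_,
  protein_status = NA_character_, category = cat, stringsAsFactors = FALSE)
deg4 <- function(gene, lfc_e, lfc_n) rbind(
  data.frame(gene_id = gene, comparison = "E4/E0", log2fc = lfc_e, p = 0,
             fdr = ifelse(abs(lfc_e) >= 1, 1e-9, 0.5),
             status = ifelse(abs(lfc_e) < 1, "ns",
                             ifelse(lfc_e > 0, "up", "down"))),
  data.frame(gene_id = gene, comparison = "N4/N0", log2fc = lfc_n, p = 0,
             fdr = ifelse(abs(lfc_n) >= 1, 1e-9, 0.5),
             status = ifelse(abs(lfc_n) < 1, "ns",
                             ifelse(lfc_n > 0, "up", "down"))))
dap4 <- function(prot, ratio_e, ratio_n) rbind(
  data.frame(protein_id = prot, gene_id = paste0("g_", prot),
             comparison = "E4/E0", n_ratios = 3, mean_ratio = ratio_e,
             p = 0.01,
             status = ifelse(ratio_e > 1.2, "up",
                             ifelse(ratio_e < 0.833, "down", "ns"))),
  data.frame(protein_id = prot, gene_id = paste0("g_", prot),
             comparison = "N4/N0", n_ratios = 3, mean_ratio = ratio_n,
             p = 0.01,
             status = ifelse(ratio_n > 1.2, "up",
                             ifelse(ratio_n < 0.833, "down", "ns"))))

test_that("each screening rule admits exactly its textbook case", {
  pairs <- rbind(pair_row("g1", "pA", "III", "E4/E0"),
                 pair_row("g2", "pB", "III", "E4/E0"),
                 pair_row("g3", "pC", "III", "E4/E0"),
                 pair_row("g4", "pD", "III", "E4/E0"),
                 pair_row(NA, "p4", "IV", "E4/E0"),
                 pair_row(NA, "p5", "IV", "E4/E0"))
  pairs$gene_id[5:6] <- c("gp4", "gp5")
  degs <- rbind(deg4("g1", 2.0, 1.2),    # rule i: margin 0.8 >= 0.5
                deg4("g2", 1.5, -1.5),   # rule ii: opposite responses
                deg4("g3", 3.0, 0.1),    # rule iii: E-only
                deg4("g4", 2.0, 1.8))    # margin 0.2: no rule
  daps <- rbind(dap4("p4", 2.0, 1.3),    # rule iv: |1| > |log2 1.3|
                dap4("p5", 2.0, 1.0))    # rule v: E-only DAP
  cand <- apply_rules(pairs, degs, daps, 4)
  got <- setNames(cand$rule, cand$id)
  expect_equal(got[["g1"]], "i")
  expect_equal(got[["g2"]], "ii")
  expect_equal(got[["g3"]], "iii")
  expect_false("g4" %in% cand$id)
  expect_equal(got[["p4"]], "iv")
  expect_equal(got[["p5"]], "v")
  # stored effects re-satisfy each rule's predicate
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, ]
    ok <- switch(r$rule,
                 i = abs(r$effect_E) - abs(r$effect_N) >= 0.5 &&
                   sign(r$effect_E) == sign(r$effect_N),
                 ii = (r$effect_E >= 1 && r$effect_N <= -1) ||
                   (r$effect_E <= -1 && r$effect_N >= 1),
                 iii = abs(r$effect_E) >= 1 && abs(r$effect_N) < 1,
                 iv = abs(r$effect_E) > abs(r$effect_N) && r$effect_N != 0,
                 v = abs(r$effect_E) > 0)
    expect_true(ok, label = paste("predicate recheck for rule", r$rule))
  }
  # raising the rule-i margin never adds candidates
  for (m in c(0.5, 0.7, 0.9, 1.5)) {
    n_i <- sum(apply_rules(pairs, degs, daps, 4, margin = m)$rule == "i")
    if (m == 0.5) n_ref <- n_i
    expect_lte(n_i, n_ref)
    n_ref <- n_i
  }
})

test_that("rule iv requires a common direction in both genotypes", {
  pairs <- pair_row("gp6", "p6", "IV", "E4/E0")
  daps <- dap4("p6", 2.0, 0.5)  # up in E, down in N: not "commonly regulated"
  cand <- apply_rules(pairs, deg4("x", 0, 0), daps, 4)
  expect_false("p6" %in% cand$id)
})

test_that("the proteome-only screen keeps tolerant-only category VI DAPs", {
  pairs <- rbind(pair_row("gx1", "q1", "VI", "E4/E0"),
                 pair_row("gx2", "q2", "VI", "E4/E0"))
  daps <- rbind(dap4("q1", 1.5, 1.0),  # DAP in E only -> candidate
                dap4("q2", 1.5, 1.6))  # DAP in both -> excluded
  cand <- protein_only_screen(pairs, daps, 4)
  expect_equal(cand$id, "q1")
  expect_equal(cand$rule, "protein_only")
})

test_that("annotation flags are plain set memberships", {
  cand <- data.frame(id = c("g1", "g2", "p1"), level = c("gene", "gene", "protein"),
                     time = 4, rule = c("i", "iii", "v"),
                     effect_E = 2, effect_N = 0, stringsAsFactors = FALSE)
  as_degs <- data.frame(gene_id = c("g1", "gz"), genotype = "E", time = 4,
                        comparison = "E4/E0", log2fc = 2, status = "up")
  map <- data.frame(protein_id = "p1", gene_id = "g9")
  ann <- annotate_candidates(cand, as_degs, osmotic_genes = c("g9", "g2"),
                             map = map)
  expect_equal(ann$as_flag, c(TRUE, FALSE, FALSE))
  expect_equal(ann$osmotic_flag, c(FALSE, TRUE, TRUE))  # p1 via gene g9
  expect_warning(annotate_candidates(cand, as_degs, NULL, map), "osmotic")
  ann0 <- suppressWarnings(annotate_candidates(cand, as_degs, NULL, map))
  expect_false(any(ann0$osmotic_flag))
})

test_that("zero-noise candidates equal the planted rule hits, per rule and time", {
  cfg <- helper_cfg_exact(seed = 91)
  sim <- simulate_multiomics(cfg)
  res <- run_pipeline(sim)
  want <- true_candidates(sim$truth)
  for (t in c(4, 24)) {
    got <- res$candidates[res$candidates$time == t, ]
    expect_identical(sort(paste(got$id, got$rule)),
                     sort(paste(want$id, want$rule)))
  }
  # every record's stored effects still satisfy its predicate
  g4 <- res$candidates[res$candidates$rule == "i", ]
  if (nrow(g4))
    expect_true(all(abs(g4$effect_E) - abs(g4$effect_N) >= 0.5))
})
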