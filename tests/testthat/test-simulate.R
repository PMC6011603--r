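test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(frac_deg = 1.5), "frac_deg")
  expect_error(sim_config(category_probs = c(I = 0.5, II = 0.5, III = 0,
                                             IV = 0, V = 0.1, VI = 0)),
               "category_probs")
  expect_error(sim_config(effect_log2fc_range = c(4, 2)),
               "effect_log2fc_range")
  expect_error(sim_config(n_planted_rule_hits = c(i = -1, ii = 0, iii = 0,
                                                  iv = 0, v = 0)),
               "n_planted_rule_hits")
  expect_error(sim_config(n_genes = 50, n_proteins = 100), "n_proteins")
  expect_output(print(sim_config()), "seed")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- helper_cfg(seed = 17)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$cds_seqs, b$cds_seqs)
  expect_identical(a$as_events, b$as_events)
  expect_identical(a$ppi_edges, b$ppi_edges)
  expect_identical(a$truth, b$truth)
  # different seed, different draws
  c2 <- simulate_multiomics(helper_cfg(seed = 18))
  expect_false(identical(a$expression$counts, c2$expression$counts))
})

test_that("a null configuration plants no expression differences", {
  cfg <- helper_cfg(frac_deg = 0, n_planted_rule_hits = c(i = 0, ii = 0,
                                                          iii = 0, iv = 0, v = 0),
                    n_planted_protein_chains = 0, frac_planted_targets = 0,
                    seed = 19)
  base <- simulate_counts(cfg)
  lfc <- as.matrix(base$truth$genes[, c("lfc_E4", "lfc_E24", "lfc_N4", "lfc_N24")])
  expect_true(all(lfc == 0))
  l2r <- as.matrix(base$truth$proteins[, c("l2r_E4", "l2r_E24", "l2r_N4", "l2r_N24")])
  expect_true(all(l2r == 0))
})

test_that("zero replicate noise reproduces the true ratios exactly", {
  cfg <- helper_cfg(protein_cv = 0, seed = 20)
  base <- simulate_counts(cfg)
  quants <- simulate_proteome(cfg, base$truth)
  tr <- base$truth$proteins
  for (r in 1:3) {
    v <- quants[[paste0("ratio_E4_r", r)]]
    expect_equal(v[!is.na(v)], 2^tr$l2r_E4[!is.na(v)])
  }
})

test_that("planted sites score below the mismatch cutoff at the planted offset", {
  cfg <- helper_cfg(seed = 21)
  sim <- simulate_multiomics(cfg)
  tt <- sim$truth$targets
  expect_gt(nrow(tt), 0)
  for (k in seq_len(nrow(tt))) {
    hits <- scan_targets(sim$mirna_seqs[[tt$mirna_id[k]]],
                         sim$cds_seqs[tt$gene_id[k]])
    hit <- hits[hits$offset == tt$offset[k], ]
    expect_equal(nrow(hit), 1L)
    expect_lte(hit$penalty, tt$mismatches[k])  # substitutions may create wobbles
    if (tt$mismatches[k] == 0) expect_equal(hit$penalty, 0)
  }
})

test_that("spurious sub-cutoff hits are absent in a fixed random fixture", {
  set.seed(22)
  mirna <- random_seq(21)
  cds <- setNames(vapply(1:10, function(i) random_seq(300), ""),
                  sprintf("c%d", 1:10))
  expect_equal(nrow(scan_targets(mirna, cds)), 0L)
})

test_that("truth consistency: planted rule hits satisfy their predicates", {
  cfg <- helper_cfg(seed = 23)
  base <- simulate_counts(cfg)
  tr <- base$truth
  hits <- tr$rule_hits
  expect_equal(nrow(hits), sum(cfg$n_planted_rule_hits))
  genes <- tr$genes; prots <- tr$proteins
  for (k in seq_len(nrow(hits))) {
    if (hits$level[k] == "gene") {
      e <- genes$lfc_E4[genes$gene_id == hits$id[k]]
      n <- genes$lfc_N4[genes$gene_id == hits$id[k]]
      ok <- switch(hits$rule[k],
                   i = sign(e) == sign(n) && abs(n) >= 1 &&
                     abs(e) - abs(n) >= 0.5,
                   ii = (e >= 1 && n <= -1) || (e <= -1 && n >= 1),
                   iii = abs(e) >= 1 && n == 0)
    } else {
      e <- prots$l2r_E4[prots$protein_id == hits$id[k]]
      n <- prots$l2r_N4[prots$protein_id == hits$id[k]]
      ok <- switch(hits$rule[k],
                   iv = sign(e) == sign(n) && abs(e) > abs(n) && n != 0,
                   v = abs(e) > 0 && n == 0)
    }
    expect_true(ok, label = paste("planted", hits$rule[k], hits$id[k]))
  }
})

test_that("identification tiers are all populated under defaults", {
  cfg <- helper_cfg(seed = 24)
  base <- simulate_counts(cfg)
  quants <- simulate_proteome(cfg, base$truth)
  tiers <- tally_identification(quants)
  expect_true(all(tiers > 0))
  expect_gte(tiers[["identified"]], tiers[["robust"]])
  expect_gte(tiers[["quantified"]], tiers[["quantified_all3"]])
  expect_equal(tiers[["identified"]], nrow(quants))
})

test_that("proteome simulation rejects mismatched truth", {
  cfg <- helper_cfg(seed = 25)
  base <- simulate_counts(cfg)
  cfg2 <- helper_cfg(n_proteins = 299, seed = 25)
  expect_error(simulate_proteome(cfg2, base$truth), "mismatch")
})
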