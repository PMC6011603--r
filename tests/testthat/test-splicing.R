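ev <- function(gene, sample, type = "IR", start = 10, end = 50) {
  data.frame(gene_id = gene, sample = sample, type = type,
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("event counting, type fractions and per-sample AS gene sets", {
  empty <- ev("g", "E0")[0, ]
  res <- count_events(empty)
  expect_true(all(res$counts == 0))
  events <- rbind(ev("g1", "E4"), ev("g1", "E4"), ev("g2", "E4"),
                  ev("g3", "E4", "ES"), ev("g1", "N0", "A5SS"))
  res <- count_events(events)
  expect_equal(res$counts["E4", "IR"], 3L)
  expect_equal(res$fractions["E4", "IR"], 0.75)
  expect_equal(sum(res$fractions["E4", ]), 1)
  # a gene with events in two samples appears in both AS sets
  expect_true("g1" %in% res$as_genes$E4 && "g1" %in% res$as_genes$N0)
  expect_error(count_events(rbind(events, ev("g9", "E4", "XX"))),
               "unknown AS event type")
})

test_that("salt-specific AS distinguishes induced from lost genes", {
  events <- rbind(ev("g1", "E4"),                # induced at 4 h
                  ev("g2", "E0"), ev("g2", "E4"),  # present in control too
                  ev("g3", "E0"),                # lost at 4 h
                  ev("g4", "N4"))
  sets <- salt_specific_as_genes(events, "E", 4)
  expect_equal(sets$induced, "g1")
  expect_equal(sets$lost, "g3")
  # other genotype's events do not leak in
  expect_false("g4" %in% sets$induced)
})

test_that("AS-DEGs are the intersection of induced AS genes and DEGs", {
  events <- rbind(ev("g1", "E4"), ev("g2", "E4"), ev("g3", "E4"),
                  ev("g3", "E0"))
  degs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     comparison = "E4/E0", log2fc = c(3, 0.2, 3),
                     p = 1e-9, fdr = c(1e-9, 0.5, 1e-9),
                     status = c("up", "ns", "up"), stringsAsFactors = FALSE)
  as_degs <- select_as_degs(events, degs)
  expect_equal(as_degs$gene_id, "g1")  # g2 not DE, g3 not salt-specific
  # AS-DEG set is a subset of both parent sets, by construction
  expect_true(all(as_degs$gene_id %in% degs$gene_id[degs$status != "ns"]))
})

test_that("candidates need |log2 E/E0| above |log2 N/N0|", {
  as_degs <- data.frame(gene_id = c("g1", "g2"), genotype = "E", time = 4,
                        comparison = "E4/E0", log2fc = c(3, 2),
                        status = "up", stringsAsFactors = FALSE)
  degs <- rbind(
    data.frame(gene_id = c("g1", "g2"), comparison = "E4/E0",
               log2fc = c(3, 2), p = 0, fdr = 0, status = "up"),
    data.frame(gene_id = c("g1", "g2"), comparison = "N4/N0",
               log2fc = c(1.2, 2.5), p = 0, fdr = 0, status = "up"))
  cand <- rank_as_candidates(as_degs, degs)
  expect_equal(cand$gene_id, "g1")
  expect_equal(cand$margin, 3 - 1.2)
})

test_that("Monte-Carlo event rates track the configured Bernoulli rates", {
  # equal rates: per-sample mean counts agree within sampling error
  cfg_eq <- helper_cfg(n_genes = 400, as_event_rate_control = 0.06,
                       as_event_rate_treated_tolerant = 0.06,
                       as_event_rate_treated_sensitive = 0.06)
  totals <- matrix(0, 20, 6)
  for (k in 1:20) {
    cfg <- helper_cfg(n_genes = 400, as_event_rate_control = 0.06,
                      as_event_rate_treated_tolerant = 0.06,
                      as_event_rate_treated_sensitive = 0.06, seed = 100 + k)
    base <- simulate_counts(cfg)
    events <- simulate_as_events(cfg, base$truth)
    totals[k, ] <- rowSums(count_events(events)$counts)[c("E0", "E4", "E24", "N0", "N4", "N24")]
  }
  expect_true(all(abs(colMeans(totals) - 400 * 0.06) < 3 * sqrt(400 * 0.06) / sqrt(20) + 1))
  # default direction: tolerant gains events under salt
  gain <- 0
  for (k in 1:20) {
    cfg <- helper_cfg(n_genes = 400, seed = 200 + k)
    base <- simulate_counts(cfg)
    events <- simulate_as_events(cfg, base$truth)
    counts <- rowSums(count_events(events)$counts)
    gain <- gain + (counts[["E24"]] > counts[["E0"]])
  }
  expect_gte(gain, 18)
})

test_that("planted AS candidates are recovered exactly at zero noise", {
  cfg <- helper_cfg_exact(seed = 61)
  sim <- simulate_multiomics(cfg)
  res <- run_pipeline(sim, scan_targets = FALSE)
  # truth-side derivation from the event table and planted effects
  tr <- sim$truth
  for (t in c(4, 24)) {
    induced <- salt_specific_as_genes(sim$as_events, "E", t)$induced
    lfc_e <- tr$genes[[paste0("lfc_E", t)]]
    lfc_n <- tr$genes[[paste0("lfc_N", t)]]
    de <- tr$genes$gene_id[lfc_e != 0]
    expected <- intersect(induced, de)
    expected <- expected[abs(lfc_e[match(expected, tr$genes$gene_id)]) >
                           abs(lfc_n[match(expected, tr$genes$gene_id)])]
    got <- res$as_candidates$gene_id[res$as_candidates$time == t]
    expect_setequal(got, expected)
  }
})
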