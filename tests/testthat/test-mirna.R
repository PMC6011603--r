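mk_profiles <- function(counts) {
  list(mirna_id = rownames(counts), class = rep("known", nrow(counts)),
       counts = counts)
}

test_that("RPM normalisation and the eligibility filter", {
  counts <- matrix(c(1, 12, 12, 1, 22, 22,      # eligible: RPM 12 at E4, sum 70
                     10, 10, 10, 10, 10, 9,     # sum 59 ineligible
                     10, 10, 10, 10, 10, 10),   # sum 60 exactly: ineligible
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("m1", "m2", "m3"),
                                   c("E0", "E4", "E24", "N0", "N4", "N24")))
  # pad every library total to exactly 1e6 so counts ARE the RPM values
  pad <- matrix(1e6 - colSums(counts), 1, 6,
                dimnames = list("pad", colnames(counts)))
  profiles <- mk_profiles(rbind(counts, pad))
  res <- filter_and_call_de_mirnas(profiles, "E4/E0")
  expect_true(res$eligible[res$mirna_id == "m1"])
  expect_false(res$eligible[res$mirna_id == "m2"])  # RPM sum 59 < 60
  expect_false(res$eligible[res$mirna_id == "m3"])  # RPM sum 60 not > 60
  rpm <- compute_rpm(profiles$counts)
  expect_equal(unname(rpm["m1", "E4"]), 12)
  # the "both samples" variant of the RPM >= 10 rule is stricter
  res_both <- filter_and_call_de_mirnas(profiles, "E4/E0",
                                        rpm_min_rule = "both")
  expect_false(res_both$eligible[res_both$mirna_id == "m1"])
})

test_that("symmetric null miRNAs are never DE", {
  counts <- matrix(500, 2, 6,
                   dimnames = list(c("m1", "m2"),
                                   c("E0", "E4", "E24", "N0", "N4", "N24")))
  res <- filter_and_call_de_mirnas(mk_profiles(counts), "E4/E0")
  expect_equal(res$p, c(1, 1))
  expect_equal(res$status, c("ns", "ns"))
})

test_that("target scanning finds exact and near-complementary sites only", {
  set.seed(71)
  mirna <- random_seq(21)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(mirna, "")[[1]]), collapse = ""))
  cds <- paste0(random_seq(200), rc, random_seq(150))
  hits <- scan_targets(mirna, c(t1 = cds))
  perfect <- hits[hits$penalty == 0, ]
  expect_equal(perfect$offset, 201L)
  # three substitutions at the site push the penalty to >= 3: no hit
  sv <- strsplit(rc, "")[[1]]
  for (p in c(3, 10, 17))
    sv[p] <- setdiff(c("A", "C"), sv[p])[1]  # never a G:U partner
  cds3 <- paste0(substr(cds, 1, 200), paste(sv, collapse = ""),
                 substr(cds, 222, nchar(cds)))
  hits3 <- scan_targets(mirna, c(t1 = cds3))
  expect_false(any(hits3$offset == 201))
  expect_error(scan_targets("ACGTN", c(t1 = cds)), "length")
  expect_error(scan_targets(mirna, c(t1 = "ACGTXACGTACGTACGTACGTACGT")),
               "position 5")
})

test_that("scanner agrees with a brute-force all-offsets oracle", {
  set.seed(72)
  for (rep in 1:2) {
    mirna <- random_seq(21)
    cds_set <- setNames(vapply(1:10, function(i) random_seq(500), ""),
                        sprintf("c%02d", 1:10))
    # plant one weak site so hits exist
    site <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(mirna, "")[[1]]), collapse = ""))
    sv <- strsplit(site, "")[[1]]
    sv[5] <- setdiff(c("A", "C", "G", "T"), sv[5])[1]
    cds_set[[3]] <- paste0(substr(cds_set[[3]], 1, 100),
                           paste(sv, collapse = ""),
                           substr(cds_set[[3]], 122, 500))
    got <- scan_targets(mirna, cds_set, penalty_max = 3)
    want <- do.call(rbind, lapply(names(cds_set), function(id) {
      h <- bf_scan(mirna, cds_set[[id]], penalty_max = 3)
      if (nrow(h)) cbind(transcript_id = id, h)
    }))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$transcript_id, got$offset), ]
      want <- want[order(want$transcript_id, want$offset), ]
      expect_equal(got$transcript_id, want$transcript_id)
      expect_equal(got$offset, as.integer(want$offset))
      expect_equal(got$penalty, want$penalty)
    }
  }
  # U and T are interchangeable on input
  m <- "UGAGGUAGUAGGUUGUAUAGU"
  cds <- paste0(random_seq(50),
                chartr("ACGU", "TGCA",
                       paste(rev(strsplit(m, "")[[1]]), collapse = "")),
                random_seq(50))
  expect_equal(scan_targets(m, c(x = cds))$penalty |> min(), 0)
})

test_that("gene-level chains require tolerant DE miRNAs and opposite targets", {
  de <- rbind(
    data.frame(mirna_id = "mA", class = "known", comparison = "E4/E0",
               eligible = TRUE, rpm_sum = 100, log2fc = 2, p = 1e-5,
               status = "up"),
    data.frame(mirna_id = "mB", class = "known", comparison = "N4/N0",
               eligible = TRUE, rpm_sum = 100, log2fc = 2, p = 1e-5,
               status = "up"))
  hits <- data.frame(mirna_id = c("mA", "mA", "mB"),
                     transcript_id = c("g1", "g2", "g3"),
                     offset = 1L, penalty = 0)
  degs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     comparison = "E4/E0", log2fc = c(-3, 3, -3),
                     p = 0, fdr = 0, status = c("down", "up", "down"))
  degs <- rbind(degs, transform(degs, comparison = "N4/N0"))
  chains <- anticorrelated_pairs(de, hits, degs)
  # mA/g1: opposite -> chain; mA/g2 same direction -> none;
  # mB is DE only in the sensitive genotype -> dropped entirely
  expect_equal(chains$mirna_id, "mA")
  expect_equal(chains$gene_id, "g1")
  expect_equal(chains$level, "gene")
  # every chain is backed by a sequence-level hit
  expect_true(all(paste(chains$mirna_id, chains$gene_id) %in%
                    paste(hits$mirna_id, hits$transcript_id)))
})

test_that("protein-level chains need category IV/VI and an opposite protein", {
  de <- data.frame(mirna_id = "mA", class = "known", comparison = "E4/E0",
                   eligible = TRUE, rpm_sum = 100, log2fc = 2, p = 1e-5,
                   status = "up")
  hits <- data.frame(mirna_id = "mA", transcript_id = c("g1", "g2"),
                     offset = 1L, penalty = 0.5)
  pairs <- data.frame(
    gene_id = c("g1", "g2"), protein_id = c("p1", "p2"),
    comparison = "E4/E0", gene_log2fc = c(0, -2),
    gene_status = c("ns", "down"), protein_log2ratio = c(-1, -1),
    protein_status = c("down", "down"), category = c("IV", "I"),
    stringsAsFactors = FALSE)
  chains <- protein_level_chains(de, hits, pairs)
  # the category I triple stays at gene level, only IV qualifies here
  expect_equal(chains$protein_id, "p1")
  expect_equal(chains$level, "protein")
})

test_that("planted chains are recovered exactly at zero noise", {
  cfg <- helper_cfg_exact(seed = 81)
  sim <- simulate_multiomics(cfg)
  res <- run_pipeline(sim)
  tr <- sim$truth$chains
  got <- rbind(res$gene_chains[, c("mirna_id", "gene_id", "comparison", "level")],
               res$protein_chains[, c("mirna_id", "gene_id", "comparison", "level")])
  expect_identical(
    sort(paste(got$mirna_id, got$gene_id, got$comparison, got$level)),
    sort(paste(tr$mirna_id, tr$gene_id, tr$comparison, tr$level)))
})

test_that("no planted targets means no chains", {
  cfg <- helper_cfg_exact(frac_planted_targets = 0,
                          n_planted_protein_chains = 0, seed = 82)
  sim <- simulate_multiomics(cfg)
  res <- run_pipeline(sim)
  expect_equal(nrow(res$gene_chains), 0L)
  expect_equal(nrow(res$protein_chains), 0L)
})
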