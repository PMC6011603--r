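#!/usr/bin/env Rscript
# Stage 3: iTRAQ identification tiers and DAP calling (geometric mean
# ratio > 1.2 or < 0.833, one-sample t on log2 replicate ratios, p < 0.05).

suppressMessages(library(saltomics))

quants <- read_omics_tsv("results/inputs/proteins.tsv")
tiers <- tally_identification(quants)
cat(sprintf(paste0("identified %d proteins; %d robust (>=2 peptides, ",
                   ">=2 replicates); %d quantified; %d in all 3 replicates\n"),
            tiers[["identified"]], tiers[["robust"]],
            tiers[["quantified"]], tiers[["quantified_all3"]]))
cat(sprintf("transcript-detected fraction of the proteome: %.2f%%\n",
            overlap_percentage(
              sum(quants$gene_id %in%
                    read_omics_tsv("results/inputs/expression.tsv")$gene_id),
              nrow(quants))))

daps <- call_daps_all(quants)
write_omics_tsv(daps, "results/daps.tsv")
for (cmp in unique(daps$comparison)) {
  d <- daps[daps$comparison == cmp, ]
  cat(sprintf("%-7s: %3d DAPs (%d up, %d down) of %d quantified\n", cmp,
              sum(d$status != "ns"), sum(d$status == "up"),
              sum(d$status == "down"), nrow(d)))
}
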