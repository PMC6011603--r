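#!/usr/bin/env Rscript
# Stage 5: alternative-splicing event accounting, salt-induced AS gene
# sets, AS-DEGs and tolerance candidates ranked by tolerant-genotype
# dominance of the fold change.

suppressMessages(library(saltomics))

events <- read_omics_tsv("results/inputs/as_events.tsv")
degs <- read_omics_tsv("results/degs.tsv")

counts <- count_events(events)
cat("AS events per sample and type:\n")
print(counts$counts)
cat(sprintf("IR fraction ranges %.2f-%.2f across samples (IR-dominant)\n",
            min(counts$fractions[, "IR"]), max(counts$fractions[, "IR"])))

as_degs <- select_as_degs(events, degs)
write_omics_tsv(as_degs, "results/as_degs.tsv")
cat(sprintf("%d AS-DEGs (salt-induced AS genes that are also DEGs)\n",
            nrow(as_degs)))

cand <- rank_as_candidates(as_degs, degs)
write_omics_tsv(cand, "results/as_candidates.tsv")
cat(sprintf("%d AS tolerance candidates with |log2 E/E0| > |log2 N/N0|\n",
            nrow(cand)))
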