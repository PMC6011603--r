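#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omics study (2 genotypes x 3 time
# points; single mRNA and small-RNA library per sample, 3 iTRAQ replicates)
# and write every input table the downstream stages consume, together with
# the planted truth used for the final recovery audit.

suppressMessages(library(saltomics))

dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
dir.create("results/truth", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
print(cfg)
sim <- simulate_multiomics(cfg)

write_expression_tsv(sim$expression, "results/inputs/expression.tsv")
write_omics_tsv(sim$proteins, "results/inputs/proteins.tsv")
write_mirna_tsv(sim$mirna, "results/inputs/mirna.tsv")
write_omics_tsv(sim$as_events, "results/inputs/as_events.tsv")
write_fasta(sim$mirna_seqs, "results/inputs/mirna.fa")
write_fasta(sim$cds_seqs, "results/inputs/cds.fa")
write_omics_tsv(sim$ortholog_map, "results/inputs/ortholog_map.tsv")
write_omics_tsv(sim$ppi_edges, "results/inputs/ppi_edges.tsv")

write_omics_tsv(sim$truth$genes, "results/truth/genes.tsv")
write_omics_tsv(sim$truth$proteins, "results/truth/proteins.tsv")
write_omics_tsv(sim$truth$mirnas, "results/truth/mirnas.tsv")
write_omics_tsv(sim$truth$chains, "results/truth/chains.tsv")
write_omics_tsv(true_candidates(sim$truth), "results/truth/candidates.tsv")

cat(sprintf("simulated %d genes, %d proteins, %d miRNAs, %d AS events\n",
            length(sim$expression$gene_id), nrow(sim$proteins),
            length(sim$mirna$mirna_id), nrow(sim$as_events)))
cat(sprintf("planted: %d rule hits, %d miRNA-target chains, 2 PPI hubs\n",
            nrow(sim$truth$rule_hits), nrow(sim$truth$chains)))
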