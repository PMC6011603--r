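#!/usr/bin/env Rscript
# Stage 6: miRNA differential expression (RPM filters + exact test),
# complementarity scan of DE miRNAs against the CDS library, and
# anticorrelated miRNA -> mRNA (-> protein) chains.

suppressMessages(library(saltomics))

profiles <- read_mirna_tsv("results/inputs/mirna.tsv")
mirna_seqs <- read_fasta("results/inputs/mirna.fa")
cds_seqs <- read_fasta("results/inputs/cds.fa")
degs <- read_omics_tsv("results/degs.tsv")
pairs <- read_omics_tsv("results/pairs.tsv")

de_mirnas <- do.call(rbind, lapply(
  c("E4/E0", "E24/E0", "N4/N0", "N24/N0"), function(cmp)
    filter_and_call_de_mirnas(profiles, cmp)))
write_omics_tsv(de_mirnas, "results/de_mirnas.tsv")
de_ids <- unique(de_mirnas$mirna_id[de_mirnas$status != "ns"])
cat(sprintf("%d of %d miRNAs DE in at least one comparison (%d eligible)\n",
            length(de_ids), length(profiles$mirna_id),
            length(unique(de_mirnas$mirna_id[de_mirnas$eligible]))))

hits <- scan_targets_all(mirna_seqs[de_ids], cds_seqs)
write_omics_tsv(hits, "results/target_hits.tsv")
cat(sprintf("%d target sites below the 3-mismatch penalty for %d DE miRNAs\n",
            nrow(hits), length(unique(hits$mirna_id))))

gene_chains <- anticorrelated_pairs(de_mirnas, hits, degs)
protein_chains <- protein_level_chains(de_mirnas, hits, pairs)
write_omics_tsv(gene_chains, "results/gene_chains.tsv")
write_omics_tsv(protein_chains, "results/protein_chains.tsv")
cat(sprintf(paste0("%d gene-level anticorrelated chains (transcript ",
                   "cleavage) and %d protein-level chains (candidate ",
                   "translational repression)\n"),
            nrow(gene_chains), nrow(protein_chains)))
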