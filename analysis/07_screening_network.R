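#!/usr/bin/env Rscript
# Stage 7: stringent candidate screening (rules i-v plus the
# proteome-only screen), AS/osmotic annotation, PPI network construction
# and hub extraction, ending with a recovery audit against the planted
# truth of stage 1.

suppressMessages(library(saltomics))

degs <- read_omics_tsv("results/degs.tsv")
daps <- read_omics_tsv("results/daps.tsv")
pairs <- read_omics_tsv("results/pairs.tsv")
as_degs <- read_omics_tsv("results/as_degs.tsv")
quants <- read_omics_tsv("results/inputs/proteins.tsv")
map <- unique(quants[, c("protein_id", "gene_id")])

candidates <- do.call(rbind, lapply(c(4, 24), function(t)
  rbind(apply_rules(pairs, degs, daps, t),
        protein_only_screen(pairs, daps, t))))
# synthetic osmotic list: the tolerant-dominant DE genes stand in for a
# GO "response to osmotic stress" homology table
osmotic <- unique(degs$gene_id[degs$comparison == "E4/E0" &
                                 degs$status != "ns"])[1:50]
candidates <- annotate_candidates(candidates, as_degs, osmotic, map)
write_omics_tsv(candidates, "results/candidates.tsv")
print(table(candidates$rule, candidates$time))
cat(sprintf("%d candidates flagged AS, %d flagged osmotic\n",
            sum(candidates$as_flag), sum(candidates$osmotic_flag)))

ortholog_map <- read_omics_tsv("results/inputs/ortholog_map.tsv")
edges <- read_omics_tsv("results/inputs/ppi_edges.tsv")
network <- build_network(unique(candidates$id), ortholog_map, edges)
write_sif(network, "results/network.sif")
hubs <- find_hubs(network)
cat(sprintf("network: %d nodes, %d edges, %d components\n",
            igraph::vcount(network), igraph::ecount(network),
            hubs$n_components))
cat("top hubs:", paste(hubs$hubs$node, "deg", hubs$hubs$degree,
                       collapse = "; "), "\n")

# recovery audit against the planted truth
truth_cand <- read_omics_tsv("results/truth/candidates.tsv")
rec <- recovery(paste(candidates$id[candidates$time == 4],
                      candidates$rule[candidates$time == 4]),
                paste(truth_cand$id, truth_cand$rule))
cat(sprintf("screening recovery vs planted truth (4 h): sensitivity %.2f, FDR %.2f\n",
            rec[["sensitivity"]], rec[["fdr"]]))
truth_chains <- read_omics_tsv("results/truth/chains.tsv")
gene_chains <- read_omics_tsv("results/gene_chains.tsv")
protein_chains <- read_omics_tsv("results/protein_chains.tsv")
got <- rbind(gene_chains[, c("mirna_id", "gene_id", "comparison")],
             protein_chains[, c("mirna_id", "gene_id", "comparison")])
rec_c <- recovery(paste(got$mirna_id, got$gene_id, got$comparison),
                  paste(truth_chains$mirna_id, truth_chains$gene_id,
                        truth_chains$comparison))
cat(sprintf("chain recovery: sensitivity %.2f, FDR %.2f\n",
            rec_c[["sensitivity"]], rec_c[["fdr"]]))
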