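#!/usr/bin/env Rscript
# Stage 2: RPKM normalisation and replicate-free DEG calling with the
# exact two-library binomial test, |log2fc| >= 1 and BH FDR < 0.001, for
# the four treated/control comparisons.

suppressMessages(library(saltomics))

expr <- read_expression_tsv("results/inputs/expression.tsv")
degs <- call_degs_all(expr)
write_omics_tsv(degs, "results/degs.tsv")

for (cmp in unique(degs$comparison)) {
  d <- degs[degs$comparison == cmp, ]
  cat(sprintf("%-7s: %4d DEGs (%d up, %d down) of %d genes\n", cmp,
              sum(d$status != "ns"), sum(d$status == "up"),
              sum(d$status == "down"), nrow(d)))
}
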