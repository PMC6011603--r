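# Fixed-format table and sequence IO. Missing values are written as
# empty cells; every writer has a reader that restores the table
# (roundtrip identity up to floating-point printing precision).

#' Write / read a pipeline TSV
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_omics_tsv` returns the data.frame.
#' @export
write_omics_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read the expression matrix
#'
#' Columns: gene_id, length, then one count column per sample
#' (E0/E4/E24/N0/N4/N24).
#'
#' @param expr expression list (gene_id, lengths, counts).
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_id, length = expr$lengths,
                   expr$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_omics_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_omics_tsv(path)
  counts <- as.matrix(df[, SAMPLES])
  rownames(counts) <- df$gene_id
  list(gene_id = df$gene_id, lengths = df$length, counts = counts)
}

#' Write / read miRNA count profiles
#'
#' @param profiles list (mirna_id, class, counts).
#' @param path file path.
#' @export
write_mirna_tsv <- function(profiles, path) {
  df <- data.frame(mirna_id = profiles$mirna_id, class = profiles$class,
                   profiles$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_omics_tsv(df, path)
}

#' @rdname write_mirna_tsv
#' @export
read_mirna_tsv <- function(path) {
  df <- read_omics_tsv(path)
  counts <- as.matrix(df[, SAMPLES])
  rownames(counts) <- df$mirna_id
  list(mirna_id = df$mirna_id, class = df$class, counts = counts)
}

#' Write / read FASTA sequence sets
#'
#' @param seqs named character vector (DNA alphabet; U accepted on read).
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a network in SIF format
#'
#' One `node_a pp node_b` line per edge.
#'
#' @param graph igraph graph.
#' @param path file path.
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  writeLines(if (nrow(el)) paste(el[, 1L], "pp", el[, 2L]) else character(),
             path)
  invisible(path)
}
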