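# Independent brute-force oracles, deliberately naive and separate from
# the package implementations they check.

# doubled-tail exact binomial by direct density summation
bf_two_library <- function(x, y, N1, N2) {
  n <- x + y
  p0 <- N1 / (N1 + N2)
  dens <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k),
                 numeric(1))
  lower <- sum(dens[seq_len(x + 1L)])
  upper <- sum(dens[seq(x + 1L, n + 1L)])
  min(1, 2 * min(lower, upper))
}

# textbook Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# upper-tail hypergeometric by direct combinatorial evaluation
bf_hyper_upper <- function(overlap, term_size, bg_size, fg_size) {
  ks <- overlap:min(term_size, fg_size)
  sum(choose(term_size, ks) * choose(bg_size - term_size, fg_size - ks)) /
    choose(bg_size, fg_size)
}

# position-by-position duplex scoring over every offset, with explicit
# pair classification
bf_scan <- function(mirna, cds, penalty_max = 3, wobble = 0.5) {
  pair_pen <- function(m, t) {
    wc <- (m == "A" && t == "T") || (m == "T" && t == "A") ||
      (m == "G" && t == "C") || (m == "C" && t == "G")
    if (wc) return(0)
    if ((m == "G" && t == "T") || (m == "T" && t == "G")) return(wobble)
    1
  }
  m <- rev(strsplit(toupper(chartr("U", "T", mirna)), "")[[1]])
  s <- strsplit(toupper(chartr("U", "T", cds)), "")[[1]]
  L <- length(m)
  hits <- list()
  for (off in seq_len(length(s) - L + 1L)) {
    pen <- 0
    for (j in seq_len(L)) pen <- pen + pair_pen(m[j], s[off + j - 1L])
    if (pen < penalty_max)
      hits[[length(hits) + 1L]] <- data.frame(offset = off, penalty = pen)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), penalty = numeric()))
  do.call(rbind, hits)
}

# small, fast generator configuration shared by recovery tests
helper_cfg <- function(...) {
  args <- utils::modifyList(list(n_genes = 900, n_proteins = 300,
                                 n_mirnas = 60, mrna_library_size = 8e5,
                                 mirna_library_size = 2e5),
                            list(...))
  do.call(sim_config, args)
}

# deterministic generator limit used for exact-recovery checks: no count
# noise and numerically negligible replicate noise (a literally constant
# replicate vector has no within-protein variance, so its location test
# is undefined by design)
helper_cfg_exact <- function(...) {
  helper_cfg(protein_cv = 1e-3, count_model = "none", ...)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
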