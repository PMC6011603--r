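# Candidate PPI network from a user-supplied ortholog map and scored
# edge table, plus generic hypergeometric term enrichment.

#' Build the candidate interaction network
#'
#' Maps candidate ids to ortholog ids, keeps edges with
#' combined_score > score_min that touch at least one candidate ortholog
#' (candidates plus their direct interactors), collapses duplicate edges
#' keeping the maximum score, and drops self-loops.
#'
#' @param candidates character vector of candidate gene/protein ids.
#' @param ortholog_map data.frame with columns `id`, `ortholog`;
#'   candidates without a mapping are dropped (with a message).
#' @param edges data.frame with columns `node_a`, `node_b`,
#'   `combined_score` (integer >= 0).
#' @param score_min keep edges with combined_score strictly greater than
#'   this (default 160).
#' @return undirected `igraph` graph; candidate orthologs carry vertex
#'   attribute `candidate = TRUE`.
#' @export
build_network <- function(candidates, ortholog_map, edges, score_min = 160) {
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns ", paste(need, collapse = ", "))
  bad <- which(is.na(edges$node_a) | is.na(edges$node_b) |
                 is.na(edges$combined_score) | edges$combined_score < 0)
  if (length(bad)) stop("malformed edge row at line ", bad[1L])
  m <- match(candidates, ortholog_map$id)
  if (anyNA(m))
    message(sum(is.na(m)), " candidate(s) without an ortholog mapping dropped")
  cand_orth <- unique(ortholog_map$ortholog[m[!is.na(m)]])
  e <- edges[edges$combined_score > score_min &
               edges$node_a != edges$node_b, , drop = FALSE]
  e <- e[e$node_a %in% cand_orth | e$node_b %in% cand_orth, , drop = FALSE]
  if (nrow(e) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  a <- pmin(e$node_a, e$node_b)
  b <- pmax(e$node_a, e$node_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(e$combined_score, key, max)
  uk <- strsplit(names(score), "\r", fixed = TRUE)
  el <- data.frame(from = vapply(uk, `[`, "", 1L),
                   to = vapply(uk, `[`, "", 2L),
                   combined_score = as.numeric(score),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::V(g)$candidate <- igraph::V(g)$name %in% cand_orth
  g
}

#' Hubs and connected components of the candidate network
#'
#' Nodes ranked by degree (ties broken by node id); the top-k are the
#' hubs, the operational stand-in for the network's main cluster centres.
#'
#' @param graph `igraph` graph from [build_network()].
#' @param k number of hubs to return (default 2).
#' @return list with `hubs` (data.frame node, degree), `n_components` and
#'   `component_sizes`.
#' @export
find_hubs <- function(graph, k = 2) {
  if (igraph::vcount(graph) == 0L)
    return(list(hubs = data.frame(node = character(), degree = integer(),
                                  stringsAsFactors = FALSE),
                n_components = 0L, component_sizes = integer()))
  deg <- igraph::degree(graph)
  ord <- order(-deg, names(deg))
  top <- ord[seq_len(min(k, length(ord)))]
  comp <- igraph::components(graph)
  list(hubs = data.frame(node = names(deg)[top],
                         degree = as.integer(deg[top]),
                         stringsAsFactors = FALSE),
       n_components = comp$no,
       component_sizes = as.integer(sort(comp$csize, decreasing = TRUE)))
}

#' Hypergeometric term over-representation with BH correction
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when sampling |foreground| ids from the
#' background without replacement; q-values by Benjamini-Hochberg across
#' terms.
#'
#' @param foreground character vector of ids, subset of `background`.
#' @param background character vector of ids (the tested universe).
#' @param annotation data.frame with columns `id`, `term`.
#' @return data.frame with term, term_size (in background), overlap, p, q,
#'   sorted by p.
#' @export
enrich_terms <- function(foreground, background, annotation) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  ann <- annotation[annotation$id %in% background, , drop = FALSE]
  terms <- unique(ann$term)
  n_bg <- length(background)
  n_fg <- length(foreground)
  res <- do.call(rbind, lapply(terms, function(tm) {
    ids <- unique(ann$id[ann$term == tm])
    k <- sum(foreground %in% ids)
    data.frame(term = tm, term_size = length(ids), overlap = k,
               p = stats::phyper(k - 1, length(ids), n_bg - length(ids),
                                 n_fg, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(term = character(), term_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}
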