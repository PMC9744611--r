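#' Hypergeometric over-representation analysis
#'
#' Tests a gene list against each gene set with the upper-tail
#' hypergeometric probability `P(X >= k)` for `k` hits in a set of size `K`
#' (after restriction to the universe), a hit list of size `n`, and a
#' universe of size `N`.  P-values are BH-adjusted across all tested sets;
#' sets with `fdr < fdr_cutoff` are flagged significant.  The universe
#' should be the genes actually measured in the cohort under test.
#'
#' @param hits character vector of genes of interest; genes outside the
#'   universe are dropped with a message.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector of all scorable genes.
#' @param fdr_cutoff significance cutoff on the adjusted p-value
#'   (default 0.2).
#' @param min_set_size sets smaller than this after restriction to the
#'   universe are skipped (default 3).
#' @return data.frame `set`, `k`, `K`, `n`, `N`, `p`, `fdr`, `significant`,
#'   sorted by p.
#' @export
hypergeom_ora <- function(hits, sets, universe, fdr_cutoff = 0.2,
                          min_set_size = 3L) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_("empty universe")
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    message(sprintf("hypergeom_ora: dropping %d hit(s) outside the universe",
                    length(outside)))
    hits <- intersect(hits, universe)
  }
  if (length(hits) == 0L) stop_("empty hit list (after universe restriction)")
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K < min_set_size) {
      message(sprintf("hypergeom_ora: skipping set '%s' (%d gene(s) in universe)",
                      nm, K))
      return(NULL)
    }
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop_("no testable gene sets")
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub genes by connectivity degree
#'
#' Cleans an interaction edge list (self-loops removed, duplicate edges
#' collapsed keeping the maximum confidence), drops edges below the
#' confidence threshold, and ranks the remaining genes by degree,
#' descending, ties broken by gene symbol ascending.
#'
#' @param edges data.frame with `gene1`, `gene2`, `confidence` columns (see
#'   [read_edge_list()]).
#' @param confidence minimum edge confidence retained (default 0.7).
#' @param top_k number of hub genes to return (default 50; fewer if the
#'   filtered graph is smaller).
#' @return data.frame `gene`, `degree`, ranked.
#' @export
hub_genes_by_degree <- function(edges, confidence = 0.7, top_k = 50L) {
  stopifnot(all(c("gene1", "gene2", "confidence") %in% names(edges)))
  # undirected canonical form, drop self-loops, collapse duplicates (max conf)
  a <- pmin(edges$gene1, edges$gene2)
  b <- pmax(edges$gene1, edges$gene2)
  keep <- a != b
  el <- data.frame(a = a[keep], b = b[keep],
                   confidence = edges$confidence[keep],
                   stringsAsFactors = FALSE)
  key <- paste(el$a, el$b, sep = "\r")
  conf <- tapply(el$confidence, key, max)
  el <- el[!duplicated(key), , drop = FALSE]
  el$confidence <- as.vector(conf[paste(el$a, el$b, sep = "\r")])
  el <- el[el$confidence >= confidence, , drop = FALSE]
  if (nrow(el) == 0L) stop_("no edges survive the confidence filter")
  g <- igraph::graph_from_data_frame(el[, c("a", "b")], directed = FALSE)
  deg <- igraph::degree(g)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
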