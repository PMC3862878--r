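# Hypergeometric over-representation of term sets in a query gene set.

#' Hypergeometric term-set enrichment
#'
#' One-sided over-representation test per term: with a universe of N
#' genes of which K belong to the term and a query of n genes with k in
#' the term, p = P(X >= k), X ~ Hypergeometric(N, K, n). Term sets are
#' intersected with the universe before testing; terms with no overlap
#' are reported with p = 1. BH adjustment is applied across all tested
#' terms.
#'
#' @param query_set character vector of query genes (must lie in
#'   `universe`).
#' @param term_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe character vector defining the sampling frame,
#'   typically all expressed genes.
#' @return data frame `term, K, n, k, N, p, q`, ordered by p.
#' @export
enrich <- function(query_set, term_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("enrichment universe is empty")
  query_set <- unique(query_set)
  if (any(!query_set %in% universe))
    stop("query genes outside the universe")
  N <- length(universe)
  n <- length(query_set)
  rows <- lapply(names(term_sets), function(term) {
    tg <- intersect(term_sets[[term]], universe)
    K <- length(tg)
    k <- length(intersect(tg, query_set))
    p <- if (k == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, K = K, n = n, k = k, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), K = integer(), n = integer(),
                      k = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$term, method = "radix"), , drop = FALSE]
}
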