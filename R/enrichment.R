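# Hypergeometric over-representation of the DCG list in pathway gene sets.

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes
#' are drawn without replacement from a universe of `N` genes of which
#' `K` are annotated:
#' `p = sum_{x = k}^{min(K, n)} C(K, x) C(N - K, n - x) / C(N, n)`.
#' Evaluated via `stats::phyper`, which works in log space internally.
#'
#' @param k Observed overlap (>= 0).
#' @param K Annotated genes in the universe.
#' @param n Genes drawn (the query list size).
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation of a DCG list
#'
#' Tests each gene set for over-representation of the query (DCG) list
#' with the hypergeometric upper tail.  The universe is the set of genes
#' actually measured (the expression dataset's genes); sets and the
#' query are intersected with it first and empty sets dropped.  No
#' multiple-testing correction is applied across sets; `significant`
#' means raw `p < alpha` (strict).
#'
#' @param dcg_genes Character vector of query gene ids.
#' @param gene_sets A `GeneSetCollection` from [read_gmt()].
#' @param universe Character vector of measured gene ids.
#' @param alpha Significance cutoff on the raw p-value (default 0.05).
#' @return Data frame with columns `set_name`, `count` (query genes in
#'   the set), `size` (set genes in the universe), `p`, `significant`,
#'   sorted by ascending `p` with ties broken by `set_name`.
#' @export
enrich_gene_sets <- function(dcg_genes, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- intersect(unique(dcg_genes), universe)
  if (!length(query))
    stop("no query (DCG) genes in the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets$sets), function(nm) {
    set <- intersect(gene_sets$sets[[nm]], universe)
    if (!length(set)) return(NULL)
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(set_name = nm, count = k, size = K,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), count = integer(),
                      size = integer(), p = numeric())
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
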