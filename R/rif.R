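# Regulatory impact factor: per-TF score from target condition means and
# the change in TF-target coexpression between conditions.

#' Per-condition mean expression of a gene
#'
#' @param dataset An [ExpressionDataset].
#' @param gene Gene id.
#' @return Numeric `c(e1, e2)`: arithmetic means over the samples of
#'   conditions 1 and 2.
#' @export
condition_means <- function(dataset, gene) {
  if (!gene %in% rownames(dataset$values))
    stop("gene '", gene, "' not in dataset")
  x <- dataset$values[gene, ]
  c(e1 = mean(x[dataset$condition == 1L]),
    e2 = mean(x[dataset$condition == 2L]))
}

#' Regulatory impact factor of one TF
#'
#' For a TF i with `n_de` targets j, condition-wise target means
#' `e1_j`, `e2_j` and TF-target correlations `r1_ij`, `r2_ij`:
#' \deqn{RIF_i = \frac{1}{n_{de}} \sum_j \left[(e1_j r1_{ij})^2 -
#'   (e2_j r2_{ij})^2\right]}
#' The score is signed: it is exactly antisymmetric under swapping the
#' two conditions, zero when the conditions are identical, and scales as
#' `c^2` when all expression values are scaled by `c`.
#'
#' @param e1,e2 Per-target mean expression in conditions 1 and 2.
#' @param r1,r2 Per-target TF correlations in conditions 1 and 2, each
#'   in `[-1, 1]`.
#' @return The RIF value (finite real).
#' @export
rif_score <- function(e1, e2, r1, r2) {
  n_de <- length(e1)
  if (n_de < 1L) stop("target set is empty (n_de = 0)")
  if (length(e2) != n_de || length(r1) != n_de || length(r2) != n_de)
    stop("e1, e2, r1, r2 must have equal length")
  if (any(!is.finite(c(e1, e2, r1, r2))))
    stop("non-finite RIF inputs")
  sum((e1 * r1)^2 - (e2 * r2)^2) / n_de
}

#' Rank transcription factors by |RIF|
#'
#' For every TF of the regulatory network that is present in the
#' expression matrix, takes as target set its DCG targets measured on
#' the array (mode `"network-dcg"`), or all DCGs except the TF itself
#' (mode `"all-dcg"`), computes the per-condition target means and
#' TF-target Pearson correlations, and scores the TF with [rif_score()].
#' TFs with no eligible target are omitted with a warning.  Ranking is
#' by descending `|RIF|`; ties break by TF name ascending.
#'
#' @param dataset An [ExpressionDataset].
#' @param network A [build_network()] result.
#' @param dcgs Character vector of DCG gene ids.
#' @param targets Target-set mode, `"network-dcg"` (default) or
#'   `"all-dcg"`.
#' @return Data frame `tf`, `n_de`, `rif`, `abs_rank`.
#' @export
rank_tfs <- function(dataset, network, dcgs,
                     targets = c("network-dcg", "all-dcg")) {
  targets <- match.arg(targets)
  genes <- rownames(dataset$values)
  tfs <- sort(unique(network$edges$tf))
  tfs <- tfs[tfs %in% genes]
  x1 <- condition_matrix(dataset, 1L)   # samples x genes
  x2 <- condition_matrix(dataset, 2L)
  e1 <- colMeans(x1)
  e2 <- colMeans(x2)
  scores <- lapply(tfs, function(tf) {
    tset <- if (targets == "network-dcg") {
      intersect(network$edges$target[network$edges$tf == tf &
                                       network$edges$target_is_dcg], genes)
    } else {
      setdiff(intersect(dcgs, genes), tf)
    }
    tset <- setdiff(tset, tf)
    if (!length(tset)) return(NULL)
    r1 <- as.numeric(suppressWarnings(cor(x1[, tf], x1[, tset])))
    r2 <- as.numeric(suppressWarnings(cor(x2[, tf], x2[, tset])))
    r1[is.na(r1)] <- 0   # zero-variance pairs carry no coexpression signal
    r2[is.na(r2)] <- 0
    data.frame(tf = tf, n_de = length(tset),
               rif = rif_score(e1[tset], e2[tset], r1, r2),
               stringsAsFactors = FALSE)
  })
  dropped <- tfs[vapply(scores, is.null, logical(1L))]
  if (length(dropped))
    warning(length(dropped), " TF(s) with no eligible target omitted: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  out <- do.call(rbind, scores)
  if (is.null(out) || !nrow(out)) stop("no rankable TF")
  out <- out[order(-abs(out$rif), out$tf), , drop = FALSE]
  out$abs_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
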