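# Differential coexpression: per-condition correlation matrices, the
# half-thresholding link filter, the root-mean-square correlation-change
# gene statistic, permutation p-values and BH-FDR selection.

# Pearson correlation with zero-variance columns mapped to r = 0 (not NA)
# so downstream sums stay finite.  `x` is samples x genes.
safe_cor <- function(x) {
  sds <- apply(x, 2L, sd)
  zero <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(x))
  if (any(zero)) {
    r[zero, ] <- 0
    r[, zero] <- 0
  }
  diag(r) <- 1
  attr(r, "zero_variance") <- colnames(x)[zero]
  r
}

#' Per-condition gene-gene correlation matrices
#'
#' Computes the Pearson correlation matrix of all genes within each
#' condition.  Zero-variance genes yield correlation 0 against every
#' other gene (with a warning naming them) rather than `NA`.
#'
#' @param dataset An [ExpressionDataset].
#' @return List with symmetric matrices `r1` and `r2` (unit diagonal,
#'   entries in `[-1, 1]`).
#' @export
condition_correlations <- function(dataset) {
  out <- lapply(1:2, function(k) safe_cor(condition_matrix(dataset, k)))
  zv <- unique(c(attr(out[[1L]], "zero_variance"),
                 attr(out[[2L]], "zero_variance")))
  if (length(zv))
    warning("zero-variance gene(s), correlations set to 0: ",
            paste(head(zv, 5L), collapse = ", "),
            if (length(zv) > 5L) ", ...")
  list(r1 = out[[1L]], r2 = out[[2L]])
}

#' Half-thresholding link filter
#'
#' A gene pair (link) is retained when its correlation magnitude in at
#' least one condition reaches the `(1 - q)` quantile of the pooled
#' `|r|` distribution of all links in both conditions (ties retained,
#' i.e. `>=`).  `q = 1` retains every link.
#'
#' @param r1,r2 Correlation matrices from [condition_correlations()].
#' @param q Fraction of links to aim to keep, in `(0, 1]`.
#' @return Symmetric logical matrix; `TRUE` marks retained links
#'   (diagonal `FALSE`).  The threshold used is attached as attribute
#'   `"threshold"`.
#' @export
filter_links <- function(r1, r2, q = 0.25) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("'q' must lie in (0, 1]")
  ut <- upper.tri(r1)
  pooled <- c(abs(r1[ut]), abs(r2[ut]))
  thr <- as.numeric(quantile(pooled, probs = 1 - q, names = FALSE))
  retained <- pmax(abs(r1), abs(r2)) >= thr
  diag(retained) <- FALSE
  attr(retained, "threshold") <- thr
  retained
}

#' Gene-level differential coexpression statistic
#'
#' For each gene, the root-mean-square change in correlation over its
#' retained links: `dC_g = sqrt( sum_links (r1 - r2)^2 / n_links )`,
#' which lies in `[0, 2]`.  Genes with no retained link get `dC = 0`.
#'
#' @inheritParams filter_links
#' @param retained Logical link matrix from [filter_links()].
#' @return Named numeric vector of `dC` values.
#' @export
gene_dc_statistics <- function(r1, r2, retained) {
  d2 <- (r1 - r2)^2
  n_links <- rowSums(retained)
  dC <- sqrt(ifelse(n_links > 0, rowSums(d2 * retained) / n_links, 0))
  setNames(as.numeric(dC), rownames(r1))
}

# one full pass: correlations -> filter -> per-gene dC
dc_statistic_pass <- function(values, condition, q) {
  r1 <- safe_cor(t(values[, condition == 1L, drop = FALSE]))
  r2 <- safe_cor(t(values[, condition == 2L, drop = FALSE]))
  retained <- filter_links(r1, r2, q)
  list(r1 = r1, r2 = r2, retained = retained,
       dC = gene_dc_statistics(r1, r2, retained))
}

#' Permutation test for differentially coexpressed genes
#'
#' Permutes the condition labels across all samples `n_perm` times and
#' recomputes the full statistic (correlations, link filter and `dC`)
#' per permutation, giving each gene its own permutation null.  The
#' add-one estimator `p_g = (1 + #{dC* >= dC_g}) / (1 + n_perm)` avoids
#' p = 0, so `p` lies in `[1 / (1 + n_perm), 1]`.
#'
#' @param dataset An [ExpressionDataset].
#' @param q Link-filter fraction, see [filter_links()].
#' @param n_perm Number of label permutations (values below 100 give a
#'   coarse p-value grid and trigger a warning).
#' @param seed Integer seed making the permutations reproducible.
#' @return A list: `table` (data frame `gene`, `dC`, `p`), `r1`, `r2`,
#'   `retained`.
#' @export
dcg_permutation_test <- function(dataset, q = 0.25, n_perm = 1000L,
                                 seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (n_perm < 100L)
    warning("n_perm = ", n_perm, " gives a minimum attainable p-value of ",
            signif(1 / (1 + n_perm), 3L),
            "; too coarse for FDR control at usual cutoffs")
  obs <- dc_statistic_pass(dataset$values, dataset$condition, q)
  set.seed(as.integer(seed))
  exceed <- integer(length(obs$dC))
  for (b in seq_len(n_perm)) {
    perm <- sample(dataset$condition)
    dC_star <- dc_statistic_pass(dataset$values, perm, q)$dC
    exceed <- exceed + (dC_star >= obs$dC)
  }
  p <- (1 + exceed) / (1 + n_perm)
  list(table = data.frame(gene = rownames(dataset$values),
                          dC = as.numeric(obs$dC), p = as.numeric(p),
                          stringsAsFactors = FALSE),
       r1 = obs$r1, r2 = obs$r2, retained = obs$retained)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `fdr_i = min over k with p_(k) >= p_i of p_(k) * m / k`, clipped at 1.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must be numeric in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differentially coexpressed genes and links
#'
#' Applies BH-FDR to the permutation p-values and flags genes with
#' `fdr < fdr_cutoff` (strict) as DCGs.  DC-links are the retained links
#' whose *both* endpoints are DCGs.
#'
#' @param test Result of [dcg_permutation_test()].
#' @param fdr_cutoff FDR threshold (default 0.25).
#' @return A list: `dcg_table` (data frame `gene`, `dC`, `p`, `fdr`,
#'   `is_dcg`), `dc_links` (data frame `gene_a`, `gene_b`, `r1`, `r2`,
#'   `d` with `gene_a < gene_b`), `dcgs` (character vector).
#' @export
select_dcgs <- function(test, fdr_cutoff = 0.25) {
  tab <- test$table
  tab$fdr <- bh_adjust(tab$p)
  tab$is_dcg <- tab$fdr < fdr_cutoff
  dcgs <- tab$gene[tab$is_dcg]
  genes <- rownames(test$r1)
  keep <- test$retained & upper.tri(test$retained) &
    outer(genes %in% dcgs, genes %in% dcgs, `&`)
  idx <- which(keep, arr.ind = TRUE)
  dc_links <- data.frame(gene_a = genes[idx[, 1L]],
                         gene_b = genes[idx[, 2L]],
                         r1 = test$r1[idx], r2 = test$r2[idx],
                         stringsAsFactors = FALSE)
  swap <- dc_links$gene_a > dc_links$gene_b
  if (any(swap)) {
    tmp <- dc_links$gene_a[swap]
    dc_links$gene_a[swap] <- dc_links$gene_b[swap]
    dc_links$gene_b[swap] <- tmp
  }
  dc_links$d <- abs(dc_links$r1 - dc_links$r2)
  dc_links <- dc_links[order(dc_links$gene_a, dc_links$gene_b), ,
                       drop = FALSE]
  rownames(dc_links) <- NULL
  list(dcg_table = tab, dc_links = dc_links, dcgs = dcgs)
}

#' Run the full DCG stage
#'
#' Convenience wrapper: permutation test, BH adjustment and selection in
#' one call.
#'
#' @inheritParams dcg_permutation_test
#' @inheritParams select_dcgs
#' @return As [select_dcgs()], plus elements `r1`, `r2`, `retained`.
#' @export
run_dcg <- function(dataset, q = 0.25, n_perm = 1000L, seed = 1L,
                    fdr_cutoff = 0.25) {
  test <- dcg_permutation_test(dataset, q = q, n_perm = n_perm, seed = seed)
  out <- select_dcgs(test, fdr_cutoff = fdr_cutoff)
  out$r1 <- test$r1
  out$r2 <- test$r2
  out$retained <- test$retained
  out
}
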