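# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files these helpers have just written.

# small expression dataset from an explicit matrix
toy_dataset <- function(values, n1 = NULL) {
  if (is.null(n1)) n1 <- ncol(values) %/% 2L
  cond <- setNames(rep(1:2, c(n1, ncol(values) - n1)), colnames(values))
  ExpressionDataset(values, cond)
}

# random dataset with named genes/samples, no structure
random_dataset <- function(n_genes, n_per_cond, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_cond, mean = 8, sd = 2),
              n_genes, 2 * n_per_cond,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(2 * n_per_cond))))
  toy_dataset(m)
}

# write an expression TSV + labels TSV; returns the two paths
write_toy_files <- function(values, labels, dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  header <- paste(c("gene_id", colnames(values)), collapse = "\t")
  rows <- apply(cbind(rownames(values), values), 1L, paste, collapse = "\t")
  writeLines(c(header, rows), mp)
  writeLines(c("sample_id\tcondition",
               paste(names(labels), labels, sep = "\t")), lp)
  c(matrix = mp, labels = lp)
}

# brute-force BH step-up: explicit min-over-suffix definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(k) ps[k] * m / k, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% annotated))
  mean(hits >= k)
}
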