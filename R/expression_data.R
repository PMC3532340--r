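#' Construct a two-condition expression dataset
#'
#' Container for a gene-by-sample matrix of (log-scale) expression values
#' together with a two-level condition assignment of the samples.  All
#' downstream statistics (per-condition correlations, condition means)
#' are computed from this object.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).  All entries finite.
#' @param condition Named integer vector over the sample ids, values in
#'   `{1, 2}`, naming which condition each sample belongs to.
#' @param condition_names Character vector of length 2: the external
#'   labels for conditions 1 and 2 (used when writing label files).
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `condition` and `condition_names`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' ds <- ExpressionDataset(m, setNames(c(1L, 1L, 2L, 2L), colnames(m)))
#' n_samples(ds, 1)
ExpressionDataset <- function(values, condition,
                              condition_names = c("1", "2")) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in 'values'")
  if (any(!nzchar(rownames(values))))
    stop("empty gene id in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values'")
  if (!all(is.finite(values)))
    stop("non-finite expression values")
  condition <- condition[colnames(values)]
  if (any(is.na(condition)))
    stop("condition assignment missing for sample(s): ",
         paste(colnames(values)[is.na(condition)], collapse = ", "))
  condition <- as.integer(condition)
  names(condition) <- colnames(values)
  if (!all(condition %in% 1:2))
    stop("'condition' values must be 1 or 2")
  for (k in 1:2) {
    if (sum(condition == k) < 3L)
      stop("condition ", k, " (", condition_names[k], ") has fewer than 3 ",
           "samples; Pearson correlation needs at least 3 points")
  }
  structure(list(values = values, condition = condition,
                 condition_names = as.character(condition_names)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  for (k in 1:2)
    cat("  condition ", k, " ('", x$condition_names[k], "'): ",
        sum(x$condition == k), " samples\n", sep = "")
  invisible(x)
}

#' Number of samples in one condition
#' @param dataset An [ExpressionDataset].
#' @param k Condition index, 1 or 2.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset, k) sum(dataset$condition == k)

#' Samples-by-genes submatrix of one condition
#' @inheritParams n_samples
#' @return Numeric matrix with samples in rows and genes in columns.
#' @export
condition_matrix <- function(dataset, k) {
  t(dataset$values[, dataset$condition == k, drop = FALSE])
}

#' Read an expression matrix and its condition labels
#'
#' The matrix file is TSV with a header row (first field `gene_id`,
#' remaining fields sample ids) and one gene per row.  The labels file is
#' TSV with two columns, sample id and condition name (a `sample_id
#' <TAB> condition` header line is accepted).  Exactly two condition
#' names must be present; they are mapped to conditions 1 and 2 in
#' lexicographic order unless `condition_1` overrides which label is
#' condition 1.  Duplicate gene ids are collapsed by averaging their
#' rows.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the sample-label TSV.
#' @param condition_1 Optional condition name to force as condition 1
#'   (RIF is antisymmetric in the condition orientation).
#' @return An [ExpressionDataset].
#' @export
read_expression <- function(matrix_path, labels_path, condition_1 = NULL) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression matrix needs a gene_id column plus sample columns")
  gene_ids <- raw[[1L]]
  if (any(!nzchar(gene_ids)))
    stop("empty gene id at row ", which(!nzchar(gene_ids))[1L])
  sample_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric expression value for gene '", gene_ids[bad[1L]],
           "', sample '", sample_ids[j], "'")
    vals[, j] <- v
  }
  # collapse duplicated gene ids by row averaging (order-independent)
  if (anyDuplicated(gene_ids)) {
    if (length(unique(gene_ids)) == 1L && nrow(vals) > 1L)
      stop("all gene ids are duplicates of a single id")
    vals <- rowsum(vals, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    rownames(vals) <- unique(gene_ids)
  } else {
    rownames(vals) <- gene_ids
  }

  lab <- read.delim(labels_path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(lab) < 2L)
    stop("labels file needs two tab-separated columns: sample_id, condition")
  if (nrow(lab) && identical(tolower(lab[1L, 1L]), "sample_id"))
    lab <- lab[-1L, , drop = FALSE]
  cond_of <- setNames(lab[[2L]], lab[[1L]])
  missing <- setdiff(sample_ids, names(cond_of))
  if (length(missing))
    stop("sample(s) absent from labels file: ",
         paste(missing, collapse = ", "))
  cond_of <- cond_of[sample_ids]
  levels <- sort(unique(cond_of))
  if (length(levels) != 2L)
    stop("expected exactly 2 condition names among the matrix samples, got ",
         length(levels), " (", paste(levels, collapse = ", "), ")")
  if (!is.null(condition_1)) {
    if (!condition_1 %in% levels)
      stop("condition_1 = '", condition_1, "' is not a condition name")
    levels <- c(condition_1, setdiff(levels, condition_1))
  }
  condition <- setNames(match(cond_of, levels), sample_ids)
  ExpressionDataset(vals, condition, condition_names = levels)
}

#' Write an expression dataset to matrix and label files
#'
#' Inverse of [read_expression()]: values are written with full double
#' precision so that a write/read round trip reproduces the dataset
#' exactly.
#'
#' @inheritParams n_samples
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, `c(matrix = matrix_path, labels = labels_path)`.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  vals <- dataset$values
  out <- cbind(gene_id = rownames(vals),
               apply(vals, 2L, function(x) sprintf("%.17g", x)))
  write.table(out, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  lab <- data.frame(sample_id = colnames(vals),
                    condition = dataset$condition_names[dataset$condition])
  write.table(lab, labels_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(c(matrix = matrix_path, labels = labels_path))
}
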