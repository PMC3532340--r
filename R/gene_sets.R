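#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.  Genes repeated
#' within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`: a list with `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, ": need name, description and at least one gene")
    name <- fields[1L]
    if (name %in% names(sets))
      stop("duplicate gene-set name '", name, "' at line ", i)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT line ", i, " ('", name, "'): empty gene list")
    sets[[name]] <- genes
    descriptions[name] <- fields[2L]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets; sizes",
      paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' Write gene sets to a GMT file
#' @param collection A `GeneSetCollection` as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcription factor to target pairs
#'
#' Two-column TSV (`tf <TAB> target`); a `tf <TAB> target` header line
#' is accepted.  Duplicate pairs are dropped keeping first-seen order;
#' self-loop rows (tf equal to target) are rejected with a warning
#' stating how many were dropped.
#'
#' @param path Path to the pairs TSV.
#' @return A data frame with character columns `tf` and `target`.
#' @export
read_regulatory_pairs <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(raw) < 2L)
    stop("regulatory pairs file needs two tab-separated columns")
  if (nrow(raw) && identical(tolower(raw[1L, 1L]), "tf"))
    raw <- raw[-1L, , drop = FALSE]
  pairs <- data.frame(tf = raw[[1L]], target = raw[[2L]],
                      stringsAsFactors = FALSE)
  self <- pairs$tf == pairs$target
  if (any(self)) {
    warning(sum(self), " self-loop pair(s) (tf == target) dropped")
    pairs <- pairs[!self, , drop = FALSE]
  }
  pairs <- pairs[!duplicated(paste0(pairs$tf, "\r", pairs$target)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write transcription factor to target pairs
#' @param pairs Data frame with columns `tf` and `target`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regulatory_pairs <- function(pairs, path) {
  write.table(pairs[, c("tf", "target")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
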