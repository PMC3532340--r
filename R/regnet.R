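# Overlay of DCG calls on the TF -> target regulatory map.

#' Build the DCG-anchored regulatory network
#'
#' Filters the known TF-to-target pairs down to those carrying
#' differential-coexpression evidence and annotates each retained edge
#' with which endpoint is the DCG and with the pair's per-condition
#' correlations (when both endpoints were measured).
#'
#' Retention rules:
#' \describe{
#'   \item{`either-endpoint`}{(default) keep a pair when the TF or the
#'     target is a DCG.  This admits non-DCG TFs whose targets are DCGs,
#'     matching networks in which both DCG and non-DCG nodes appear.}
#'   \item{`dc-link`}{stricter: keep only pairs that are themselves
#'     DC-links (both endpoints DCGs and the pair retained by the link
#'     filter).}
#' }
#' When both endpoints are DCGs the edge's `dcg_label` is the TF
#' (TF-side precedence).
#'
#' @param dcgs Character vector of DCG gene ids.
#' @param dc_links Data frame of DC-links (`gene_a`, `gene_b`) as
#'   produced by [select_dcgs()]; only consulted for the `dc-link` rule.
#' @param reg_pairs Data frame with columns `tf`, `target`
#'   ([read_regulatory_pairs()]).
#' @param r1,r2 Optional correlation matrices used to annotate edges.
#' @param retention `"either-endpoint"` or `"dc-link"`.
#' @return An object of class `RegulatoryNetwork`: list with data frames
#'   `nodes` (`id`, `role` in TF/target/both, `is_dcg`) and `edges`
#'   (`tf`, `target`, `tf_is_dcg`, `target_is_dcg`, `dcg_label`, `r1`,
#'   `r2`).
#' @export
build_network <- function(dcgs, dc_links, reg_pairs, r1 = NULL, r2 = NULL,
                          retention = c("either-endpoint", "dc-link")) {
  retention <- match.arg(retention)
  edges <- data.frame(tf = reg_pairs$tf, target = reg_pairs$target,
                      stringsAsFactors = FALSE)
  edges$tf_is_dcg <- edges$tf %in% dcgs
  edges$target_is_dcg <- edges$target %in% dcgs
  if (retention == "either-endpoint") {
    keep <- edges$tf_is_dcg | edges$target_is_dcg
  } else {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    link_keys <- if (nrow(dc_links))
      key(dc_links$gene_a, dc_links$gene_b) else character()
    keep <- key(edges$tf, edges$target) %in% link_keys
  }
  edges <- edges[keep, , drop = FALSE]
  edges$dcg_label <- ifelse(edges$tf_is_dcg, edges$tf,
                            ifelse(edges$target_is_dcg, edges$target,
                                   NA_character_))
  edges$r1 <- rep(NA_real_, nrow(edges))
  edges$r2 <- rep(NA_real_, nrow(edges))
  if (!is.null(r1) && nrow(edges)) {
    measured <- edges$tf %in% rownames(r1) & edges$target %in% rownames(r1)
    idx <- cbind(match(edges$tf[measured], rownames(r1)),
                 match(edges$target[measured], rownames(r1)))
    edges$r1[measured] <- r1[idx]
    edges$r2[measured] <- r2[idx]
  }
  rownames(edges) <- NULL
  ids <- unique(c(edges$tf, edges$target))
  nodes <- data.frame(id = ids,
                      role = ifelse(ids %in% edges$tf,
                                    ifelse(ids %in% edges$target, "both",
                                           "TF"),
                                    "target"),
                      is_dcg = ids %in% dcgs,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork:", nrow(x$edges), "edges between",
      sum(x$nodes$role != "target"), "TFs and",
      sum(x$nodes$role != "TF"), "targets;",
      sum(x$nodes$is_dcg), "DCG nodes\n")
  invisible(x)
}

#' Classify the network's transcription factors
#'
#' A TF that is itself a DCG is a `DCG-TF`; a TF that is not a DCG but
#' regulates at least one DCG target is a `TF-of-DCGs`.
#'
#' @param network A [build_network()] result.
#' @return Data frame `tf`, `class`, `n_targets`, `n_dcg_targets`.
#' @export
classify_tfs <- function(network) {
  edges <- network$edges
  tfs <- unique(edges$tf)
  out <- data.frame(tf = tfs, stringsAsFactors = FALSE)
  out$class <- ifelse(tfs %in% edges$tf[edges$tf_is_dcg],
                      "DCG-TF", "TF-of-DCGs")
  out$n_targets <- vapply(tfs, function(t) sum(edges$tf == t), integer(1L))
  out$n_dcg_targets <- vapply(tfs, function(t)
    sum(edges$tf == t & edges$target_is_dcg), integer(1L))
  rownames(out) <- NULL
  out
}

#' Export the regulatory network
#'
#' Writes `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` (correlations with
#' 6 decimals) and `<prefix>.graphml` carrying the same attributes.
#'
#' @param network A [build_network()] result.
#' @param out_prefix Output path prefix.
#' @return Named character vector of files written.
#' @export
export_network <- function(network, out_prefix) {
  paths <- c(nodes = paste0(out_prefix, "_nodes.tsv"),
             edges = paste0(out_prefix, "_edges.tsv"),
             graphml = paste0(out_prefix, ".graphml"))
  write.table(network$nodes, paths[["nodes"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  ed <- network$edges
  ed$r1 <- ifelse(is.na(ed$r1), "NA", sprintf("%.6f", ed$r1))
  ed$r2 <- ifelse(is.na(ed$r2), "NA", sprintf("%.6f", ed$r2))
  write.table(ed, paths[["edges"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  g <- igraph::graph_from_data_frame(
    d = transform(network$edges,
                  dcg_label = ifelse(is.na(dcg_label), "", dcg_label)),
    directed = TRUE, vertices = network$nodes)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  paths
}
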