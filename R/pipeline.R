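# End-to-end orchestration: file-based stages (dcg -> enrich -> network
# -> rif) driven by one config and one seed, with a JSON run manifest.

#' Assemble a pipeline configuration
#'
#' @param expression,labels Paths to the expression matrix and sample
#'   labels ([read_expression()] formats).
#' @param gene_sets Path to a GMT file.
#' @param regulatory_pairs Path to a TF-target pairs TSV.
#' @param out_dir Output directory; must not coincide with an input file.
#' @param fdr_cutoff DCG selection cutoff on BH-FDR (default 0.25).
#' @param alpha Enrichment significance cutoff (default 0.05).
#' @param q_filter Link-filter fraction (default 0.25).
#' @param n_perm Label permutations for the DCG test (default 1000).
#' @param seed Master seed; each stage derives its own sub-seed from it
#'   and the stage name, so stages are independently reproducible.
#' @param retention Network retention rule, see [build_network()].
#' @param rif_targets RIF target-set mode, see [rank_tfs()].
#' @param condition_1 Optional condition label to orient as condition 1.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(expression, labels, gene_sets, regulatory_pairs,
                            out_dir, fdr_cutoff = 0.25, alpha = 0.05,
                            q_filter = 0.25, n_perm = 1000L, seed = 1L,
                            retention = "either-endpoint",
                            rif_targets = "network-dcg",
                            condition_1 = NULL) {
  cfg <- list(expression = expression, labels = labels,
              gene_sets = gene_sets, regulatory_pairs = regulatory_pairs,
              out_dir = out_dir, fdr_cutoff = fdr_cutoff, alpha = alpha,
              q_filter = q_filter, n_perm = as.integer(n_perm),
              seed = as.integer(seed), retention = retention,
              rif_targets = rif_targets, condition_1 = condition_1)
  if (cfg$fdr_cutoff < 0 || cfg$fdr_cutoff > 1) stop("fdr_cutoff in [0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha in (0, 1)")
  if (cfg$q_filter <= 0 || cfg$q_filter > 1) stop("q_filter in (0, 1]")
  if (cfg$n_perm < 1L) stop("n_perm must be >= 1")
  inputs <- c(expression, labels, gene_sets, regulatory_pairs)
  if (any(normalizePath(inputs, mustWork = FALSE) ==
            normalizePath(out_dir, mustWork = FALSE)))
    stop("out_dir must be distinct from the input files")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys are the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# deterministic per-stage sub-seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

out_path <- function(config, name) file.path(config$out_dir, name)

require_stage_file <- function(config, name, producer) {
  p <- out_path(config, name)
  if (!file.exists(p))
    stop("missing '", name, "': run the '", producer, "' stage first")
  p
}

fmt6 <- function(x) sprintf("%.6f", x)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_dataset <- function(config) {
  read_expression(config$expression, config$labels,
                  condition_1 = config$condition_1)
}

#' Run one pipeline stage from files on disk
#'
#' Stages read their inputs (and the outputs of earlier stages) from
#' `config$out_dir` and write fixed-name TSVs there, so each stage is
#' independently re-runnable.  Stage outputs:
#' \describe{
#'   \item{dcg}{`dcg_table.tsv` (gene, dC, p, fdr, is_dcg) and
#'     `dc_links.tsv` (gene_a, gene_b, r1, r2, d).}
#'   \item{enrich}{`enrichment.tsv` (set_name, count, size, p,
#'     significant).}
#'   \item{network}{`network_nodes.tsv`, `network_edges.tsv`,
#'     `network.graphml`, `tf_classes.tsv`.}
#'   \item{rif}{`rif_table.tsv` (tf, n_de, rif, abs_rank).}
#' }
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"dcg"`, `"enrich"`, `"network"`, `"rif"`.
#' @return Invisibly, a named list of row counts of the tables written.
#' @export
run_stage <- function(config, stage = c("dcg", "enrich", "network", "rif")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- switch(
    stage,
    dcg = {
      dataset <- read_dataset(config)
      res <- run_dcg(dataset, q = config$q_filter, n_perm = config$n_perm,
                     seed = stage_seed(config$seed, "dcg"),
                     fdr_cutoff = config$fdr_cutoff)
      tab <- res$dcg_table
      tab$dC <- fmt6(tab$dC); tab$p <- fmt6(tab$p); tab$fdr <- fmt6(tab$fdr)
      write_tsv(tab, out_path(config, "dcg_table.tsv"))
      links <- res$dc_links
      for (col in c("r1", "r2", "d")) links[[col]] <- fmt6(links[[col]])
      write_tsv(links, out_path(config, "dc_links.tsv"))
      list(dcg_table = nrow(tab), dc_links = nrow(links),
           n_dcgs = length(res$dcgs))
    },
    enrich = {
      dataset <- read_dataset(config)
      dcg_tab <- read.delim(require_stage_file(config, "dcg_table.tsv",
                                               "dcg"))
      dcgs <- dcg_tab$gene[dcg_tab$is_dcg == "TRUE" | dcg_tab$is_dcg == TRUE]
      gsc <- read_gmt(config$gene_sets)
      enr <- if (length(dcgs)) {
        enrich_gene_sets(dcgs, gsc, rownames(dataset$values),
                         alpha = config$alpha)
      } else {
        data.frame(set_name = character(), count = integer(),
                   size = integer(), p = numeric(),
                   significant = logical())
      }
      enr$p <- sprintf("%.6g", enr$p)
      write_tsv(enr, out_path(config, "enrichment.tsv"))
      list(enrichment = nrow(enr))
    },
    network = {
      dataset <- read_dataset(config)
      dcg_tab <- read.delim(require_stage_file(config, "dcg_table.tsv",
                                               "dcg"))
      dcgs <- dcg_tab$gene[dcg_tab$is_dcg == "TRUE" | dcg_tab$is_dcg == TRUE]
      links <- read.delim(require_stage_file(config, "dc_links.tsv", "dcg"),
                          colClasses = c(gene_a = "character",
                                         gene_b = "character"))
      pairs <- read_regulatory_pairs(config$regulatory_pairs)
      cors <- suppressWarnings(condition_correlations(dataset))
      net <- build_network(dcgs, links, pairs, cors$r1, cors$r2,
                           retention = config$retention)
      export_network(net, out_path(config, "network"))
      write_tsv(classify_tfs(net), out_path(config, "tf_classes.tsv"))
      list(nodes = nrow(net$nodes), edges = nrow(net$edges))
    },
    rif = {
      dataset <- read_dataset(config)
      dcg_tab <- read.delim(require_stage_file(config, "dcg_table.tsv",
                                               "dcg"))
      dcgs <- dcg_tab$gene[dcg_tab$is_dcg == "TRUE" | dcg_tab$is_dcg == TRUE]
      edges <- read.delim(require_stage_file(config, "network_edges.tsv",
                                             "network"),
                          colClasses = "character")
      edges$target_is_dcg <- edges$target_is_dcg == "TRUE"
      edges$tf_is_dcg <- edges$tf_is_dcg == "TRUE"
      net <- structure(list(edges = edges), class = "RegulatoryNetwork")
      rif <- if (nrow(edges) && length(dcgs)) {
        rank_tfs(dataset, net, dcgs, targets = config$rif_targets)
      } else {
        data.frame(tf = character(), n_de = integer(), rif = numeric(),
                   abs_rank = integer())
      }
      rif$rif <- fmt6(rif$rif)
      write_tsv(rif, out_path(config, "rif_table.tsv"))
      list(rif_table = nrow(rif))
    })
  invisible(counts)
}

#' Run the whole pipeline and write a manifest
#'
#' Executes the dcg, enrich, network and rif stages in order on the
#' configured inputs, then writes `manifest.json` recording the package
#' version, every threshold applied, the seed and the row counts of all
#' outputs.  Identical config and seed reproduce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  counts <- list()
  for (stage in c("dcg", "enrich", "network", "rif")) {
    message("[dcrif] stage: ", stage)
    res <- tryCatch(run_stage(config, stage), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    counts <- c(counts, res)
  }
  manifest <- list(
    package = "dcrif",
    version = as.character(packageVersion("dcrif")),
    seed = config$seed,
    parameters = config[c("fdr_cutoff", "alpha", "q_filter", "n_perm",
                          "retention", "rif_targets")],
    inputs = config[c("expression", "labels", "gene_sets",
                      "regulatory_pairs")],
    row_counts = counts)
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
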