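#' Specify a two-condition simulation with planted coexpression modules
#'
#' Describes a gene-by-sample dataset in which a chosen number of gene
#' modules are coexpressed with correlation `rho1` in condition 1 and
#' `rho2` in condition 2, while all remaining genes share a weak
#' background correlation `baseline_rho` in both conditions.  Defaults
#' emulate a small two-group log2-intensity microarray study: 6 samples
#' per condition and within-module correlations that flip from about
#' +0.95 to about -0.85 between conditions.
#'
#' Each module is driven by one latent standard-normal factor per
#' condition.  A module gene g gets loading `sign * sqrt(|rho_c|)` on the
#' factor plus independent noise, so any two module genes correlate at
#' `+/- |rho_c|`.  The first gene of every module is its *anchor* (the
#' proxy transcription factor) and always loads positively; when `rho_c`
#' is negative, `floor(module_size / 2)` of the non-anchor genes load
#' negatively, so roughly half of all within-module pairs - anchor-target
#' pairs included - flip correlation sign between conditions.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_condition Samples per condition (>= 3).
#' @param n_modules Number of planted modules (>= 0).
#' @param module_size Genes per module (>= 2).
#' @param rho1,rho2 Target within-module correlation in conditions 1 and
#'   2, each in (-1, 1).
#' @param baseline_rho Background pairwise correlation of non-module
#'   genes, in `[0, 1)` (a common negative pairwise correlation across
#'   more than two genes is not realizable).
#' @param mean_log_expr,sd_log_expr Location and scale of the expression
#'   values (log2-microarray-like defaults: mean 8, sd 2).
#' @param seed Integer RNG seed; identical specs give identical data.
#' @return An object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_genes = 2000L,
                            n_samples_per_condition = 6L,
                            n_modules = 2L,
                            module_size = 10L,
                            rho1 = 0.95,
                            rho2 = -0.85,
                            baseline_rho = 0,
                            mean_log_expr = 8,
                            sd_log_expr = 2,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_condition = as.integer(n_samples_per_condition),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               rho1 = rho1, rho2 = rho2, baseline_rho = baseline_rho,
               mean_log_expr = mean_log_expr, sd_log_expr = sd_log_expr,
               seed = as.integer(seed))
  if (spec$n_genes < 1L) stop("n_genes must be positive")
  if (spec$n_samples_per_condition < 3L)
    stop("n_samples_per_condition must be >= 3")
  if (spec$n_modules < 0L) stop("n_modules must be >= 0")
  if (spec$n_modules > 0L && spec$module_size < 2L)
    stop("module_size must be >= 2")
  if (spec$n_modules * spec$module_size > spec$n_genes)
    stop("n_modules * module_size exceeds n_genes")
  for (r in c(spec$rho1, spec$rho2))
    if (abs(r) >= 1) stop("rho1 and rho2 must lie in (-1, 1)")
  if (spec$baseline_rho < 0 || spec$baseline_rho >= 1)
    stop("baseline_rho must lie in [0, 1)")
  if (spec$sd_log_expr <= 0) stop("sd_log_expr must be positive")
  class(spec) <- "SimulationSpec"
  spec
}

#' Simulate a two-condition dataset with known ground truth
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{an [ExpressionDataset] (`n_genes` x
#'       `2 * n_samples_per_condition`; condition names `case`/`control`
#'       map to conditions 1/2),}
#'     \item{truth}{ground truth: `dc_genes` (all module members),
#'       `modules` (named list of gene-id vectors), `planted_tf_of_module`
#'       (anchor gene per module), `dc_links` (data frame of unordered
#'       within-module pairs whose correlation sign flips between
#'       conditions), and the `spec`.}
#'   }
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$n_samples_per_condition
  g <- spec$n_genes
  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- c(sprintf("case_%02d", seq_len(n)),
                  sprintf("ctrl_%02d", seq_len(n)))
  condition <- setNames(rep(1:2, each = n), sample_ids)

  modules <- list()
  flip_sets <- list()
  if (spec$n_modules > 0L) {
    for (m in seq_len(spec$n_modules)) {
      idx <- ((m - 1L) * spec$module_size + 1L):(m * spec$module_size)
      modules[[paste0("module", m)]] <- gene_ids[idx]
      # genes whose loading sign follows sign(rho_c); anchor (first) never flips
      n_flip <- spec$module_size %/% 2L
      flip_sets[[m]] <- if (n_flip > 0L) idx[1L + seq_len(n_flip)] else integer()
    }
  }
  module_of <- integer(g)
  for (m in seq_along(modules))
    module_of[match(modules[[m]], gene_ids)] <- m

  z <- matrix(NA_real_, g, 2L * n)
  rho_c <- c(spec$rho1, spec$rho2)
  for (cond in 1:2) {
    cols <- which(condition == cond)
    noise <- matrix(rnorm(g * n), g, n)
    bg <- rnorm(n)                       # shared background factor
    b <- sqrt(spec$baseline_rho)
    zc <- b * matrix(bg, g, n, byrow = TRUE) + sqrt(1 - b^2) * noise
    if (spec$n_modules > 0L) {
      rho <- rho_c[cond]
      a <- sqrt(abs(rho))
      for (m in seq_len(spec$n_modules)) {
        f <- rnorm(n)                    # latent module factor
        idx <- match(modules[[m]], gene_ids)
        sgn <- rep(1, length(idx))
        sgn[idx %in% flip_sets[[m]]] <- sign(rho)
        zc[idx, ] <- sgn * a * matrix(f, length(idx), n, byrow = TRUE) +
          sqrt(1 - abs(rho)) * matrix(rnorm(length(idx) * n), length(idx), n)
      }
    }
    z[, cols] <- zc
  }
  vals <- spec$mean_log_expr + spec$sd_log_expr * z
  dimnames(vals) <- list(gene_ids, sample_ids)
  dataset <- ExpressionDataset(vals, condition,
                               condition_names = c("case", "control"))

  dc_links <- data.frame(gene_a = character(), gene_b = character())
  if (spec$n_modules > 0L && sign(spec$rho1) != sign(spec$rho2)) {
    for (m in seq_len(spec$n_modules)) {
      idx <- match(modules[[m]], gene_ids)
      flipped <- idx %in% flip_sets[[m]]
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i < j && xor(flipped[i], flipped[j])) {
          pr <- sort(gene_ids[c(idx[i], idx[j])])
          dc_links <- rbind(dc_links,
                            data.frame(gene_a = pr[1L], gene_b = pr[2L]))
        }
      }
    }
  }
  truth <- list(dc_genes = unlist(modules, use.names = FALSE),
                modules = modules,
                planted_tf_of_module =
                  vapply(modules, `[`, character(1L), 1L),
                module_of = setNames(module_of, gene_ids),
                dc_links = dc_links,
                spec = spec)
  list(dataset = dataset, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits everything the pipeline consumes: the expression matrix and
#' sample labels, a GMT file with one pathway per planted module plus
#' size-matched decoy sets of background genes, a TF-to-target pairs
#' file in which each module's anchor gene regulates the rest of its
#' module and decoy TFs (random background genes) regulate random
#' targets, and a ground-truth table.
#'
#' @param sim Result of [simulate_expression()].
#' @param out_dir Output directory (created if needed).
#' @param n_decoy_sets Number of decoy gene sets in the GMT.
#' @param decoy_tf_count Number of decoy TFs in the pairs file.
#' @param targets_per_decoy Targets drawn per decoy TF.
#' @param seed Seed for the decoy draws (defaults to the simulation seed
#'   offset by one so fixtures are reproducible).
#' @return Named character vector of the files written: `matrix`,
#'   `labels`, `gmt`, `pairs`, `truth`.
#' @export
write_fixture_bundle <- function(sim, out_dir,
                                 n_decoy_sets = 5L,
                                 decoy_tf_count = 20L,
                                 targets_per_decoy = 5L,
                                 seed = sim$truth$spec$seed + 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- sim$dataset
  truth <- sim$truth
  gene_ids <- rownames(dataset$values)
  paths <- c(matrix = file.path(out_dir, "expression.tsv"),
             labels = file.path(out_dir, "labels.tsv"),
             gmt = file.path(out_dir, "gene_sets.gmt"),
             pairs = file.path(out_dir, "regulatory_pairs.tsv"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  write_expression(dataset, paths[["matrix"]], paths[["labels"]])

  set.seed(seed)
  background <- setdiff(gene_ids, truth$dc_genes)
  sets <- truth$modules
  names(sets) <- toupper(names(sets))
  size <- if (length(truth$modules)) length(truth$modules[[1L]]) else 10L
  for (d in seq_len(n_decoy_sets))
    sets[[sprintf("DECOY%02d", d)]] <-
      sample(background, min(size, length(background)))
  gsc <- structure(list(sets = sets,
                        descriptions = setNames(rep("synthetic", length(sets)),
                                                names(sets))),
                   class = "GeneSetCollection")
  write_gmt(gsc, paths[["gmt"]])

  pairs <- data.frame(tf = character(), target = character())
  for (m in seq_along(truth$modules)) {
    tf <- truth$planted_tf_of_module[[m]]
    targets <- setdiff(truth$modules[[m]], tf)
    pairs <- rbind(pairs, data.frame(tf = tf, target = targets))
  }
  # decoy TFs and their targets are background genes: a decoy edge must
  # carry no planted differential-coexpression signal by construction
  decoy_tfs <- sample(background, decoy_tf_count)
  for (tf in decoy_tfs) {
    targets <- sample(setdiff(background, tf), targets_per_decoy)
    pairs <- rbind(pairs, data.frame(tf = tf, target = targets))
  }
  write_regulatory_pairs(pairs, paths[["pairs"]])

  gt <- data.frame(gene_id = gene_ids,
                   stringsAsFactors = FALSE,
                   is_dc = as.integer(gene_ids %in% truth$dc_genes),
                   module = ifelse(truth$module_of > 0L,
                                   paste0("module", truth$module_of), "."))
  write.table(gt, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  paths
}

#' Generate the canonical validation fixture
#'
#' One fixed, documented simulation used throughout the package's
#' end-to-end validation: 200 genes, 2 planted modules of 10 genes
#' (hence 2 planted anchor TFs), 20 samples per condition, within-module
#' correlations +0.95 / -0.85, 20 decoy TFs with 5 background targets
#' each and 5 decoy gene sets.  Only the seed varies between runs.
#'
#' @param out_dir Directory to write the fixture files into.
#' @param seed Integer seed.
#' @return A list: `sim` (the [simulate_expression()] result) and
#'   `paths` (the [write_fixture_bundle()] files).
#' @export
make_fixture <- function(out_dir, seed = 1L) {
  spec <- simulation_spec(n_genes = 200L, n_samples_per_condition = 20L,
                          n_modules = 2L, module_size = 10L, seed = seed)
  sim <- simulate_expression(spec)
  paths <- write_fixture_bundle(sim, out_dir, n_decoy_sets = 5L,
                                decoy_tf_count = 20L,
                                targets_per_decoy = 5L)
  list(sim = sim, paths = paths)
}
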