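make_toy_net <- function(dcgs, retention = "either-endpoint",
                         dc_links = data.frame(gene_a = character(),
                                               gene_b = character())) {
  pairs <- data.frame(tf = c("NKX3L", "HLFL", "E2FL", "NONE"),
                      target = c("NUDT", "GPR", "TALL", "OTHER"),
                      stringsAsFactors = FALSE)
  build_network(dcgs, dc_links, pairs, retention = retention)
}

test_that("edges are retained iff an endpoint is a DCG; TF-side label precedence", {
  net <- make_toy_net(c("NUDT", "HLFL", "E2FL", "TALL"))
  expect_setequal(net$edges$tf, c("NKX3L", "HLFL", "E2FL"))
  # non-DCG TF with DCG target: labelled by the target
  expect_identical(net$edges$dcg_label[net$edges$tf == "NKX3L"], "NUDT")
  # DCG TF: labelled by the TF
  expect_identical(net$edges$dcg_label[net$edges$tf == "HLFL"], "HLFL")
  # both endpoints DCGs: TF wins
  expect_identical(net$edges$dcg_label[net$edges$tf == "E2FL"], "E2FL")
  # pair with neither endpoint a DCG is dropped
  expect_false("NONE" %in% net$edges$tf)
  expect_false("OTHER" %in% net$nodes$id)
})

test_that("dc-link retention only keeps pairs that are DC-links", {
  links <- data.frame(gene_a = "GPR", gene_b = "HLFL")  # unordered pair
  net <- build_network(c("HLFL", "GPR", "NUDT"),
                       links,
                       data.frame(tf = c("HLFL", "NKX3L"),
                                  target = c("GPR", "NUDT")),
                       retention = "dc-link")
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$tf, "HLFL")
})

test_that("retention is monotone in the DCG set and bounded by the pair list", {
  pairs <- data.frame(tf = letters[1:5], target = letters[6:10])
  empty_links <- data.frame(gene_a = character(), gene_b = character())
  small <- build_network(c("a"), empty_links, pairs)
  large <- build_network(c("a", "f", "g"), empty_links, pairs)
  expect_true(all(paste(small$edges$tf, small$edges$target) %in%
                    paste(large$edges$tf, large$edges$target)))
  expect_lte(nrow(large$edges), nrow(pairs))
  expect_setequal(large$nodes$id, c(large$edges$tf, large$edges$target))
})

test_that("TF classification separates DCG-TFs from TFs of DCGs", {
  net <- make_toy_net(c("NUDT", "HLFL", "E2FL", "TALL"))
  cls <- classify_tfs(net)
  expect_identical(cls$class[cls$tf == "HLFL"], "DCG-TF")
  expect_identical(cls$class[cls$tf == "E2FL"], "DCG-TF")
  expect_identical(cls$class[cls$tf == "NKX3L"], "TF-of-DCGs")
})

test_that("a planted anchor TF classifies as DCG-TF in most seeded runs", {
  hits <- 0L
  n_runs <- 20L
  for (i in seq_len(n_runs)) {
    spec <- simulation_spec(n_genes = 60, n_samples_per_condition = 20,
                            n_modules = 1, module_size = 10, seed = 100 + i)
    sim <- simulate_expression(spec)
    res <- suppressWarnings(run_dcg(sim$dataset, n_perm = 150, seed = i))
    tf <- sim$truth$planted_tf_of_module[[1]]
    targets <- setdiff(sim$truth$modules$module1, tf)
    net <- build_network(res$dcgs, res$dc_links,
                         data.frame(tf = tf, target = targets))
    cls <- classify_tfs(net)
    if (tf %in% cls$tf && cls$class[cls$tf == tf] == "DCG-TF")
      hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("network export round-trips through GraphML and writes TSVs", {
  r1 <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("HLFL", "GPR"), c("HLFL", "GPR")))
  r2 <- -r1
  diag(r2) <- 1
  net <- build_network("HLFL",
                       data.frame(gene_a = character(),
                                  gene_b = character()),
                       data.frame(tf = "HLFL", target = "GPR"),
                       r1 = r1, r2 = r2)
  prefix <- file.path(tempfile("net"), "out")
  dir.create(dirname(prefix))
  paths <- export_network(net, prefix)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[["edges"]])
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$r1, 0.5, tolerance = 1e-6)

  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(igraph::E(g)$r1, net$edges$r1)
})

test_that("an empty network exports header-only tables and valid GraphML", {
  net <- build_network(character(),
                       data.frame(gene_a = character(),
                                  gene_b = character()),
                       data.frame(tf = character(), target = character()))
  expect_equal(nrow(net$edges), 0L)
  prefix <- file.path(tempfile("emptynet"), "out")
  dir.create(dirname(prefix))
  paths <- export_network(net, prefix)
  expect_equal(nrow(read.delim(paths[["edges"]])), 0L)
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), 0L)
})
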