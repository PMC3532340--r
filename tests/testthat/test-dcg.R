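test_that("condition correlations match hand-computed Pearson values", {
  m <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1),
             w = c(2, 4, 6, 8))
  m2 <- cbind(m, m)                        # same values in both conditions
  colnames(m2) <- paste0("s", 1:8)
  ds <- toy_dataset(m2, n1 = 4L)
  r <- condition_correlations(ds)
  expect_equal(r$r1["x", "w"], 1)          # perfect linearity
  expect_equal(r$r1["x", "z"], -1)         # perfect anti-linearity
  # hand computation: centered x = (-1.5,-0.5,0.5,1.5), y = (-1.5,0.5,-0.5,1.5)
  # sum xy = 4, sum x^2 = sum y^2 = 5, so r = 4/5
  expect_equal(r$r1["x", "y"], 4 / 5)
  expect_true(isSymmetric(r$r1))
  expect_equal(unname(diag(r$r1)), rep(1, 4))
})

test_that("zero-variance genes give correlation 0 with a warning", {
  m <- rbind(flat = rep(5, 8), a = rnorm(8), b = rnorm(8))
  colnames(m) <- paste0("s", 1:8)
  ds <- toy_dataset(m)
  expect_warning(r <- condition_correlations(ds), "zero-variance.*flat")
  expect_equal(r$r1["flat", "a"], 0)
  expect_equal(r$r1["flat", "flat"], 1)
})

test_that("link filter keeps the top-q links by max |r|, ties retained", {
  set.seed(1)
  ds <- random_dataset(4, 4)
  r <- condition_correlations(ds)
  all_links <- filter_links(r$r1, r$r2, q = 1)
  expect_equal(sum(all_links[upper.tri(all_links)]), 6L)  # all 6 of K4

  # brute-force check on a 10-link toy (5 genes)
  ds5 <- random_dataset(5, 6, seed = 2)
  r5 <- condition_correlations(ds5)
  q <- 0.25
  got <- filter_links(r5$r1, r5$r2, q)
  ut <- upper.tri(r5$r1)
  pooled <- c(abs(r5$r1[ut]), abs(r5$r2[ut]))
  thr <- quantile(pooled, 1 - q, names = FALSE)
  expect_identical(unname(got[ut]),
                   unname(pmax(abs(r5$r1), abs(r5$r2))[ut] >= thr))

  # all correlations equal: >= tie rule retains every link
  r_const <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(r_const) <- 1
  got <- filter_links(r_const, r_const, q = 0.5)
  expect_equal(sum(got[upper.tri(got)]), 3L)

  expect_error(filter_links(r5$r1, r5$r2, q = 0), "\\(0, 1\\]")
  expect_error(filter_links(r5$r1, r5$r2, q = 1.5), "\\(0, 1\\]")
})

test_that("gene dC statistic is the RMS correlation change over retained links", {
  nm <- c("a", "b", "c")
  mk <- function(ab, ac, bc) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- ab
    m[1, 3] <- m[3, 1] <- ac
    m[2, 3] <- m[3, 2] <- bc
    dimnames(m) <- list(nm, nm)
    m
  }
  retained <- mk(1, 1, 1) > 0
  diag(retained) <- FALSE

  # r1 == r2 everywhere -> dC = 0
  r <- mk(0.3, -0.2, 0.7)
  expect_equal(unname(gene_dc_statistics(r, r, retained)), rep(0, 3))

  # two links with (r1, r2) = (1, -1) and (-1, 1) -> dC = sqrt((4 + 4)/2) = 2
  r1 <- mk(1, -1, 0)
  r2 <- mk(-1, 1, 0)
  expect_equal(gene_dc_statistics(r1, r2, retained)[["a"]], 2)

  # the worked single-link example: |0.970975 - (-0.88501)| = 1.855985
  r1 <- mk(0.970975, 0, 0)
  r2 <- mk(-0.88501, 0, 0)
  only_ab <- mk(1, 0, 0) > 0.5
  diag(only_ab) <- FALSE
  expect_equal(gene_dc_statistics(r1, r2, only_ab)[["a"]], 1.855985,
               tolerance = 1e-9)

  # no retained links -> dC = 0
  none <- retained & FALSE
  expect_equal(unname(gene_dc_statistics(r1, r2, none)), rep(0, 3))
})

test_that("permutation p-values respect the add-one bounds and determinism", {
  ds <- random_dataset(20, 5, seed = 3)
  res1 <- dcg_permutation_test(ds, n_perm = 199, seed = 9)
  res2 <- dcg_permutation_test(ds, n_perm = 199, seed = 9)
  expect_identical(res1$table, res2$table)
  expect_gte(min(res1$table$p), 1 / 200)
  expect_lte(max(res1$table$p), 1)
  expect_warning(dcg_permutation_test(ds, n_perm = 99, seed = 1),
                 "coarse")
})

test_that("dC, p and FDR are invariant under swapping the two conditions", {
  spec <- simulation_spec(n_genes = 30, n_samples_per_condition = 8,
                          n_modules = 1, module_size = 5,
                          rho1 = 0.9, rho2 = -0.9, seed = 6)
  ds <- simulate_expression(spec)$dataset
  swapped <- ExpressionDataset(ds$values,
                               setNames(3L - ds$condition,
                                        names(ds$condition)))
  a <- dcg_permutation_test(ds, n_perm = 120, seed = 5)
  b <- dcg_permutation_test(swapped, n_perm = 120, seed = 5)
  expect_equal(a$table$dC, b$table$dC)
  expect_equal(a$table$p, b$table$p)
})

test_that("bh_adjust matches hand computations and validates input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  # order preserved under input permutation
  p <- c(0.3, 0.01, 0.7, 0.02)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_gte(min(bh_adjust(p) - p), 0)  # BH can only increase p
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("DCG selection is strict at the cutoff and links need both endpoints", {
  fake <- list(table = data.frame(gene = c("a", "b", "c"),
                                  dC = c(1, 0.5, 0.1),
                                  p = c(0.01, 0.25, 0.9)),
               r1 = diag(3), r2 = diag(3),
               retained = matrix(TRUE, 3, 3))
  dimnames(fake$r1) <- dimnames(fake$r2) <- list(c("a", "b", "c"),
                                                 c("a", "b", "c"))
  diag(fake$retained) <- FALSE
  # fdr = 0.03, 0.375, 0.9 -> fdr exactly at cutoff is NOT selected
  sel <- select_dcgs(fake, fdr_cutoff = 0.375)
  expect_identical(sel$dcgs, "a")
  expect_equal(nrow(sel$dc_links), 0L)

  sel2 <- select_dcgs(fake, fdr_cutoff = 1)
  expect_identical(sel2$dcgs, c("a", "b", "c"))
  expect_equal(nrow(sel2$dc_links), 3L)   # complete graph K3
  expect_true(all(sel2$dc_links$gene_a < sel2$dc_links$gene_b))
  expect_equal(sel2$dc_links$d, abs(sel2$dc_links$r1 - sel2$dc_links$r2))

  sel3 <- select_dcgs(fake, fdr_cutoff = 0)
  expect_length(sel3$dcgs, 0L)
  expect_equal(nrow(sel3$dc_links), 0L)
})
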