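toy_counts <- function(mat, genes = paste0("g", seq_len(nrow(mat)))) {
  rownames(mat) <- genes
  colnames(mat) <- paste0("i", seq_len(ncol(mat)))
  mat
}

test_that("CPM filter keeps genes at the threshold", {
  counts <- toy_counts(rbind(rep(0, 4),          # all zero: removed
                             rep(10, 4),         # CPM exactly 0.5: kept
                             rep(100, 4)))
  lib <- rep(2e7, 4)
  kept <- cpm_filter(counts, lib, threshold = 0.5)
  expect_setequal(rownames(kept), c("g2", "g3"))
  expect_equal(attr(kept, "removed"), "g1")
  # toy CPMs {0.4, 0.5, 5}
  counts2 <- toy_counts(rbind(rep(8, 4), rep(10, 4), rep(100, 4)))
  expect_equal(nrow(cpm_filter(counts2, lib)), 2)
  expect_error(cpm_filter(counts, rep(0, 4)), "> 0")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p))
})

test_that("permutation test: null toys give p = 1, oracle agreement on 3v3", {
  groups <- rep(c("female", "male"), each = 3)
  lib <- rep(1e6, 6)
  flat <- toy_counts(matrix(50, nrow = 2, ncol = 6))
  r <- internal_de_test(flat, groups, lib)
  expect_equal(r$p, c(1, 1))
  expect_equal(r$log2FC, c(0, 0))

  set.seed(9)
  counts <- toy_counts(matrix(rnbinom(5 * 6, mu = 80, size = 5), nrow = 5))
  r2 <- internal_de_test(counts, groups, lib)
  for (g in seq_len(5)) {
    expect_equal(r2$p[g], oracle_perm_p(counts[g, ], lib, groups),
                 tolerance = 1e-12)
  }
  expect_error(internal_de_test(counts, rep("a", 6), lib), "two groups")
})

test_that("permutation test recovers a four-fold change", {
  set.seed(11)
  n_genes <- 200
  mu_f <- 100
  counts <- toy_counts(cbind(
    matrix(rnbinom(n_genes * 5, mu = mu_f, size = 8), n_genes),
    matrix(rnbinom(n_genes * 5, mu = mu_f * 4, size = 8), n_genes)))
  groups <- rep(c("female", "male"), each = 5)
  r <- internal_de_test(counts, groups, rep(1e6, 10))
  expect_lt(abs(median(r$log2FC) - 2), 0.5)
  expect_true(all(r$p >= 1 / choose(10, 5)))
})

test_that("consensus voting applies the two-method FDR rule", {
  res <- data.frame(
    gene = rep(c("g1", "g2", "g3", "g4"), times = 3),
    method = rep(c("m1", "m2", "m3"), each = 4),
    p = 1, q = 1, log2FC = 0, stringsAsFactors = FALSE)
  set_q <- function(res, gene, method, q, fc) {
    i <- res$gene == gene & res$method == method
    res$q[i] <- q
    res$log2FC[i] <- fc
    res
  }
  res <- set_q(res, "g1", "m1", 1e-6, 2)   # one method only: not called
  res <- set_q(res, "g2", "m1", 1e-6, 2)   # two methods, both positive
  res <- set_q(res, "g2", "m2", 1e-5, 1.5)
  res <- set_q(res, "g3", "m1", 1e-6, 2)   # two methods, conflicting sign
  res <- set_q(res, "g3", "m3", 1e-6, -2)
  calls <- suppressMessages(consensus_vote(res))
  expect_false(calls$consensus[calls$gene == "g1"])
  expect_true(calls$consensus[calls$gene == "g2"])
  expect_equal(calls$direction[calls$gene == "g2"], "male")
  expect_false(calls$consensus[calls$gene == "g3"])
  expect_true(calls$dropped_conflict[calls$gene == "g3"])
  expect_false(calls$consensus[calls$gene == "g4"])

  # the consensus set shrinks as the rule tightens
  loose <- suppressMessages(consensus_vote(res, fdr_cutoff = 1e-3))
  strict3 <- suppressMessages(consensus_vote(res, min_methods = 3))
  expect_true(all(calls$gene[calls$consensus] %in%
                    loose$gene[loose$consensus]))
  expect_lte(sum(strict3$consensus), sum(calls$consensus))

  one <- res[res$method == "m1", ]
  expect_error(consensus_vote(one), "two methods")
  disjoint <- res
  disjoint$gene[disjoint$method == "m2"] <- paste0("x",
    disjoint$gene[disjoint$method == "m2"])
  disjoint$gene[disjoint$method == "m3"] <- paste0("y",
    disjoint$gene[disjoint$method == "m3"])
  expect_error(consensus_vote(disjoint), "disjoint")
})

test_that("class enrichment percentages and a balanced Fisher toy", {
  # 4 of 20 biased in both classes: perfectly balanced, p = 1
  asn <- data.frame(contig = paste0("g", 1:40),
                    assigned_type = rep(c("XY", "autosomal"), each = 20),
                    stringsAsFactors = FALSE)
  calls <- data.frame(gene = paste0("g", 1:40),
                      n_methods_significant = 0L,
                      consensus = rep(c(TRUE, FALSE, TRUE, FALSE),
                                      times = c(4, 16, 4, 16)),
                      direction = NA, min_q = 1, dropped_conflict = FALSE,
                      stringsAsFactors = FALSE)
  enr <- enrichment_summary(calls, asn)
  expect_equal(enr$classes$percent[enr$classes$class == "XY"], 20)
  expect_equal(enr$tests$p[enr$tests$comparison ==
                             "sex_linked_vs_autosomal"], 1)
  expect_equal(enr$classes$n_total[enr$classes$class == "sex_linked"], 20)
})

test_that("published sex-bias percentages follow from the counts", {
  expect_equal(unname(as_percent(c(2682, 591))), c(81.94, 18.06))
  expect_equal(as_percent(241, 1364), 17.67)
  expect_equal(as_percent(206, 3706), 5.56)
  expect_equal(as_percent(228, 241), 94.61)
})

test_that("null counts produce almost no consensus calls at FDR 1e-4", {
  set.seed(17)
  n_genes <- 5000
  counts <- toy_counts(matrix(rnbinom(n_genes * 12, mu = 100, size = 8),
                              nrow = n_genes),
                       genes = paste0("n", seq_len(n_genes)))
  groups <- rep(c("female", "male"), each = 6)
  de <- run_de_methods(counts, groups, seed = 19)
  calls <- suppressMessages(consensus_vote(de))
  expect_lte(sum(calls$consensus) / n_genes, 1e-3)
})
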