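test_that("identical configurations give byte-identical output", {
  cfg <- sim_config(n_contigs = 40, seed = 99)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(s1$dataset$gt, s2$dataset$gt)
  expect_identical(s1$dataset$d1, s2$dataset$d1)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$haplotypes, `[[`, "y"),
                   lapply(s2$haplotypes, `[[`, "y"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(type_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(n_sons = 0), "son")
  expect_error(sim_config(n_daughters = 0), "son|daughter")
  expect_error(sim_config(genotyping_error = 1), "\\[0, 1\\)")
})

test_that("a degenerate all-autosomal mixture yields only autosomal contigs", {
  sim <- small_sim(n = 50, seed = 3, type_proportions = c(1, 0, 0))
  expect_true(all(sim$truth$type == "autosomal"))
  expect_true(all(is.na(sim$truth$yx_factor)))
  expect_length(sim$haplotypes, 0)
})

test_that("X/Y transmission holds exactly without genotyping error", {
  sim <- small_sim(n = 120, seed = 5, genotyping_error = 0)
  ds <- sim$dataset
  xy <- sim$truth$contig[sim$truth$type == "XY"]
  role <- ds$samples$role
  mother <- role == "mother"
  daughters <- role == "daughter"
  sons <- role == "son"
  father <- role == "father"
  # diagnostic X/Y SNPs are simulated with mother hom allele1, Y = allele2:
  # the Y allele must appear in the father and every son and never in the
  # mother or a daughter
  for (ct in xy) {
    rows <- which(ds$snps$contig == ct)
    diag_rows <- rows[ds$gt[rows, mother] == 1L]
    carries_y <- ds$gt[diag_rows, , drop = FALSE] >= 2L
    expect_true(all(carries_y[, father]))
    expect_true(all(carries_y[, sons]))
    expect_false(any(carries_y[, mother]))
    expect_false(any(carries_y[, daughters]))
  }
})

test_that("empirical type frequencies match the mixture proportions", {
  sim <- simulate_family(sim_config(n_contigs = 2000, seed = 1))
  freq <- table(factor(sim$truth$type,
                       c("autosomal", "XY", "X_hemizygous"))) / 2000
  expect_lt(max(abs(freq - c(0.73, 0.24, 0.03))), 0.03)
})

test_that("library sizes equal each individual's summed simulated reads", {
  sim <- small_sim(n = 60, seed = 21)
  expect_identical(sim$dataset$samples$library_size,
                   unname(colSums(sim$dataset$counts)))
  # SNP depths are a subset of the totals they feed
  snp_total <- colSums(sim$dataset$d1) + colSums(sim$dataset$d2)
  expect_true(all(snp_total <= sim$dataset$samples$library_size))
})

test_that("X-hemizygous contigs carry no Y allele and less male depth", {
  sim <- small_sim(n = 300, seed = 31, compensated_fraction = 0,
                   type_proportions = c(0.6, 0.2, 0.2),
                   x_polymorphism_rate = 1, sex_bias_spec = quiet_bias)
  hemi <- sim$truth$contig[sim$truth$type == "X_hemizygous" &
                             sim$truth$has_snps]
  expect_gt(length(hemi), 2)
  male <- sim$dataset$samples$sex == "male"
  tot <- sim$dataset$d1 + sim$dataset$d2
  rows <- sim$dataset$snps$contig %in% hemi
  # uncompensated single-copy male X: roughly half the female depth
  expect_lt(mean(tot[rows, male]), 0.7 * mean(tot[rows, !male]))
  expect_true(all(sim$truth$yx_factor[sim$truth$type == "X_hemizygous"] == 0))
})

test_that("haplotype divergence: zero target gives identical sequences", {
  anc <- toy_ancestor(120)
  pair <- mutate_haplotypes(anc, 0, seed = 1)
  expect_identical(pair$x, pair$y)
  expect_identical(pair$realized_ds, 0)
})

test_that("haplotype divergence round-trips through the dS estimator", {
  anc <- toy_ancestor(300)
  for (target in c(0.05, 0.1, 0.17)) {
    pair <- mutate_haplotypes(anc, target, seed = 17)
    est <- ng86_ds(pair)
    expect_lt(abs(est$ds - pair$realized_ds), 0.02)
    expect_lt(abs(est$ds - target), 0.02)
  }
})

test_that("forced stop injection always creates a premature Y stop", {
  anc <- toy_ancestor(80)
  for (s in 1:20) {
    pair <- mutate_haplotypes(anc, 0.05, stop_probability = 1, seed = s)
    expect_true(pair$y_premature_stop)
    expect_true(detect_premature_stops(pair$y)$has_premature_stop)
  }
})

test_that("haplotype mutation validates its input frame", {
  expect_error(mutate_haplotypes("ATGAA", 0.1), "multiple of 3")
  expect_error(mutate_haplotypes("AAATTT", 0.1), "ATG")
  expect_error(mutate_haplotypes("ATGTAACCC", 0.1), "stop")
})
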