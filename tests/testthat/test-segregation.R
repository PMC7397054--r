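test_that("configuration sets match the brute-force enumerator", {
  for (type in c("autosomal", "XY", "X_hemizygous")) {
    ours <- enumerate_configurations(type)
    oracle <- oracle_enumerate(type)
    expect_equal(nrow(ours), length(oracle))
    # every oracle configuration appears with the same offspring
    # distributions
    ours_key <- apply(
      cbind(ours$son_hom1, ours$son_het, ours$son_hom2,
            ours$daughter_hom1, ours$daughter_het, ours$daughter_hom2),
      1, paste, collapse = ",")
    oracle_key <- vapply(oracle, function(cf) {
      paste(c(cf$son, cf$daughter), collapse = ",")
    }, character(1))
    expect_setequal(ours_key, oracle_key)
  }
  expect_equal(nrow(enumerate_configurations("autosomal")), 9)
  expect_equal(nrow(enumerate_configurations("XY")), 12)
  expect_equal(nrow(enumerate_configurations("X_hemizygous")), 6)
  expect_error(enumerate_configurations("XY", c("A", "B", "C")),
               "bi-allelic")
})

test_that("forced X/Y configuration example: sons A/B, daughters A/A", {
  cfg <- enumerate_configurations("XY", c("A", "B"))
  row <- cfg[cfg$mother == "A/A" & cfg$father == "X=A;Y=B", ]
  expect_equal(nrow(row), 1)
  expect_equal(c(row$son_hom1, row$son_het, row$son_hom2), c(0, 1, 0))
  expect_equal(c(row$daughter_hom1, row$daughter_het, row$daughter_hom2),
               c(1, 0, 0))
  auto <- enumerate_configurations("autosomal", c("A", "B"))
  het <- auto[auto$mother == "A/B" & auto$father == "A/B", ]
  expect_equal(c(het$son_hom1, het$son_het, het$son_hom2),
               c(0.25, 0.5, 0.25))
})

test_that("SNP likelihood equals exhaustive enumeration", {
  roles <- c("mother", "father", "son", "son", "daughter", "daughter")
  cases <- list(
    list(gt = c(1L, 2L, 2L, 2L, 1L, 1L), eps = 0.05),    # clean X/Y pattern
    list(gt = c(2L, 1L, 1L, 3L, 2L, 1L), eps = 0.02),    # maternal het
    list(gt = c(1L, 3L, 2L, 2L, 2L, NA), eps = 0.1),     # missing genotype
    list(gt = c(2L, 2L, 1L, 2L, 3L, 2L), eps = 0)        # error-free
  )
  for (case in cases) {
    for (type in c("autosomal", "XY", "X_hemizygous")) {
      expect_equal(
        snp_likelihood(case$gt, roles, type, case$eps),
        oracle_snp_likelihood(case$gt, roles, type, case$eps),
        tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("a perfect X/Y pattern without error beats autosomal", {
  roles <- c("mother", "father", "son", "son", "daughter", "daughter")
  gt <- c(1L, 2L, 2L, 2L, 1L, 1L)   # father-only allele to all sons only
  l_xy <- snp_likelihood(gt, roles, "XY", 0)
  l_auto <- snp_likelihood(gt, roles, "autosomal", 0)
  expect_equal(l_xy, 1 / 12)  # exactly one of 12 configurations, probability 1
  expect_lt(l_auto, l_xy)
})

test_that("an observation impossible under a type has likelihood zero", {
  roles <- c("mother", "father", "son", "daughter")
  # heterozygous son is impossible under X-hemizygous segregation
  gt <- c(2L, 1L, 2L, 2L)
  expect_equal(snp_likelihood(gt, roles, "X_hemizygous", 0), 0)
  expect_error(snp_likelihood(c(NA, NA, NA, NA), roles, "XY", 0.1),
               "no scored")
  expect_error(snp_likelihood(gt, roles, "XY", 1), "epsilon")
})

test_that("EM recovers a zero error rate and a two-type mixture", {
  sim <- small_sim(n = 300, seed = 23, type_proportions = c(0.5, 0.5, 0),
                   genotyping_error = 0, snps_per_contig = list(min = 4L,
                                                               max = 10L))
  fit <- em_fit(sim$dataset)
  expect_lte(fit$epsilon, 0.005)
  # the recoverable estimand is the realized type frequency of the contigs
  # entering the fit
  realized <- table(factor(sim$truth$type[sim$truth$has_snps],
                           c("autosomal", "XY", "X_hemizygous")))
  realized <- realized / sum(realized)
  expect_lt(max(abs(fit$pi - realized)), 0.02)
  expect_true(all(diff(fit$trace) >= -1e-6))
})

test_that("posteriors are normalized and the trace is monotone", {
  sim <- small_sim(n = 80, seed = 29)
  fit <- em_fit(sim$dataset)
  cp <- fit$contig_posterior
  expect_true(all(abs(cp$P_auto + cp$P_XY + cp$P_hemi - 1) < 1e-9))
  st <- fit$snp_table
  expect_true(all(abs(st$post_auto + st$post_xy + st$post_hemi - 1) < 1e-9))
  expect_true(all(diff(fit$trace) >= -1e-6))
})

test_that("contig assignment follows the posterior and error-free rules", {
  sim <- small_sim(n = 250, seed = 37)
  fit <- em_fit(sim$dataset)
  a <- fit$assignments
  # confident autosomal posteriors are assigned autosomal
  conf_auto <- a$P_auto > 0.9 & a$n_informative > 0
  expect_true(all(a$assigned_type[conf_auto] == "autosomal"))
  # sex-linked calls require the error-free-SNP rule
  sl <- a$assigned_type %in% c("XY", "X_hemizygous")
  expect_true(all(a$has_errorfree_sexlinked_snp[sl]))
  # X-hemizygous if and only if sex-linked with zero male Y depth
  expect_true(all(a$zero_y_expression[a$assigned_type == "X_hemizygous"]))
  expect_false(any(a$zero_y_expression[a$assigned_type == "XY"]))
  # no informative SNP means unassigned
  expect_true(all(a$assigned_type[a$n_informative == 0] == "unassigned"))
})

test_that("stochastic EM runs and stays close to the deterministic fit", {
  sim <- small_sim(n = 120, seed = 41)
  det <- em_fit(sim$dataset)
  sem <- em_fit(sim$dataset, stochastic = TRUE, seed = 2, max_iter = 60)
  expect_lt(abs(det$epsilon - sem$epsilon), 0.01)
  expect_lt(max(abs(det$pi - sem$pi)), 0.05)
})

test_that("segregation percentages reproduce the published accounting", {
  expect_equal(unname(segregation_percentages(c(3706, 1196, 168))),
               c(73.10, 23.59, 3.31))
  expect_equal(unname(segregation_percentages(c(1, 0, 0))),
               c(100, 0, 0))
  expect_equal(unname(segregation_percentages(c(10, 10, 20))),
               c(25, 25, 50))
  expect_error(segregation_percentages(c(0, 0, 0)), "zero")
})
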