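test_that("corrected gene-loss arithmetic", {
  expect_equal(corrected_gene_loss(168, 424), 39.62)
  expect_equal(corrected_gene_loss(0, 424), 0)
  expect_equal(corrected_gene_loss(424, 424), 100)
  expect_error(corrected_gene_loss(10, 0), "> 0")
})

test_that("premature stop detection", {
  r <- detect_premature_stops("ATGTAAAAATGA")
  expect_true(r$has_premature_stop)
  expect_equal(r$first_stop_codon, 2L)  # TAA at codon 2 of 4
  r2 <- detect_premature_stops("ATGAAATGA")  # terminal stop only
  expect_false(r2$has_premature_stop)
  expect_true(is.na(r2$first_stop_codon))
  expect_error(detect_premature_stops("ATGAA"), "multiple of 3")
})

test_that("stop injection frequency is recovered within binomial bounds", {
  p_inject <- 0.3
  n <- 400
  anc <- toy_ancestor(120)
  set.seed(71)
  hits <- sum(vapply(seq_len(n), function(i) {
    detect_premature_stops(
      mutate_haplotypes(anc, 0.02, stop_probability = p_inject)$y
    )$has_premature_stop
  }, logical(1)))
  half_width <- qnorm(0.995) * sqrt(p_inject * (1 - p_inject) / n)
  expect_lt(abs(hits / n - p_inject), half_width + 1e-9)
})

test_that("stop contingency reproduces published percentages", {
  r <- stop_contingency(17, 1196, 56, 1196)
  expect_equal(r$percent_x, 1.4)
  expect_equal(r$percent_y, 4.7)
  expect_lt(r$p_value, 1e-4)
  same <- stop_contingency(5, 50, 5, 50)
  expect_equal(same$p_value, 1)
  expect_error(stop_contingency(5, 4, 1, 10), "non-negative|exceed")
})

test_that("Fisher two-tailed p matches exhaustive margin-fixed enumeration", {
  cases <- list(c(2, 10, 8, 10), c(17, 1196, 56, 1196), c(0, 5, 5, 5),
                c(3, 7, 1, 9))
  for (cs in cases) {
    ours <- stop_contingency(cs[1], cs[2], cs[3], cs[4])$p_value
    oracle <- oracle_fisher_p(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3])
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
  # invariance under transposing the table
  expect_equal(stop_contingency(2, 10, 8, 10)$p_value,
               stop_contingency(8, 10, 2, 10)$p_value)
})

test_that("NG86 divergence on hand-counted codon pairs", {
  # identical sequences
  expect_equal(ng86_ds("ATGAAATTT", "ATGAAATTT")$ds, 0)

  # one synonymous third-position change, sites counted by hand:
  # ATG (0 syn sites) + TTT (1/3) + GGT/GGC (1) + AAA (1/3) = 5/3 per
  # sequence; 1 synonymous difference; ps = 3/5
  r <- ng86_ds("ATGTTTGGTAAA", "ATGTTTGGCAAA")
  expect_equal(r$syn_sites, 5 / 3)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$ps, 0.6)
  expect_equal(r$ds, -0.75 * log(1 - 0.8))
  expect_equal(r$nonsyn_diffs, 0)

  # multi-hit codon TTT -> GTA: two minimal pathways, averaged by hand to
  # 0.5 synonymous + 1.5 non-synonymous differences; sites: ATG 0 +
  # (TTT 1/3 | GTA 1) + AAA 1/3, averaged = 1
  r2 <- ng86_ds("ATGTTTAAA", "ATGGTAAAA")
  expect_equal(r2$syn_sites, 1)
  expect_equal(r2$syn_diffs, 0.5)
  expect_equal(r2$nonsyn_diffs, 1.5)
  expect_equal(r2$ds, -0.75 * log(1 - 4 * 0.5 / 3))
  expect_equal(r2$dn, -0.75 * log(1 - 4 * (1.5 / 8) / 3))
})

test_that("NG86 is symmetric and skips N-containing codons", {
  for (s in 1:10) {
    pair <- mutate_haplotypes(toy_ancestor(150, seed = s), 0.12, seed = s)
    expect_equal(ng86_ds(pair$x, pair$y)$ds, ng86_ds(pair$y, pair$x)$ds)
  }
  # an N codon is dropped from both sites and differences
  a <- "ATGTTTGGTAAA"
  b <- "ATGTTTGGCAAA"
  an <- sub("GGT", "GNT", a)
  bn <- sub("GGC", "GNC", b)
  r <- ng86_ds(an, bn)
  expect_equal(r$n_codons_used, 3)
  expect_equal(r$syn_diffs, 0)
  expect_error(ng86_ds("ATGAAA", "ATG"), "equal length")
})

test_that("maximum dS honours the length filter and matches truth", {
  p1 <- mutate_haplotypes(toy_ancestor(120, seed = 1), 0.05,
                          contig = "short_low", seed = 1)
  p2 <- mutate_haplotypes(toy_ancestor(250, seed = 2), 0.15,
                          contig = "short_high", seed = 2)   # 750 bp
  p3 <- mutate_haplotypes(toy_ancestor(400, seed = 3), 0.10,
                          contig = "long_mid", seed = 3)     # 1200 bp
  pairs <- list(p1, p2, p3)
  expect_equal(as.numeric(ds_max(list(p1))), ng86_ds(p1)$ds)
  all_max <- ds_max(pairs)
  expect_equal(attr(all_max, "contig"), "short_high")
  kb_max <- ds_max(pairs, min_length_bp = 1000)
  expect_equal(attr(kb_max, "contig"), "long_mid")
  expect_error(ds_max(pairs, min_length_bp = 10000), "length filter")
  expect_error(ds_max(list()), "no haplotype")
  # estimator tracks the realized truth labels
  truth_max <- max(vapply(pairs, `[[`, numeric(1), "realized_ds"))
  expect_lt(abs(as.numeric(all_max) - truth_max), 0.02)
})

test_that("externally computed dS tables feed the maximum directly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tds\tlength_bp",
               "c1\t0.05\t600", "c2\t0.17\t900", "c3\t0.12\t1500"), path)
  tab <- read_ds_table(path)
  expect_equal(as.numeric(ds_max(tab)), 0.17)
  expect_equal(attr(ds_max(tab, 1000), "contig"), "c3")
  expect_error(ds_max(tab[tab$length_bp > 2000, ]), "length filter|pairs")
})

test_that("molecular-clock ages follow the published arithmetic", {
  per_year <- clock_spec("brassicaceae", "per_year", 1.5e-8)
  expect_equal(age_estimate(0.17, per_year), 11.3)
  expect_equal(age_estimate(0.13, per_year), 8.7)
  expect_equal(age_estimate(0, per_year), 0)
  expect_error(age_estimate(-0.1, per_year), ">= 0")
  # per-generation ages scale linearly with generation time
  g1 <- clock_spec("mutation", "per_generation", 7.1e-9,
                   generation_time_years = 1)
  g15 <- clock_spec("mutation", "per_generation", 7.1e-9,
                    generation_time_years = 1.5)
  a1 <- 0.17 / (2 * 7.1e-9) * 1 / 1e6
  expect_equal(age_estimate(0.17, g1), round(a1, 1))
  expect_equal(age_estimate(0.17, g15), round(a1 * 1.5, 1))
  expect_error(clock_spec("bad", "per_generation", 7.1e-9), "generation")
})
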