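test_that("allelic normalization arithmetic and scaling law", {
  expect_equal(normalize_allelic(0, 1e7, 2), 0)
  expect_equal(normalize_allelic(200, 1e7, 2), 10)
  expect_equal(normalize_allelic(100, 2e7, 4),
               normalize_allelic(100, 1e7, 4) / 2)
  expect_error(normalize_allelic(10, 0, 1), "library")
  expect_error(normalize_allelic(10, 1e6, 0), "n_snps")
})

test_that("autosomal correction equalizes the sex medians", {
  # equal medians: coefficient 1, table unchanged
  eq <- toy_expression(male_vals = c(1, 2, 3), female_vals = c(1, 2, 3))
  out <- autosomal_correction(eq)
  expect_equal(out$coefficient, 1)
  expect_equal(out$sex_linked, eq$sex_linked)

  # male median 2, female median 4: coefficient 0.5, male values doubled
  tw <- toy_expression(male_vals = c(1, 2, 3), female_vals = c(2, 4, 6))
  out2 <- autosomal_correction(tw)
  expect_equal(out2$coefficient, 0.5)
  expect_equal(out2$sex_linked$x_norm[out2$sex_linked$sex == "male"],
               tw$sex_linked$x_norm[tw$sex_linked$sex == "male"] * 2)
  m_med <- median(out2$autosomal$norm[out2$autosomal$sex == "male"])
  f_med <- median(out2$autosomal$norm[out2$autosomal$sex == "female"])
  expect_identical(m_med, f_med)

  # applying the correction again is the identity
  out3 <- autosomal_correction(out2)
  expect_equal(out3$coefficient, 1)
  expect_equal(out3$sex_linked, out2$sex_linked)
})

test_that("correction rejects degenerate autosomal references", {
  bad <- toy_expression(male_vals = c(0, 0, 0), female_vals = c(1, 2, 3))
  expect_error(autosomal_correction(bad), "zero")
  none <- toy_expression(1, 1)
  none$autosomal <- none$autosomal[0, ]
  expect_error(autosomal_correction(none), "autosomal")
})

test_that("per-contig ratios follow their definitions on a toy table", {
  tab <- data.frame(
    contig = rep(c("c1", "c2"), each = 4),
    individual = rep(c("m1", "m2", "f1", "f2"), 2),
    sex = rep(c("male", "male", "female", "female"), 2),
    n_snps = 2L,
    x_depth = 0, y_depth = 0,
    x_norm = c(2, 4, 4, 8, 3, 3, 6, 6),
    y_norm = c(2, 4, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  tab$total_norm <- tab$x_norm + tab$y_norm
  asn <- data.frame(contig = c("c1", "c2"),
                    assigned_type = c("XY", "X_hemizygous"),
                    stringsAsFactors = FALSE)
  r <- contig_ratios(tab, asn)
  # equal X and Y expression in every male: Y/X = 1
  expect_equal(r$yx_ratio[r$contig == "c1"], 1)
  # X-hemizygous contigs get Y/X = 0 by definition
  expect_equal(r$yx_ratio[r$contig == "c2"], 0)
  # Xmale/2Xfemale: c1 mean male X = 3, mean female total = 6
  expect_equal(r$xm_2xf[r$contig == "c1"], 0.5)
  expect_equal(r$log2_xm_2xf[r$contig == "c1"], -1)
  expect_false(any(r$unratioable))
})

test_that("zero-X males are skipped and zero-female contigs flagged", {
  tab <- data.frame(
    contig = "c1",
    individual = c("m1", "m2", "f1"),
    sex = c("male", "male", "female"),
    n_snps = 1L, x_depth = 0, y_depth = 0,
    x_norm = c(0, 2, 0), y_norm = c(3, 1, 0),
    stringsAsFactors = FALSE)
  tab$total_norm <- tab$x_norm + tab$y_norm
  asn <- data.frame(contig = "c1", assigned_type = "XY",
                    stringsAsFactors = FALSE)
  r <- contig_ratios(tab, asn)
  expect_equal(r$yx_ratio, 0.5)  # only the second male contributes
  expect_true(r$unratioable)     # female mean is zero
  expect_true(is.na(r$xm_2xf))
})

test_that("normalization conserves X + Y totals on simulated data", {
  sim <- small_sim(n = 150, seed = 53)
  fit <- em_fit(sim$dataset)
  ae <- allelic_expression(sim$dataset, fit)
  sl <- ae$sex_linked
  expect_true(nrow(sl) > 0)
  expect_equal(sl$total_norm, sl$x_norm + sl$y_norm)
  expect_equal(sl$x_norm + sl$y_norm,
               normalize_allelic(sl$x_depth + sl$y_depth,
                                 sim$dataset$samples$library_size[
                                   match(sl$individual,
                                         sim$dataset$samples$individual)],
                                 sl$n_snps))
  # females never get Y expression
  expect_true(all(sl$y_norm[sl$sex == "female"] == 0))
  expect_true(all(sl$x_norm >= 0))
})

test_that("corrected male and female autosomal medians agree exactly", {
  sim <- small_sim(n = 150, seed = 53)
  fit <- em_fit(sim$dataset)
  ae <- autosomal_correction(allelic_expression(sim$dataset, fit))
  m_med <- median(ae$autosomal$norm[ae$autosomal$sex == "male"])
  f_med <- median(ae$autosomal$norm[ae$autosomal$sex == "female"])
  expect_equal(m_med, f_med, tolerance = 1e-12)
})

test_that("undegenerate, uncompensated contigs centre near log2 = -1", {
  # X/Y contigs with Y/X near 1 and no compensation: the male single X over
  # the female double X should centre on -1 on the log2 scale
  sim <- simulate_family(sim_config(
    n_contigs = 350, type_proportions = c(0.35, 0.6, 0.05),
    compensated_fraction = 0, sex_bias_spec = quiet_bias, seed = 61))
  fit <- em_fit(sim$dataset)
  ae <- autosomal_correction(allelic_expression(sim$dataset, fit))
  r <- contig_ratios(ae$sex_linked, fit$assignments)
  m <- merge(r, sim$truth, by = "contig")
  stratum <- m[m$type == "XY" & m$yx_factor > 0.75, ]
  expect_gt(nrow(stratum), 20)
  expect_gt(median(stratum$log2_xm_2xf, na.rm = TRUE), -1.15)
  expect_lt(median(stratum$log2_xm_2xf, na.rm = TRUE), -0.85)
})
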