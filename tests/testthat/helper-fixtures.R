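# Shared fixtures: small configurations and hand-built toy objects.

quiet_bias <- list(male_frac = 0, female_frac = 0, fold_change = 1,
                   hub_frac = 0.01, hub_fold_change = 30)

small_sim <- function(n = 300, seed = 7, ...) {
  simulate_family(sim_config(n_contigs = n, seed = seed, ...))
}

# A dosage stratum: mostly X-hemizygous contigs, all with maternal X
# polymorphism so they are detectable, no sex-biased genes.
stratum_config <- function(compensated, n = 400, seed = 11) {
  sim_config(n_contigs = n, type_proportions = c(0.35, 0.05, 0.60),
             x_polymorphism_rate = 1,
             compensated_fraction = compensated,
             sex_bias_spec = quiet_bias, seed = seed)
}

# Toy allelic-expression tables for the correction arithmetic.
toy_expression <- function(male_vals, female_vals) {
  auto <- data.frame(
    contig = paste0("a", seq_len(length(male_vals) + length(female_vals))),
    individual = c(paste0("m", seq_along(male_vals)),
                   paste0("f", seq_along(female_vals))),
    sex = c(rep("male", length(male_vals)),
            rep("female", length(female_vals))),
    n_snps = 1L,
    norm = c(male_vals, female_vals),
    stringsAsFactors = FALSE)
  sl <- data.frame(contig = "s1",
                   individual = c("m1", "f1"),
                   sex = c("male", "female"),
                   n_snps = 1L, x_depth = c(10, 20), y_depth = c(5, 0),
                   x_norm = c(1, 2), y_norm = c(0.5, 0),
                   total_norm = c(1.5, 2),
                   stringsAsFactors = FALSE)
  list(sex_linked = sl, autosomal = auto, corrected = FALSE)
}

# A small ancestral ORF built from a fixed codon pool (deterministic).
toy_ancestor <- function(n_codons = 300, seed = 42) {
  set.seed(seed)
  pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(pool, n_codons - 1, replace = TRUE)), collapse = "")
}
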