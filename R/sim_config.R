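#' Configuration for the synthetic family-cross simulator
#'
#' Defines the study conditions emulated by [simulate_family()]: a two-parent
#' cross with sexed F1 offspring, contigs of three segregation types, a
#' per-genotype error rate, per-contig Y/X expression decay, dosage
#' compensation, sex-biased genes and library-size variation.
#'
#' Defaults reproduce the design of the motivating study: 5 sons and 5
#' daughters, segregation-type proportions (0.73, 0.24, 0.03) for
#' (autosomal, X/Y, X-hemizygous), a genotyping-error rate of 0.02, and an
#' X-polymorphism rate of 0.35 (the observed fraction of X/Y contigs with
#' X polymorphism, 424/1196).  The Y/X expression decay of X/Y contigs is
#' drawn from a Beta(2, 1.2) (mean 0.625, matching the reported average Y/X
#' expression ratio of about 0.63); X-hemizygous contigs have a true Y/X
#' factor of exactly 0.
#'
#' @param n_contigs Number of contigs to simulate.
#' @param type_proportions Length-3 vector of segregation-type proportions
#'   (autosomal, X/Y, X-hemizygous); must sum to 1.
#' @param snps_per_contig List with `min` and `max`: per-contig SNP counts are
#'   drawn uniformly on that integer range.
#' @param n_sons,n_daughters Number of sexed F1 offspring of each sex (both
#'   must be at least 1; inference requires both sexes).
#' @param genotyping_error Probability that an observed genotype is replaced
#'   by a uniformly chosen different genotype.
#' @param x_polymorphism_rate Probability that a sex-linked contig carries
#'   two distinct maternal X alleles.  X-hemizygous contigs without maternal
#'   X polymorphism are monomorphic within the family and emit no SNPs.
#' @param yx_decay_distribution List with Beta parameters `shape1`, `shape2`
#'   for the per-contig true Y/X expression factor of X/Y contigs.
#' @param compensated_fraction Probability that a sex-linked contig is
#'   dosage-compensated (male X expression raised so male total matches the
#'   female total).
#' @param sex_bias_spec List with `male_frac`, `female_frac`, `fold_change`
#'   (ordinary sex-biased genes) and `hub_frac`, `hub_fold_change` (a small
#'   set of autosomal genes extremely highly expressed in males, which
#'   inflates male library sizes and creates the apparent global
#'   under-expression of males that the autosomal correction removes).
#' @param library_sizes List with `mean` (expected per-individual total read
#'   count) and `sdlog` (log-normal spread of individual totals).
#' @param base_expression_distribution List with `meanlog`, `sdlog` of the
#'   log-normal per-contig per-copy expected SNP read depth.
#' @param dispersion Negative-binomial size parameter of read depths
#'   (Poisson as `dispersion -> Inf`).
#' @param orf_length_distribution List with `min`, `max` codon counts of
#'   simulated ancestral ORFs.
#' @param ds_target_distribution List with `min`, `max` of the uniform
#'   per-contig target synonymous X-Y divergence.
#' @param stop_probability List with `x`, `y`: probability of injecting a
#'   premature stop codon into the X / Y haplotype of an X/Y contig.
#' @param seed Integer seed; fully determines the simulator output.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_family()]
#' @export
sim_config <- function(n_contigs = 2000,
                       type_proportions = c(0.73, 0.24, 0.03),
                       snps_per_contig = list(min = 2L, max = 10L),
                       n_sons = 5L,
                       n_daughters = 5L,
                       genotyping_error = 0.02,
                       x_polymorphism_rate = 0.35,
                       yx_decay_distribution = list(shape1 = 2, shape2 = 1.2),
                       compensated_fraction = 0.4,
                       sex_bias_spec = list(male_frac = 0.05,
                                            female_frac = 0.015,
                                            fold_change = 4,
                                            hub_frac = 0.01,
                                            hub_fold_change = 30),
                       library_sizes = list(mean = 1e7, sdlog = 0.15),
                       base_expression_distribution = list(meanlog = log(300),
                                                           sdlog = 0.8),
                       dispersion = 8,
                       orf_length_distribution = list(min = 100L, max = 500L),
                       ds_target_distribution = list(min = 0, max = 0.17),
                       stop_probability = list(x = 0.014, y = 0.05),
                       seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    type_proportions = as.numeric(type_proportions),
    snps_per_contig = snps_per_contig,
    n_sons = as.integer(n_sons),
    n_daughters = as.integer(n_daughters),
    genotyping_error = genotyping_error,
    x_polymorphism_rate = x_polymorphism_rate,
    yx_decay_distribution = yx_decay_distribution,
    compensated_fraction = compensated_fraction,
    sex_bias_spec = sex_bias_spec,
    library_sizes = library_sizes,
    base_expression_distribution = base_expression_distribution,
    dispersion = dispersion,
    orf_length_distribution = orf_length_distribution,
    ds_target_distribution = ds_target_distribution,
    stop_probability = stop_probability,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_contigs < 1L) stop("n_contigs must be >= 1", call. = FALSE)
  p <- cfg$type_proportions
  if (length(p) != 3L || any(p < 0)) {
    stop("type_proportions must be 3 non-negative values", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("type_proportions must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
  if (cfg$n_sons < 1L || cfg$n_daughters < 1L) {
    stop("at least one son and one daughter are required: segregation-type ",
         "inference needs offspring of both sexes", call. = FALSE)
  }
  probs <- c(cfg$genotyping_error, cfg$x_polymorphism_rate,
             cfg$compensated_fraction,
             cfg$sex_bias_spec$male_frac, cfg$sex_bias_spec$female_frac,
             cfg$sex_bias_spec$hub_frac,
             cfg$stop_probability$x, cfg$stop_probability$y)
  if (any(probs < 0) || any(probs > 1) || cfg$genotyping_error >= 1) {
    stop("probabilities must lie in [0, 1] (genotyping_error in [0, 1))",
         call. = FALSE)
  }
  if (cfg$snps_per_contig$min < 1L ||
      cfg$snps_per_contig$max < cfg$snps_per_contig$min) {
    stop("snps_per_contig must satisfy 1 <= min <= max", call. = FALSE)
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic family-cross configuration\n")
  cat(sprintf("  contigs: %d  (autosomal/XY/X-hemizygous = %s)\n",
              x$n_contigs, paste(x$type_proportions, collapse = "/")))
  cat(sprintf("  offspring: %d sons + %d daughters\n", x$n_sons, x$n_daughters))
  cat(sprintf("  genotyping error: %.3f   X-polymorphism rate: %.2f\n",
              x$genotyping_error, x$x_polymorphism_rate))
  cat(sprintf("  compensated fraction: %.2f   seed: %d\n",
              x$compensated_fraction, x$seed))
  invisible(x)
}
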