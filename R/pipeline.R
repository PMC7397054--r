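#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full analysis: the simulator block
#' (a [sim_config()]), the inference block (posterior threshold, EM
#' tolerance and iteration cap), the expression block (autosomal correction
#' on/off), the dosage block (classification band, bootstrap settings), the
#' sex-bias block (methods, CPM threshold, consensus rule) and the
#' molecular clocks.  Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param sim A [sim_config()].
#' @param inference List: `posterior_threshold`, `tol`, `max_iter`,
#'   `stochastic`.
#' @param expression List: `correction` (apply the autosomal male/female
#'   correction).
#' @param dosage List: `band`, `scheme`, `n_bootstrap`.
#' @param sexbias List: `methods`, `cpm_threshold`, `min_methods`,
#'   `fdr_cutoff`.
#' @param generation_time_years Generation time used by the per-generation
#'   clock.
#' @param stages Named logical list enabling `expression`, `degeneration`,
#'   `dosage`, `sexbias`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = derive_seed(seed, 1L)),
                            inference = list(posterior_threshold = 0.8,
                                             tol = 1e-6, max_iter = 200L,
                                             stochastic = FALSE),
                            expression = list(correction = TRUE),
                            dosage = list(band = 0.2, scheme = "fine",
                                          n_bootstrap = 500L),
                            sexbias = list(methods = c("edgeR", "limma_voom",
                                                       "permutation"),
                                           cpm_threshold = 0.5,
                                           min_methods = 2L,
                                           fdr_cutoff = 1e-4),
                            generation_time_years = 1,
                            stages = list(expression = TRUE,
                                          degeneration = TRUE,
                                          dosage = TRUE, sexbias = TRUE)) {
  structure(list(seed = as.integer(seed), sim = sim, inference = inference,
                 expression = expression, dosage = dosage, sexbias = sexbias,
                 generation_time_years = generation_time_years,
                 stages = stages),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim)
  pipeline_config(seed = x$seed, sim = sim, inference = x$inference,
                  expression = x$expression, dosage = x$dosage,
                  sexbias = x$sexbias,
                  generation_time_years = x$generation_time_years,
                  stages = x$stages)
}

#' Run the full analysis pipeline on a simulated cross
#'
#' Executes simulate - infer - expression - degeneration - dosage - sexbias
#' as enabled in the configuration, and returns (optionally writes as JSON)
#' a machine-readable summary holding every headline statistic: type counts
#' and percentages, the fitted mixture proportions and error rate, the
#' corrected gene-loss rate, premature-stop contingency, maximum dS and
#' per-clock ages, compensation class counts and sex-bias percentages.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, the summary JSON and
#'   the stage tables are written there.
#' @return List of class `pipeline_result` with `summary` plus the stage
#'   objects (`sim`, `fit`, `assignments`, `expression`, `ratios`,
#'   `degeneration`, `dosage`, `sexbias`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- list()
  summary <- list(seed = config$seed, sim_seed = config$sim$seed)
  on.exit({
    if (!is.null(output_dir)) {
      write_pipeline_outputs(result, summary, output_dir)
    }
  })

  tryCatch({
    sim <- simulate_family(config$sim)
    result$sim <- sim
    summary$n_contigs_simulated <- config$sim$n_contigs
    summary$n_contigs_with_snps <- sum(sim$truth$has_snps)

    stage <- "infer"
    inf <- config$inference
    fit <- em_fit(sim$dataset,
                  tol = inf$tol %||% 1e-6,
                  max_iter = inf$max_iter %||% 200L,
                  stochastic = isTRUE(inf$stochastic),
                  seed = derive_seed(config$seed, 2L))
    thr <- inf$posterior_threshold %||% 0.8
    assignments <- assign_contigs(fit, posterior_threshold = thr)
    result$fit <- fit
    result$assignments <- assignments
    counts_by_type <- table(factor(assignments$assigned_type,
                                   levels = c(TYPE_LEVELS, "unassigned")))
    summary$epsilon_hat <- fit$epsilon
    summary$pi_hat <- as.list(fit$pi)
    summary$assigned_counts <- as.list(counts_by_type)
    n3 <- as.numeric(counts_by_type[TYPE_LEVELS])
    if (sum(n3) > 0) {
      summary$segregation_percentages <-
        as.list(segregation_percentages(n3))
    }
    n_xy_xpoly <- sum(assignments$assigned_type == "XY" &
                        assignments$has_x_polymorphism)
    n_hemi <- sum(assignments$assigned_type == "X_hemizygous")
    summary$n_xy_with_x_polymorphism <- n_xy_xpoly
    if (n_xy_xpoly > 0) {
      summary$corrected_gene_loss_percent <-
        corrected_gene_loss(n_hemi, n_xy_xpoly)
    }

    ratios <- NULL
    if (isTRUE(config$stages$expression)) {
      stage <- "expression"
      ae <- allelic_expression(sim$dataset, fit, assignments,
                               posterior_threshold = thr)
      if (isTRUE(config$expression$correction)) {
        ae <- autosomal_correction(ae)
        summary$correction_coefficient <- ae$coefficient
      }
      ratios <- contig_ratios(ae$sex_linked, assignments)
      result$expression <- ae
      result$ratios <- ratios
      summary$yx_ratio_mean <- mean(ratios$yx_ratio, na.rm = TRUE)
      summary$yx_ratio_median <- median(ratios$yx_ratio, na.rm = TRUE)
    }

    if (isTRUE(config$stages$degeneration)) {
      stage <- "degeneration"
      xy_assigned <- assignments$contig[assignments$assigned_type == "XY"]
      pairs <- sim$haplotypes[intersect(names(sim$haplotypes), xy_assigned)]
      deg <- list()
      if (length(pairs) > 0) {
        dmax_all <- ds_max(pairs, 0)
        deg$ds_max_all <- as.numeric(dmax_all)
        long <- vapply(pairs, function(p) nchar(p$x) >= 1000, logical(1))
        deg$ds_max_1kb <- if (any(long))
          as.numeric(ds_max(pairs, 1000)) else NA_real_
        clocks <- default_clocks(config$generation_time_years)
        deg$ages_myr <- lapply(clocks, function(ck) {
          list(clock = ck$name,
               age_all = age_estimate(deg$ds_max_all, ck),
               age_1kb = if (is.na(deg$ds_max_1kb)) NA_real_ else
                 age_estimate(deg$ds_max_1kb, ck))
        })
        x_stops <- vapply(pairs, function(p)
          detect_premature_stops(p$x)$has_premature_stop, logical(1))
        y_stops <- vapply(pairs, function(p)
          detect_premature_stops(p$y)$has_premature_stop, logical(1))
        deg$stop_contingency <- stop_contingency(sum(x_stops), length(pairs),
                                                 sum(y_stops), length(pairs))
      }
      result$degeneration <- deg
      summary$degeneration <- deg
    }

    if (isTRUE(config$stages$dosage) && !is.null(ratios) &&
        nrow(ratios) > 0) {
      stage <- "dosage"
      retained <- filter_extreme(ratios)
      retained$compensation_class <-
        classify_compensation(retained$log2_xm_2xf,
                              band = config$dosage$band %||% 0.2)
      hemi_log2 <- retained$log2_xm_2xf[retained$assigned_type ==
                                          "X_hemizygous"]
      bimodal <- bimodality_counts(hemi_log2,
                                   band_halfwidth = config$dosage$band %||%
                                     0.2)
      cat_sum <- tryCatch(
        category_summary(retained, scheme = config$dosage$scheme %||% "fine",
                         n_bootstrap = config$dosage$n_bootstrap %||% 500L,
                         seed = derive_seed(config$seed, 3L)),
        error = function(e) NULL)
      result$dosage <- list(retained = retained,
                            excluded = attr(retained, "excluded"),
                            category_summary = cat_sum)
      summary$dosage <- list(
        n_retained = nrow(retained),
        n_excluded = nrow(attr(retained, "excluded") %||%
                            data.frame()),
        compensation_counts = as.list(table(retained$compensation_class)),
        bimodality = as.list(bimodal))
    }

    if (isTRUE(config$stages$sexbias) && !is.null(sim$dataset$counts)) {
      stage <- "sexbias"
      sb <- config$sexbias
      counts <- sim$dataset$counts
      lib <- sim$dataset$samples$library_size
      filtered <- cpm_filter(counts, lib,
                             threshold = sb$cpm_threshold %||% 0.5)
      methods <- sb$methods %||% c("edgeR", "limma_voom", "permutation")
      methods <- methods[vapply(methods, function(m) {
        !(m %in% c("edgeR", "limma_voom")) ||
          requireNamespace(sub("_voom", "", m), quietly = TRUE)
      }, logical(1))]
      de <- run_de_methods(filtered, sim$dataset$samples$sex,
                           methods = methods,
                           seed = derive_seed(config$seed, 4L))
      calls <- consensus_vote(de, min_methods = sb$min_methods %||% 2L,
                              fdr_cutoff = sb$fdr_cutoff %||% 1e-4)
      enrich <- enrichment_summary(calls, assignments)
      result$sexbias <- list(de = de, calls = calls, enrichment = enrich)
      n_male <- sum(calls$consensus & calls$direction == "male",
                    na.rm = TRUE)
      n_female <- sum(calls$consensus & calls$direction == "female",
                      na.rm = TRUE)
      dir_pct <- if (n_male + n_female > 0)
        as.list(setNames(as_percent(c(n_male, n_female)),
                         c("male", "female"))) else NULL
      summary$sexbias <- list(
        n_genes_tested = nrow(filtered),
        n_consensus = sum(calls$consensus),
        n_male_biased = n_male,
        n_female_biased = n_female,
        direction_percentages = dir_pct,
        class_percentages = enrich$classes,
        enrichment_tests = enrich$tests)
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  result$summary <- summary
  class(result) <- "pipeline_result"
  result
}

write_pipeline_outputs <- function(result, summary, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(result$assignments)) {
    write_table_tsv(result$assignments,
                    file.path(output_dir, "assignments.tsv"))
  }
  if (!is.null(result$ratios)) {
    write_table_tsv(result$ratios, file.path(output_dir, "contig_ratios.tsv"))
  }
  if (!is.null(result$sim)) {
    write_table_tsv(result$sim$truth, file.path(output_dir, "truth.tsv"))
  }
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("xyseg pipeline result\n")
  cat(sprintf("  contigs simulated: %s (with SNPs: %s)\n",
              s$n_contigs_simulated, s$n_contigs_with_snps))
  cat(sprintf("  epsilon-hat: %.4f\n", s$epsilon_hat))
  if (!is.null(s$assigned_counts)) {
    cat("  assigned:", paste(names(s$assigned_counts), s$assigned_counts,
                             sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(s$corrected_gene_loss_percent)) {
    cat(sprintf("  corrected gene loss: %.2f%%\n",
                s$corrected_gene_loss_percent))
  }
  invisible(x)
}
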