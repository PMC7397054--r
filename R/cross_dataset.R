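#' Family-cross genotype and allele-depth dataset
#'
#' The central container of the package: per-SNP observed genotypes and
#' per-allele read depths for a two-parent cross with sexed offspring,
#' grouped by contig, plus per-individual library sizes (total mapped read
#' counts) and optionally a raw per-gene count matrix.
#'
#' Genotypes are coded per SNP relative to its two alleles:
#' `1` = homozygous for `allele1`, `2` = heterozygous, `3` = homozygous for
#' `allele2`, `NA` = missing.
#'
#' @param samples Data frame with columns `individual`, `sex`
#'   (`"male"`/`"female"`), `role` (`"mother"`, `"father"`, `"son"`,
#'   `"daughter"`) and `library_size`.
#' @param snps Data frame with columns `contig`, `pos`, `allele1`, `allele2`
#'   (one row per SNP).
#' @param gt Integer matrix (SNPs x individuals) of genotype codes.
#' @param d1,d2 Integer matrices (SNPs x individuals) of read depths for
#'   `allele1` and `allele2`.
#' @param counts Optional numeric matrix (genes x individuals) of raw read
#'   counts used by the sex-bias stage.
#' @return An object of class `cross_dataset`.
#' @export
cross_dataset <- function(samples, snps, gt, d1, d2, counts = NULL) {
  samples <- as.data.frame(samples)
  snps <- as.data.frame(snps)
  need <- c("individual", "sex", "role", "library_size")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (sum(samples$role == "mother") != 1L ||
      sum(samples$role == "father") != 1L) {
    stop("dataset must contain exactly one mother and one father",
         call. = FALSE)
  }
  if (!all(samples$sex %in% c("male", "female")) ||
      !all(samples$role %in% ROLE_LEVELS)) {
    stop("unknown sex or role in sample table", call. = FALSE)
  }
  if (any(samples$sex[samples$role %in% c("mother", "daughter")] != "female") ||
      any(samples$sex[samples$role %in% c("father", "son")] != "male")) {
    stop("sex and role disagree for at least one individual", call. = FALSE)
  }
  n_ind <- nrow(samples)
  n_snp <- nrow(snps)
  for (m in list(gt = gt, d1 = d1, d2 = d2)) {
    if (!is.matrix(m) || nrow(m) != n_snp || ncol(m) != n_ind) {
      stop("gt/d1/d2 must be (n_snps x n_individuals) matrices",
           call. = FALSE)
    }
  }
  if (any(gt < 1L | gt > 3L, na.rm = TRUE)) {
    stop("genotype codes must be 1, 2, 3 or NA", call. = FALSE)
  }
  if (any(d1 < 0, na.rm = TRUE) || any(d2 < 0, na.rm = TRUE)) {
    stop("read depths must be non-negative", call. = FALSE)
  }
  if (n_snp > 0L && any(rowSums(!is.na(gt)) == 0L)) {
    stop("every SNP must have at least one non-missing genotype",
         call. = FALSE)
  }
  colnames(gt) <- colnames(d1) <- colnames(d2) <- samples$individual
  structure(list(samples = samples, snps = snps, gt = gt, d1 = d1, d2 = d2,
                 counts = counts),
            class = "cross_dataset")
}

#' @export
print.cross_dataset <- function(x, ...) {
  cat(sprintf("Family-cross dataset: %d SNPs on %d contigs, %d individuals\n",
              nrow(x$snps), length(unique(x$snps$contig)), nrow(x$samples)))
  tab <- table(x$samples$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$counts)) {
    cat(sprintf("  count matrix: %d genes\n", nrow(x$counts)))
  }
  invisible(x)
}

# Numeric class codes used by the likelihood machinery.
role_class <- function(role) match(role, ROLE_LEVELS)
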