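# File formats.  Positions are 1-based in both the VCF (standard) and the
# TSV dialect; every table is written with a header naming its columns.

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write cross genotypes as VCF 4.2
#'
#' One record per SNP with `GT` and `AD` FORMAT fields; the contig is the
#' CHROM, the SNP index the POS, `allele1` the REF and `allele2` the ALT.
#'
#' @param dataset A [cross_dataset()].
#' @param path Output file.
#' @export
write_genotypes_vcf <- function(dataset, path) {
  samples <- dataset$samples$individual
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xyseg",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- matrix(GT_STRINGS[dataset$gt], nrow = nrow(dataset$gt))
  gt_str[is.na(dataset$gt)] <- "./."
  field <- matrix(paste0(gt_str, ":", dataset$d1, ",", dataset$d2),
                  nrow = nrow(dataset$gt))
  body <- paste(dataset$snps$contig, dataset$snps$pos, ".",
                dataset$snps$allele1, dataset$snps$allele2, ".", "PASS",
                ".", "GT:AD",
                apply(field, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write cross genotypes as flat TSV
#'
#' Long layout, one row per SNP x individual: `contig`, `pos` (1-based),
#' `individual`, `sex`, `role`, `allele1`, `allele2`, `genotype`
#' (e.g. `A/G`, `NA` when missing), `depth1`, `depth2`.
#'
#' @param dataset A [cross_dataset()].
#' @param path Output file.
#' @export
write_genotypes_tsv <- function(dataset, path) {
  n_snp <- nrow(dataset$snps)
  n_ind <- nrow(dataset$samples)
  snp_rep <- dataset$snps[rep(seq_len(n_snp), n_ind), ]
  ind_rep <- dataset$samples[rep(seq_len(n_ind), each = n_snp), ]
  a1 <- snp_rep$allele1
  a2 <- snp_rep$allele2
  code <- as.vector(dataset$gt)
  gt_lab <- ifelse(is.na(code), NA,
                   ifelse(code == 1L, paste0(a1, "/", a1),
                          ifelse(code == 2L, paste0(a1, "/", a2),
                                 paste0(a2, "/", a2))))
  out <- data.frame(contig = snp_rep$contig, pos = snp_rep$pos,
                    individual = ind_rep$individual, sex = ind_rep$sex,
                    role = ind_rep$role,
                    allele1 = a1, allele2 = a2, genotype = gt_lab,
                    depth1 = as.vector(dataset$d1),
                    depth2 = as.vector(dataset$d2),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the sample sheet
#'
#' Columns `individual`, `sex`, `role` and (optionally) `library_size`.
#'
#' @param samples The `samples` data frame of a dataset.
#' @param path TSV file.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "sex", "role")
  if (!all(need %in% names(d))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (r in c("mother", "father")) {
    if (sum(d$role == r) != 1L) {
      stop("sample sheet must name exactly one ", r, call. = FALSE)
    }
  }
  d
}

#' Read a genotype table (VCF 4.2 or TSV dialect) into a dataset
#'
#' Auto-detects the format.  Sample sex and role come from the sample sheet;
#' library sizes come from its `library_size` column when present (else
#' they must be supplied).
#'
#' @param path VCF (GT + AD) or TSV written by [write_genotypes_tsv()].
#' @param sample_sheet Data frame from [read_sample_sheet()] or a path.
#' @param library_sizes Optional named vector overriding the sheet.
#' @return A [cross_dataset()].
#' @export
read_genotype_table <- function(path, sample_sheet, library_sizes = NULL) {
  if (is.character(sample_sheet)) {
    sample_sheet <- read_sample_sheet(sample_sheet)
  }
  if (!is.null(library_sizes)) {
    sample_sheet$library_size <- library_sizes[sample_sheet$individual]
  }
  if (is.null(sample_sheet$library_size)) {
    stop("library sizes are required (sample-sheet column or argument)",
         call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    read_genotypes_vcf(path, sample_sheet)
  } else {
    read_genotypes_tsv(path, sample_sheet)
  }
}

read_genotypes_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  missing_samples <- setdiff(samples$individual, colnames(gt_raw))
  if (length(missing_samples) > 0L) {
    stop("unknown sample(s) in sheet, absent from VCF: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  gt_raw <- gt_raw[, samples$individual, drop = FALSE]
  ad_raw <- ad_raw[, samples$individual, drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  norm <- gsub("\\|", "/", gt_raw)
  code[norm == "0/0"] <- 1L
  code[norm %in% c("0/1", "1/0")] <- 2L
  code[norm == "1/1"] <- 3L
  bad <- !is.na(norm) & norm != "./." & is.na(code)
  if (any(bad)) {
    stop("malformed GT value(s), e.g. ", norm[bad][1L], call. = FALSE)
  }
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 2L & !is.na(x))) {
      stop("AD arity mismatch: expected 2 depths per genotype",
           call. = FALSE)
    }
    num <- suppressWarnings(vapply(parts, function(p)
      as.numeric(p[1:2]), numeric(2)))
    num
  }
  ad <- split_ad(as.vector(ad_raw))
  d1 <- matrix(ad[1L, ], nrow(gt_raw), ncol(gt_raw))
  d2 <- matrix(ad[2L, ], nrow(gt_raw), ncol(gt_raw))
  d1[is.na(d1)] <- 0
  d2[is.na(d2)] <- 0
  snps <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                     allele1 = fix$REF, allele2 = fix$ALT,
                     stringsAsFactors = FALSE)
  cross_dataset(samples, snps, code, d1, d2)
}

read_genotypes_tsv <- function(path, samples) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "individual", "allele1", "allele2",
            "genotype", "depth1", "depth2")
  if (!all(need %in% names(d))) {
    stop("genotype TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(d$individual), samples$individual)
  if (length(unknown) > 0L) {
    stop("unknown sample(s) in genotype table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(d$contig, d$pos)
  snp_keys <- unique(key)
  snp_idx <- match(key, snp_keys)
  ind_idx <- match(d$individual, samples$individual)
  first_rows <- match(snp_keys, key)
  snps <- data.frame(contig = d$contig[first_rows], pos = d$pos[first_rows],
                     allele1 = d$allele1[first_rows],
                     allele2 = d$allele2[first_rows],
                     stringsAsFactors = FALSE)
  n_snp <- nrow(snps)
  n_ind <- nrow(samples)
  code <- matrix(NA_integer_, n_snp, n_ind)
  d1 <- matrix(0, n_snp, n_ind)
  d2 <- matrix(0, n_snp, n_ind)
  hom1 <- paste0(d$allele1, "/", d$allele1)
  het <- paste0(d$allele1, "/", d$allele2)
  hom2 <- paste0(d$allele2, "/", d$allele2)
  val <- ifelse(is.na(d$genotype), NA_integer_,
                ifelse(d$genotype == hom1, 1L,
                       ifelse(d$genotype == het, 2L,
                              ifelse(d$genotype == hom2, 3L, -1L))))
  if (any(val == -1L, na.rm = TRUE)) {
    stop("malformed genotype string(s), e.g. ",
         d$genotype[which(val == -1L)[1L]], call. = FALSE)
  }
  idx <- cbind(snp_idx, ind_idx)
  code[idx] <- val
  d1[idx] <- d$depth1
  d2[idx] <- d$depth2
  cross_dataset(samples, snps, code, d1, d2)
}

#' Write / read a gene x individual count matrix as TSV
#'
#' @param counts Numeric matrix with gene rownames and individual colnames.
#' @param path TSV file.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' Write truth labels or assignment tables as TSV
#'
#' @param table Data frame.
#' @param path TSV file.
#' @export
write_table_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
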