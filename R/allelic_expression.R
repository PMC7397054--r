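#' Normalize an allele read depth by library size and SNP count
#'
#' Allelic expression is measured from reads spanning diagnostic X/Y SNPs
#' and normalized by the individual's library size and the number of
#' studied SNPs in the contig, scaled per million:
#' `depth / (library_size * n_snps) * 1e6`.
#'
#' @param depth Summed allele read depth (vectorized).
#' @param library_size Total mapped read count of the individual (> 0).
#' @param n_snps Number of studied SNPs in the contig (>= 1).
#' @return Normalized expression value(s).
#' @examples
#' normalize_allelic(200, 1e7, 2)  # 10
#' @export
normalize_allelic <- function(depth, library_size, n_snps) {
  if (any(library_size <= 0)) stop("library size must be > 0", call. = FALSE)
  if (any(n_snps < 1)) stop("n_snps must be >= 1", call. = FALSE)
  depth / (library_size * n_snps) * 1e6
}

#' Per-contig, per-individual allelic expression of sex-linked contigs
#'
#' For every contig assigned X/Y or X-hemizygous, sums X-allele and Y-allele
#' read depths over the retained sex-linked SNPs usable for allele-specific
#' measurement (X/Y-diagnostic SNPs, where the Y allele is distinct from the
#' X alleles, plus X-hemizygous-type SNPs), normalizes by library size and
#' SNP count, and also computes the normalized total expression of retained
#' autosomal SNPs on contigs assigned autosomal (used by
#' [autosomal_correction()]).
#'
#' In males the X depth at a diagnostic SNP is the total minus the Y-allele
#' depth; in females the Y component is identically 0 and the X depth is the
#' total over both X copies.
#'
#' @param dataset A [cross_dataset()].
#' @param fit A `segregation_fit`.
#' @param assignments Contig assignments (defaults to the fit's).
#' @param posterior_threshold Per-SNP retention threshold (as in
#'   [assign_contigs()]).
#' @return List with `sex_linked` (contig x individual table: depths,
#'   `x_norm`, `y_norm`, `total_norm`, `n_snps`) and `autosomal`
#'   (contig x individual normalized total expression), both uncorrected.
#' @export
allelic_expression <- function(dataset, fit,
                               assignments = fit$assignments,
                               posterior_threshold = 0.8) {
  st <- fit$snp_table
  p_sl <- st$post_xy + st$post_hemi
  retained <- pmax(st$post_auto, p_sl) > posterior_threshold
  sl_snp <- retained & (p_sl > st$post_auto)
  usable <- sl_snp & (st$diagnostic_xy | st$best_sl_type == "X_hemizygous")

  samples <- dataset$samples
  male <- samples$sex == "male"
  lib <- samples$library_size
  total <- dataset$d1 + dataset$d2

  idx_by_contig <- split(seq_len(nrow(st)), st$contig)
  sl_contigs <- assignments$contig[assignments$assigned_type %in%
                                     c("XY", "X_hemizygous")]
  out_sl <- list()
  for (ct in sl_contigs) {
    idx <- idx_by_contig[[ct]]
    idx <- idx[usable[idx]]
    if (length(idx) == 0L) next
    ns <- length(idx)
    tot <- total[idx, , drop = FALSE]
    ydep <- matrix(0, ns, ncol(tot))
    is_xy <- st$best_sl_type[idx] == "XY"
    if (any(is_xy)) {
      ya <- st$y_allele[idx][is_xy]
      dsel <- ifelse(matrix(ya == 1L, sum(is_xy), sum(male)),
                     dataset$d1[idx[is_xy], male, drop = FALSE],
                     dataset$d2[idx[is_xy], male, drop = FALSE])
      ydep[is_xy, male] <- dsel
    }
    xdep <- tot - ydep
    out_sl[[ct]] <- data.frame(
      contig = ct, individual = samples$individual, sex = samples$sex,
      n_snps = ns,
      x_depth = colSums(xdep), y_depth = colSums(ydep),
      x_norm = normalize_allelic(colSums(xdep), lib, ns),
      y_norm = normalize_allelic(colSums(ydep), lib, ns),
      stringsAsFactors = FALSE)
  }
  sex_linked <- if (length(out_sl) > 0) do.call(rbind, out_sl) else
    data.frame(contig = character(0), individual = character(0),
               sex = character(0), n_snps = integer(0),
               x_depth = numeric(0), y_depth = numeric(0),
               x_norm = numeric(0), y_norm = numeric(0))
  sex_linked$total_norm <- sex_linked$x_norm + sex_linked$y_norm
  rownames(sex_linked) <- NULL

  auto_contigs <- assignments$contig[assignments$assigned_type == "autosomal"]
  out_auto <- list()
  auto_retained <- retained & st$post_auto >= p_sl
  for (ct in auto_contigs) {
    idx <- idx_by_contig[[ct]]
    idx <- idx[auto_retained[idx]]
    if (length(idx) == 0L) next
    dep <- colSums(total[idx, , drop = FALSE])
    out_auto[[ct]] <- data.frame(
      contig = ct, individual = samples$individual, sex = samples$sex,
      n_snps = length(idx),
      norm = normalize_allelic(dep, lib, length(idx)),
      stringsAsFactors = FALSE)
  }
  autosomal <- if (length(out_auto) > 0) do.call(rbind, out_auto) else
    data.frame(contig = character(0), individual = character(0),
               sex = character(0), n_snps = integer(0), norm = numeric(0))
  rownames(autosomal) <- NULL

  list(sex_linked = sex_linked, autosomal = autosomal, corrected = FALSE)
}

#' Autosomal male/female expression correction
#'
#' Males can appear globally less expressed than females after library-size
#' normalization (a few genes extremely highly expressed in developing male
#' organs inflate male libraries).  The correction coefficient is the ratio
#' of the median male autosomal expression to the median female autosomal
#' expression; every male expression value (sex-linked and autosomal) is
#' divided by it, making the male and female autosomal medians equal.
#'
#' @param table Output of [allelic_expression()] (element `sex_linked`), or
#'   the full list returned by that function.
#' @param autosomal_contig_expression The `autosomal` element (ignored when
#'   `table` is the full list).
#' @return List with `coefficient` and the corrected `sex_linked` and
#'   `autosomal` tables (flagged `corrected = TRUE`).
#' @export
autosomal_correction <- function(table, autosomal_contig_expression = NULL) {
  if (is.list(table) && !is.data.frame(table) &&
      all(c("sex_linked", "autosomal") %in% names(table))) {
    auto <- table$autosomal
    sl <- table$sex_linked
  } else {
    sl <- table
    auto <- autosomal_contig_expression
  }
  if (is.null(auto) || nrow(auto) == 0L) {
    stop("at least one autosomal contig with expression is required",
         call. = FALSE)
  }
  med_m <- median(auto$norm[auto$sex == "male"])
  med_f <- median(auto$norm[auto$sex == "female"])
  if (!is.finite(med_m) || !is.finite(med_f) || med_m == 0 || med_f == 0) {
    stop("male or female autosomal median expression is zero", call. = FALSE)
  }
  coefficient <- med_m / med_f
  male_sl <- sl$sex == "male"
  for (col in c("x_norm", "y_norm", "total_norm")) {
    sl[[col]][male_sl] <- sl[[col]][male_sl] / coefficient
  }
  male_auto <- auto$sex == "male"
  auto$norm[male_auto] <- auto$norm[male_auto] / coefficient
  list(coefficient = coefficient, sex_linked = sl, autosomal = auto,
       corrected = TRUE)
}

#' Per-contig Y/X and Xmale/2Xfemale expression ratios
#'
#' The Y/X ratio is computed for each male separately (his normalized
#' Y-allele over X-allele expression) and averaged across males; males with
#' zero X expression are skipped, and X-hemizygous contigs get a Y/X ratio
#' of 0.  Xmale is the mean corrected male X expression, 2Xfemale the mean
#' female total expression at the same SNPs; their log2 ratio is the
#' dosage-compensation statistic (expected at -1 with no compensation,
#' 0 with full compensation).
#'
#' @param table Corrected `sex_linked` table (from [autosomal_correction()]).
#' @param assignments Contig assignment table.
#' @return One row per sex-linked contig: `yx_ratio`, `xmale`, `two_xfemale`,
#'   `ymale`, `male_total`, `xm_2xf`, `log2_xm_2xf`, and flags
#'   (`unratioable`: zero female or male mean; `yx_undefined`: every male
#'   had zero X expression).
#' @export
contig_ratios <- function(table, assignments) {
  if (nrow(table) == 0L) {
    stop("empty allelic-expression table", call. = FALSE)
  }
  type <- setNames(assignments$assigned_type, assignments$contig)
  contigs <- unique(table$contig)
  rows <- lapply(contigs, function(ct) {
    d <- table[table$contig == ct, ]
    males <- d[d$sex == "male", ]
    females <- d[d$sex == "female", ]
    hemi <- identical(unname(type[ct]), "X_hemizygous")
    ok <- males$x_norm > 0
    yx_undefined <- FALSE
    if (hemi) {
      yx <- 0
    } else if (any(ok)) {
      yx <- mean(males$y_norm[ok] / males$x_norm[ok])
    } else {
      yx <- NA_real_
      yx_undefined <- TRUE
    }
    xmale <- mean(males$x_norm)
    ymale <- mean(males$y_norm)
    male_total <- mean(males$total_norm)
    two_xf <- mean(females$total_norm)
    unratioable <- two_xf == 0 || xmale == 0
    xm_2xf <- if (unratioable) NA_real_ else xmale / two_xf
    data.frame(contig = ct, assigned_type = unname(type[ct]),
               n_snps = d$n_snps[1L],
               yx_ratio = yx, xmale = xmale, ymale = ymale,
               male_total = male_total, two_xfemale = two_xf,
               xm_2xf = xm_2xf,
               log2_xm_2xf = if (is.na(xm_2xf)) NA_real_ else log2(xm_2xf),
               unratioable = unratioable, yx_undefined = yx_undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
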