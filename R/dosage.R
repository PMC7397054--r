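#' Exclude contigs with extreme Xmale/2Xfemale ratios
#'
#' Contigs with Xmale/2Xfemale above 8 or under 0.125 are strongly
#' sex-biased in X expression and are not informative about dosage
#' compensation; they are excluded ("above"/"under" read strictly, so the
#' boundary values 8 and 0.125 are retained).  Contigs whose ratio is
#' undefined (zero male or female expression) are excluded with a reason.
#'
#' @param records Data frame from [contig_ratios()] (needs `xm_2xf`).
#' @param lower,upper Inclusive retention bounds.
#' @return The retained rows; excluded rows (with an `excluded_reason`
#'   column) are available as `attr(, "excluded")`.
#' @export
filter_extreme <- function(records, lower = 0.125, upper = 8) {
  undefined <- is.na(records$xm_2xf)
  out_of_band <- !undefined & (records$xm_2xf > upper |
                                 records$xm_2xf < lower)
  excluded <- records[undefined | out_of_band, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    excluded$excluded_reason <- ifelse(is.na(excluded$xm_2xf),
                                       "undefined_ratio", "extreme_ratio")
  }
  retained <- records[!(undefined | out_of_band), , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "excluded") <- excluded
  retained
}

#' Classify dosage-compensation status from the log2 Xmale/2Xfemale ratio
#'
#' Contigs expressed equally in males and females (log2 ratio `0 +/- band`)
#' are compensated; contigs expressed twice as much in females
#' (log2 ratio `-1 +/- band`) are non-compensated; everything else is
#' unclassified.  Bands are closed.
#'
#' @param log2_ratio Numeric vector of log2(Xmale/2Xfemale) values.
#' @param band Half-width of the classification bands (default 0.2; a wider
#'   0.5 band can be used for robustness checks).
#' @return Character vector: `"compensated"`, `"non_compensated"`,
#'   `"unclassified"` (`NA` stays `NA`).
#' @export
classify_compensation <- function(log2_ratio, band = 0.2) {
  ifelse(is.na(log2_ratio), NA_character_,
         ifelse(abs(log2_ratio) <= band, "compensated",
                ifelse(abs(log2_ratio + 1) <= band, "non_compensated",
                       "unclassified")))
}

#' Bin contigs by Y/X expression ratio
#'
#' Half-open intervals `(a, b]` with Y/X = 0 (X-hemizygous) as its own
#' category.  The `"coarse"` scheme uses 0, (0, 0.5], (0.5, 1], > 1; the
#' `"fine"` scheme uses 0 and five 0.25-wide bins up to 1.25 (ratios above
#' 1.25 are excluded, returned as `NA`).
#'
#' @param yx_ratio Numeric vector of Y/X ratios (>= 0).
#' @param scheme `"coarse"` or `"fine"`.
#' @return Factor of bin labels (ordered by increasing Y/X).
#' @export
bin_by_yx <- function(yx_ratio, scheme = c("coarse", "fine")) {
  scheme <- match.arg(scheme)
  if (any(yx_ratio < 0, na.rm = TRUE)) {
    stop("Y/X ratios must be >= 0", call. = FALSE)
  }
  if (scheme == "coarse") {
    breaks <- c(0, 0.5, 1, Inf)
    labels <- c("(0,0.5]", "(0.5,1]", ">1")
  } else {
    breaks <- c(0, 0.25, 0.5, 0.75, 1, 1.25)
    labels <- c("(0,0.25]", "(0.25,0.5]", "(0.5,0.75]", "(0.75,1]",
                "(1,1.25]")
  }
  bin <- as.character(cut(yx_ratio, breaks = breaks, labels = labels,
                          right = TRUE))
  bin[!is.na(yx_ratio) & yx_ratio == 0] <- "0"
  factor(bin, levels = c("0", labels))
}

#' Per-category expression medians normalized by female XX expression
#'
#' For each Y/X category, computes the median over contigs of female XX
#' expression, male X, male Y and male total (X+Y) expression, normalizes
#' all medians by the category's female XX median, and attaches 95%
#' percentile-bootstrap confidence intervals (resampling contigs).  Also
#' emits the two reference predictions for male X: full dosage compensation
#' (`Xmale = XXfemale - Ymale`) and none (`Xmale = 0.5 * XXfemale`).
#'
#' @param records Retained, classified records (from [filter_extreme()];
#'   needs `yx_ratio`, `xmale`, `ymale`, `male_total`, `two_xfemale`).
#' @param scheme Binning scheme passed to [bin_by_yx()].
#' @param n_bootstrap Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return One row per non-empty category: `n`, normalized medians
#'   (`xxfemale` is 1 by construction), their CIs, and the two predictions.
#' @export
category_summary <- function(records, scheme = "fine", n_bootstrap = 2000,
                             seed = 1) {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  bins <- bin_by_yx(records$yx_ratio, scheme)
  set.seed(seed)
  out <- list()
  for (lv in levels(bins)) {
    d <- records[!is.na(bins) & bins == lv, , drop = FALSE]
    if (nrow(d) == 0L) next
    stat <- function(idx) {
      ref <- median(d$two_xfemale[idx])
      c(xxfemale = 1,
        xmale = median(d$xmale[idx]) / ref,
        ymale = median(d$ymale[idx]) / ref,
        xy_male = median(d$male_total[idx]) / ref)
    }
    point <- stat(seq_len(nrow(d)))
    boots <- replicate(n_bootstrap,
                       stat(sample.int(nrow(d), replace = TRUE)))
    ci <- apply(boots, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
    out[[lv]] <- data.frame(
      category = lv, n = nrow(d),
      xxfemale = 1,
      xmale = point[["xmale"]],
      xmale_lo = ci[1L, "xmale"], xmale_hi = ci[2L, "xmale"],
      ymale = point[["ymale"]],
      ymale_lo = ci[1L, "ymale"], ymale_hi = ci[2L, "ymale"],
      xy_male = point[["xy_male"]],
      xy_male_lo = ci[1L, "xy_male"], xy_male_hi = ci[2L, "xy_male"],
      pred_full_compensation = 1 - point[["ymale"]],
      pred_no_compensation = 0.5,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("every category is empty", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bimodality counts of the X-hemizygous log2 ratio distribution
#'
#' Counts X-hemizygous contigs whose log2(Xmale/2Xfemale) falls within a
#' band around -1 (no compensation) and around 0 (total compensation),
#' summarizing the bimodal distribution expected when a subset of
#' X-hemizygous genes is fully compensated.
#'
#' @param log2_ratio Numeric vector (X-hemizygous contigs only).
#' @param band_halfwidth Band half-width (default 0.2).
#' @return Named vector `c(n_near_minus1, n_near_0)`.
#' @export
bimodality_counts <- function(log2_ratio, band_halfwidth = 0.2) {
  x <- log2_ratio[!is.na(log2_ratio)]
  c(n_near_minus1 = sum(abs(x + 1) <= band_halfwidth),
    n_near_0 = sum(abs(x) <= band_halfwidth))
}
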