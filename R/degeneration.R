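#' Corrected Y gene-loss rate
#'
#' X-hemizygous contigs (lost or silenced Y copies) can only be detected
#' where the X carries polymorphism, so their raw count underestimates gene
#' loss.  The corrected rate expresses the number of X-hemizygous contigs
#' relative to the number of X/Y contigs with X polymorphism, as a
#' percentage.
#'
#' @param n_hemizygous Number of X-hemizygous contigs.
#' @param n_xy_with_x_polymorphism Number of X/Y contigs with X polymorphism
#'   (> 0).
#' @return Percentage, rounded to two decimals.
#' @examples
#' corrected_gene_loss(168, 424)  # 39.62
#' @export
corrected_gene_loss <- function(n_hemizygous, n_xy_with_x_polymorphism) {
  if (n_xy_with_x_polymorphism <= 0) {
    stop("n_xy_with_x_polymorphism must be > 0", call. = FALSE)
  }
  if (n_hemizygous < 0) stop("counts must be non-negative", call. = FALSE)
  round(100 * n_hemizygous / n_xy_with_x_polymorphism, 2)
}

#' Detect premature stop codons
#'
#' A stop codon (TAA/TAG/TGA, standard code) at any codon position before
#' the final codon is premature; a terminal stop is not.
#'
#' @param sequence In-frame nucleotide sequence (length a multiple of 3).
#' @return List with `has_premature_stop` and `first_stop_codon` (1-based
#'   codon position of the first premature stop, `NA` if none).
#' @export
detect_premature_stops <- function(sequence) {
  codons <- split_codons(sequence)
  k <- length(codons)
  internal <- if (k > 1L) which(is_stop_codon(codons[-k])) else integer(0)
  list(has_premature_stop = length(internal) > 0L,
       first_stop_codon = if (length(internal) > 0L) internal[1L]
       else NA_integer_)
}

#' Premature-stop contingency analysis of X versus Y alleles
#'
#' Compares the frequency of premature stop codons between X and Y alleles
#' with a two-tailed Fisher exact test on the 2x2 (stop / no stop) x (X / Y)
#' table.
#'
#' @param n_x_stop,n_x_total Stops and totals for X alleles.
#' @param n_y_stop,n_y_total Stops and totals for Y alleles.
#' @return List with `percent_x`, `percent_y` (one decimal) and `p_value`.
#' @examples
#' stop_contingency(17, 1196, 56, 1196)
#' @export
stop_contingency <- function(n_x_stop, n_x_total, n_y_stop, n_y_total) {
  cells <- c(n_x_stop, n_x_total - n_x_stop, n_y_stop, n_y_total - n_y_stop)
  if (any(cells < 0)) {
    stop("stop counts must not exceed totals and must be non-negative",
         call. = FALSE)
  }
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  list(percent_x = round(100 * n_x_stop / n_x_total, 1),
       percent_y = round(100 * n_y_stop / n_y_total, 1),
       p_value = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Pairwise synonymous and non-synonymous divergence (Nei-Gojobori 1986)
#'
#' Counts synonymous and non-synonymous sites (per-position fractions of
#' synonymous changes, averaged over the two sequences) and differences
#' (averaged over all minimal mutational pathways for multi-hit codons,
#' excluding pathways through stop codons), then applies the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4p/3)`.  Codons containing N or a stop in
#' either sequence are skipped.  Symmetric in its arguments.
#'
#' @param x,y Aligned in-frame sequences of equal length, or a single
#'   `hap_pair` passed as `x`.
#' @return List with `ds`, `dn`, `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `ps`, `pn` and `n_codons_used`.
#' @export
ng86_ds <- function(x, y = NULL) {
  if (inherits(x, "hap_pair")) {
    y <- x$y
    x <- x$x
  }
  if (nchar(x) != nchar(y)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  cx <- split_codons(x)
  cy <- split_codons(y)
  ok <- !grepl("N", cx, fixed = TRUE) & !grepl("N", cy, fixed = TRUE) &
    !is_stop_codon(cx) & !is_stop_codon(cy)
  cx <- cx[ok]
  cy <- cy[ok]
  if (length(cx) == 0L) stop("no usable codons", call. = FALSE)

  syn_tab <- syn_fraction_table()
  s_x <- sum(rowSums(syn_tab[cx, , drop = FALSE]))
  s_y <- sum(rowSums(syn_tab[cy, , drop = FALSE]))
  syn_sites <- (s_x + s_y) / 2
  nonsyn_sites <- 3 * length(cx) - syn_sites

  sd <- 0
  nd <- 0
  diff <- which(cx != cy)
  for (i in diff) {
    d <- codon_path_diffs(cx[i], cy[i])
    sd <- sd + d[["syn"]]
    nd <- nd + d[["nonsyn"]]
  }
  ps <- if (syn_sites > 0) sd / syn_sites else 0
  pn <- if (nonsyn_sites > 0) nd / nonsyn_sites else 0
  if (ps >= 0.75) {
    stop("proportion of synonymous differences >= 3/4; Jukes-Cantor ",
         "correction undefined", call. = FALSE)
  }
  ds <- if (ps > 0) -0.75 * log(1 - 4 * ps / 3) else 0
  dn <- if (pn >= 0.75) NA_real_ else if (pn > 0) -0.75 * log(1 - 4 * pn / 3)
  else 0
  if (is.na(dn)) {
    warning("proportion of non-synonymous differences >= 3/4; dn undefined",
            call. = FALSE)
  }
  list(ds = ds, dn = dn, syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       syn_diffs = unname(sd), nonsyn_diffs = unname(nd), ps = ps, pn = pn,
       n_codons_used = length(cx))
}

#' Maximum synonymous divergence over qualifying haplotype pairs
#'
#' The oldest gametolog pairs (the first to stop recombining) carry the
#' highest X-Y synonymous divergence, which dates the recombination arrest.
#'
#' @param pairs List of `hap_pair` objects, or a data frame of externally
#'   computed per-contig divergences (columns `contig`, `ds`, and
#'   `length_bp` when a length filter is wanted), e.g. from
#'   [read_ds_table()].
#' @param min_length_bp Minimum aligned length in bp (0 = no filter).
#' @return The maximum `ds` over qualifying pairs, with the contributing
#'   contig as attribute `"contig"`.
#' @export
ds_max <- function(pairs, min_length_bp = 0) {
  if (is.data.frame(pairs)) {
    keep <- if (min_length_bp > 0) {
      if (is.null(pairs$length_bp)) {
        stop("length filtering needs a length_bp column", call. = FALSE)
      }
      pairs$length_bp >= min_length_bp
    } else rep(TRUE, nrow(pairs))
    if (!any(keep)) {
      stop("no pair passes the length filter (", min_length_bp, " bp)",
           call. = FALSE)
    }
    d <- pairs[keep, ]
    best <- which.max(d$ds)
    return(structure(d$ds[best], contig = d$contig[best]))
  }
  if (length(pairs) == 0L) stop("no haplotype pairs supplied", call. = FALSE)
  keep <- vapply(pairs, function(p) nchar(p$x) >= min_length_bp, logical(1))
  if (!any(keep)) {
    stop("no pair passes the length filter (", min_length_bp, " bp)",
         call. = FALSE)
  }
  pairs <- pairs[keep]
  ds <- vapply(pairs, function(p) ng86_ds(p)$ds, numeric(1))
  best <- which.max(ds)
  structure(ds[best], contig = pairs[[best]]$contig)
}

#' Read externally computed per-contig dS values
#'
#' Adapter for users who prefer a codon-model ML estimate of dS over the
#' in-package counting estimator: a TSV with columns `contig`, `ds` and
#' optionally `length_bp` feeds directly into [ds_max()].
#'
#' @param path TSV file.
#' @return Data frame with `contig`, `ds` (and `length_bp` if present).
#' @export
read_ds_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig", "ds") %in% names(d))) {
    stop("dS table must have columns: contig, ds", call. = FALSE)
  }
  if (any(d$ds < 0)) stop("dS values must be >= 0", call. = FALSE)
  d
}

#' Molecular clock specification
#'
#' @param name Clock label.
#' @param rate_type `"per_year"` (substitutions/synonymous site/year) or
#'   `"per_generation"` (substitutions/site/generation, mu).
#' @param rate Positive rate.
#' @param generation_time_years Generation time in years (required for
#'   per-generation clocks).
#' @return An object of class `clock_spec`.
#' @export
clock_spec <- function(name, rate_type = c("per_year", "per_generation"),
                       rate, generation_time_years = NULL) {
  rate_type <- match.arg(rate_type)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (rate_type == "per_generation" &&
      (is.null(generation_time_years) || generation_time_years <= 0)) {
    stop("per-generation clocks need a positive generation time",
         call. = FALSE)
  }
  structure(list(name = name, rate_type = rate_type, rate = rate,
                 generation_time_years = generation_time_years),
            class = "clock_spec")
}

#' Default molecular clocks
#'
#' The three Brassicaceae-derived clocks used to date the sex chromosomes:
#' 1.5e-8 substitutions/synonymous site/year (fossil-calibrated divergence
#' of *Barbarea* and *Cardamine*), 7.1e-9 substitutions/site/generation
#' (spontaneous mutation rate in *Arabidopsis thaliana*; generation time
#' configurable, 1 year by default), and 4e-9 substitutions/synonymous
#' site/year (six-fossil Brassicales calibration).
#'
#' @param generation_time_years Generation time for the per-generation
#'   clock.
#' @return List of [clock_spec()] objects.
#' @export
default_clocks <- function(generation_time_years = 1) {
  list(
    clock_spec("brassicaceae_divergence_1.5e-8_per_year", "per_year", 1.5e-8),
    clock_spec("arabidopsis_mutation_7.1e-9_per_generation",
               "per_generation", 7.1e-9,
               generation_time_years = generation_time_years),
    clock_spec("brassicales_fossils_4e-9_per_year", "per_year", 4e-9)
  )
}

#' Age of the sex chromosomes from maximum synonymous divergence
#'
#' For per-year clocks, `age_years = ds_max / rate`; for per-generation
#' clocks, `age_years = ds_max / (2 * mu) * generation_time` (the divergence
#' accumulates on both the X and Y lineages, hence the factor 2 on the
#' per-generation mutation rate).  Reported in Myr to one decimal.
#'
#' @param ds_max Maximum synonymous divergence (>= 0).
#' @param clock A [clock_spec()].
#' @return Age in Myr, rounded to one decimal.
#' @examples
#' age_estimate(0.17, clock_spec("brassicaceae", "per_year", 1.5e-8))  # 11.3
#' @export
age_estimate <- function(ds_max, clock) {
  stopifnot(inherits(clock, "clock_spec"))
  if (ds_max < 0) stop("ds_max must be >= 0", call. = FALSE)
  years <- if (clock$rate_type == "per_year") {
    ds_max / clock$rate
  } else {
    ds_max / (2 * clock$rate) * clock$generation_time_years
  }
  round(years / 1e6, 1)
}
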