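#' Aligned X/Y haplotype pair for one contig
#'
#' In-frame, positionally aligned X and Y ORF sequences (substitutions only,
#' no indels), as produced from X/Y-segregating SNPs substituted into the
#' contig reference.
#'
#' @param contig Contig identifier.
#' @param x,y X and Y nucleotide sequences (equal length, multiple of 3,
#'   alphabet A/C/G/T/N).
#' @return An object of class `hap_pair`.
#' @export
hap_pair <- function(contig, x, y) {
  x <- toupper(x)
  y <- toupper(y)
  if (nchar(x) != nchar(y)) {
    stop("X and Y sequences must have equal length", call. = FALSE)
  }
  if (nchar(x) %% 3L != 0L) {
    stop("sequence length must be a multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGTN]", x) || grepl("[^ACGTN]", y)) {
    stop("sequences must use the A/C/G/T/N alphabet", call. = FALSE)
  }
  structure(list(contig = contig, x = x, y = y), class = "hap_pair")
}

#' Diverge an ancestral ORF into an X/Y haplotype pair of known dS
#'
#' Places synonymous single-nucleotide substitutions on the Y copy of an
#' ancestral coding sequence until the realized synonymous divergence
#' (Jukes-Cantor corrected, Nei-Gojobori site counting) approximates
#' `ds_target`; the X copy stays ancestral.  Substituted codons are distinct,
#' so each change is a single-hit synonymous difference.  Optionally injects
#' a premature stop codon into the Y copy.
#'
#' @param ancestral In-frame coding sequence: length a multiple of 3,
#'   starting with ATG, no internal stop codon.
#' @param ds_target Target synonymous substitutions per synonymous site.
#' @param stop_probability Probability of replacing one internal Y codon
#'   with a stop codon (after divergence is placed).
#' @param contig Contig id carried on the returned pair.
#' @param seed Optional integer seed for reproducibility outside a seeded
#'   simulation stream.
#' @return A `hap_pair` with extra fields `realized_ds` (Jukes-Cantor
#'   corrected divergence implied by the placed changes), `n_syn_changes`
#'   and `y_premature_stop`.
#' @export
mutate_haplotypes <- function(ancestral, ds_target, stop_probability = 0,
                              contig = "contig", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ds_target < 0) stop("ds_target must be >= 0", call. = FALSE)
  codons <- split_codons(ancestral)  # errors unless length %% 3 == 0
  k <- length(codons)
  if (codons[1L] != "ATG") {
    stop("ancestral sequence must start with ATG", call. = FALSE)
  }
  internal <- codons[-c(1L, k)]
  if (any(is_stop_codon(internal)) || is_stop_codon(codons[1L])) {
    stop("ancestral sequence must not contain an internal stop codon",
         call. = FALSE)
  }

  syn_sites <- sum(vapply(codons[!is_stop_codon(codons)],
                          codon_syn_sites, numeric(1)))
  # invert the Jukes-Cantor correction to get the proportion of synonymous
  # sites that must differ
  p_target <- 0.75 * (1 - exp(-4 * ds_target / 3))
  n_changes <- round(syn_sites * p_target)

  candidates <- which(!is_stop_codon(codons) &
                        vapply(codons, function(cd) {
                          length(syn_neighbours(cd)) > 0L
                        }, logical(1)))
  candidates <- setdiff(candidates, 1L)  # keep the start codon intact
  n_changes <- min(n_changes, length(candidates))

  y_codons <- codons
  if (n_changes > 0L) {
    chosen <- sample(candidates, n_changes)
    for (i in chosen) {
      nb <- syn_neighbours(codons[i])
      y_codons[i] <- nb[sample.int(length(nb), 1L)]
    }
  }
  realized_p <- if (syn_sites > 0) n_changes / syn_sites else 0
  realized_ds <- if (realized_p > 0) -0.75 * log(1 - 4 * realized_p / 3) else 0

  y_stop <- FALSE
  if (stop_probability > 0 && k > 2L && runif(1) < stop_probability) {
    pos <- if (k > 3L) sample(2:(k - 1L), 1L) else 2L
    y_codons[pos] <- STOP_CODONS[sample.int(3L, 1L)]
    y_stop <- TRUE
  }

  pair <- hap_pair(contig, ancestral, paste(y_codons, collapse = ""))
  pair$realized_ds <- realized_ds
  pair$n_syn_changes <- n_changes
  pair$y_premature_stop <- y_stop
  pair
}

#' Write haplotype pairs as FASTA
#'
#' Headers follow the `<contig>_X` / `<contig>_Y` pairing convention.
#'
#' @param pairs List of `hap_pair` objects.
#' @param path Output file.
#' @export
write_haplotypes_fasta <- function(pairs, path) {
  seqs <- character(0)
  for (p in pairs) {
    seqs[paste0(p$contig, "_X")] <- p$x
    seqs[paste0(p$contig, "_Y")] <- p$y
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read haplotype pairs from FASTA
#'
#' Expects the `<contig>_X` / `<contig>_Y` header convention written by
#' [write_haplotypes_fasta()]; unpaired sequences are dropped with a warning.
#'
#' @param path FASTA file.
#' @return List of `hap_pair` objects.
#' @export
read_haplotypes_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  contigs_x <- sub("_X$", "", nm[grepl("_X$", nm)])
  contigs_y <- sub("_Y$", "", nm[grepl("_Y$", nm)])
  shared <- intersect(contigs_x, contigs_y)
  orphans <- setdiff(union(contigs_x, contigs_y), shared)
  if (length(orphans) > 0L) {
    warning("dropping unpaired haplotypes: ",
            paste(head(orphans, 5L), collapse = ", "), call. = FALSE)
  }
  lapply(shared, function(ct) {
    hap_pair(ct, as.character(seqs[[paste0(ct, "_X")]]),
             as.character(seqs[[paste0(ct, "_Y")]]))
  })
}
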