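# Codon-level machinery shared by the divergence estimator and the
# haplotype simulator.  Standard genetic code (translation table 1) only.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_env <- new.env(parent = emptyenv())

# Amino acid for each of the 64 codons, from the standard code ("*" = stop).
codon_aa <- function() {
  if (is.null(codon_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    codon_env$aa <- setNames(as.character(gc), names(gc))
  }
  codon_env$aa
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Fraction of the three possible single-nucleotide changes at each codon
# position that are synonymous.  Changes producing a stop codon count as
# non-synonymous; the total synonymous site count of a codon is the sum of
# the three per-position fractions (Nei & Gojobori 1986 counting).
syn_fraction_table <- function() {
  if (!is.null(codon_env$syn)) return(codon_env$syn)
  aa <- codon_aa()
  codons <- names(aa)
  syn <- matrix(0, nrow = length(codons), ncol = 3L,
                dimnames = list(codons, NULL))
  for (cd in codons) {
    if (is_stop_codon(cd)) next  # stop codons carry no counted sites
    nts <- strsplit(cd, "")[[1L]]
    for (pos in 1:3) {
      alts <- setdiff(BASES, nts[pos])
      n_syn <- 0L
      for (alt in alts) {
        mut <- nts
        mut[pos] <- alt
        mut_cd <- paste(mut, collapse = "")
        if (!is_stop_codon(mut_cd) && aa[[mut_cd]] == aa[[cd]]) {
          n_syn <- n_syn + 1L
        }
      }
      syn[cd, pos] <- n_syn / 3
    }
  }
  codon_env$syn <- syn
  syn
}

codon_syn_sites <- function(codon) {
  sum(syn_fraction_table()[codon, ])
}

# Single-nucleotide synonymous neighbours of a codon (never stops); cached.
syn_neighbours <- function(codon) {
  if (is.null(codon_env$nbrs)) {
    codon_env$nbrs <- lapply(setNames(nm = names(codon_aa())),
                             syn_neighbours_compute)
  }
  codon_env$nbrs[[codon]]
}

syn_neighbours_compute <- function(codon) {
  aa <- codon_aa()
  nts <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(BASES, nts[pos])) {
      mut <- nts
      mut[pos] <- alt
      mut_cd <- paste(mut, collapse = "")
      if (!is_stop_codon(mut_cd) && aa[[mut_cd]] == aa[[codon]]) {
        out <- c(out, mut_cd)
      }
    }
  }
  out
}

# Average synonymous / non-synonymous difference counts between two codons,
# over all minimal mutational pathways.  Pathways passing through a stop
# codon are excluded; if every pathway is blocked the average falls back to
# all pathways (rare; documented convention).
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  aa <- codon_aa()
  n1 <- strsplit(c1, "")[[1L]]
  n2 <- strsplit(c2, "")[[1L]]
  pos <- which(n1 != n2)
  perms <- permutations_of(pos)
  count_path <- function(order, allow_stop) {
    cur <- n1
    sd <- 0
    nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- n2[p]
      cd_cur <- paste(cur, collapse = "")
      cd_nxt <- paste(nxt, collapse = "")
      if (!allow_stop && is_stop_codon(cd_nxt) && cd_nxt != c2) return(NULL)
      if (is_stop_codon(cd_cur) || is_stop_codon(cd_nxt)) {
        nd <- nd + 1  # change involving a stop scored non-synonymous
      } else if (aa[[cd_cur]] == aa[[cd_nxt]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(syn = sd, nonsyn = nd)
  }
  paths <- lapply(perms, count_path, allow_stop = FALSE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0L) {
    paths <- lapply(perms, count_path, allow_stop = TRUE)
  }
  Reduce(`+`, paths) / length(paths)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
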