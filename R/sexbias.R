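#' Counts per million
#'
#' @param counts Gene x individual count matrix.
#' @param library_sizes Per-individual totals (> 0); defaults to column
#'   sums.
#' @return CPM matrix.
#' @export
cpm <- function(counts, library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stop("library sizes must be > 0",
                                    call. = FALSE)
  sweep(counts, 2L, library_sizes, `/`) * 1e6
}

#' Filter lowly expressed genes by mean CPM
#'
#' Genes whose mean CPM across individuals is lower than the threshold are
#' filtered out (a gene exactly at the threshold is retained).
#'
#' @param counts Gene x individual count matrix (non-negative).
#' @param library_sizes Per-individual library sizes.
#' @param threshold Mean-CPM threshold (default 0.5).
#' @return The filtered count matrix; removed gene names in
#'   `attr(, "removed")`.
#' @export
cpm_filter <- function(counts, library_sizes = colSums(counts),
                       threshold = 0.5) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  keep <- rowMeans(cpm(counts, library_sizes)) >= threshold
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Permutation test of differential expression between sexes
#'
#' A self-contained, exact differential-expression test used as the
#' package-internal method alongside external tools: the statistic is the
#' difference of group means of log2(CPM + 0.5); p-values come from a
#' two-sided permutation test over group labelings (full enumeration when
#' the number of labelings is at most `max_exact`, otherwise Monte-Carlo
#' with `n_mc` draws).  The reported fold change is the log2 ratio of group
#' mean CPMs with a pseudo-count of 0.5.
#'
#' With 5 vs 5 individuals the smallest achievable p is 1/252, so this test
#' cannot reach very stringent FDR cutoffs on its own; it serves as a
#' robust, assumption-free vote next to the model-based methods.
#'
#' @param counts Gene x individual count matrix.
#' @param groups Factor/character of two group labels (e.g. sex), aligned
#'   with columns; the *second* level (alphabetically, or by factor order)
#'   is the numerator of the fold change, so with `c("female", "male")`
#'   positive log2FC means male-biased.
#' @param library_sizes Per-individual library sizes.
#' @param max_exact Enumerate all labelings when their number is at most
#'   this (default 252 = choose(10, 5)).
#' @param n_mc Monte-Carlo permutations otherwise.
#' @param seed Seed for Monte-Carlo sampling.
#' @return Data frame: `gene`, `p`, `log2FC`, `method = "permutation"`.
#' @export
internal_de_test <- function(counts, groups,
                             library_sizes = colSums(counts),
                             max_exact = 252, n_mc = 10000, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("at least two individuals per group are required", call. = FALSE)
  }
  lcpm <- log2(cpm(counts, library_sizes) + 0.5)
  n <- ncol(counts)
  g2 <- which(groups == levels(groups)[2L])
  n2 <- length(g2)

  weight_for <- function(idx2) {
    w <- rep(-1 / (n - n2), n)
    w[idx2] <- 1 / n2
    w
  }
  obs <- as.vector(lcpm %*% weight_for(g2))

  n_lab <- choose(n, n2)
  if (n_lab <= max_exact) {
    combs <- combn(n, n2)
  } else {
    set.seed(seed)
    combs <- replicate(n_mc, sample.int(n, n2))
  }
  W <- apply(combs, 2L, weight_for)
  perm <- lcpm %*% W  # genes x labelings
  p <- rowMeans(abs(perm) >= abs(obs) - 1e-12)

  cpm_mat <- cpm(counts, library_sizes)
  m2 <- rowMeans(cpm_mat[, g2, drop = FALSE])
  m1 <- rowMeans(cpm_mat[, -g2, drop = FALSE])
  data.frame(gene = rownames(counts), p = p,
             log2FC = log2((m2 + 0.5) / (m1 + 0.5)),
             method = "permutation", stringsAsFactors = FALSE)
}

#' edgeR differential-expression wrapper
#'
#' Tagwise-dispersion GLM likelihood-ratio test (male versus female) on raw
#' counts, as commonly used for sex-bias calling.
#'
#' @inheritParams internal_de_test
#' @return Data frame: `gene`, `p`, `log2FC`, `method = "edgeR"`.
#' @export
de_edger <- function(counts, groups) {
  if (!requireNamespace("edgeR", quietly = TRUE)) {
    stop("the edgeR package is required for de_edger()", call. = FALSE)
  }
  groups <- as.factor(groups)
  dge <- edgeR::DGEList(counts = counts, group = groups)
  dge <- edgeR::calcNormFactors(dge)
  design <- stats::model.matrix(~groups)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tab <- lrt$table
  data.frame(gene = rownames(tab), p = tab$PValue, log2FC = tab$logFC,
             method = "edgeR", stringsAsFactors = FALSE)
}

#' limma-voom differential-expression wrapper
#'
#' Voom-transformed linear model with empirical-Bayes moderation.
#'
#' @inheritParams internal_de_test
#' @return Data frame: `gene`, `p`, `log2FC`, `method = "limma_voom"`.
#' @export
de_limma <- function(counts, groups) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop("the limma package is required for de_limma()", call. = FALSE)
  }
  groups <- as.factor(groups)
  design <- stats::model.matrix(~groups)
  v <- limma::voom(counts, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tab <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none")
  data.frame(gene = rownames(tab), p = tab$P.Value, log2FC = tab$logFC,
             method = "limma_voom", stringsAsFactors = FALSE)
}

#' Run several differential-expression methods
#'
#' Runs the requested methods and stacks their per-gene results, adding a
#' within-method BH false-discovery-rate column `q`.
#'
#' @inheritParams internal_de_test
#' @param methods Any of `"edgeR"`, `"limma_voom"`, `"permutation"`.
#' @param seed Seed for the permutation method.
#' @return Long data frame: `gene`, `method`, `p`, `q`, `log2FC`.
#' @export
run_de_methods <- function(counts, groups,
                           methods = c("edgeR", "limma_voom", "permutation"),
                           seed = 1) {
  res <- list()
  for (m in methods) {
    r <- switch(m,
                edgeR = de_edger(counts, groups),
                limma_voom = de_limma(counts, groups),
                permutation = internal_de_test(counts, groups, seed = seed),
                stop("unknown method: ", m, call. = FALSE))
    r$q <- bh_fdr(r$p)
    res[[m]] <- r[, c("gene", "method", "p", "q", "log2FC")]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted q-values (monotone step-up; always `q >= p`).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Multi-method consensus sex-bias call
#'
#' A gene is called sex-biased when it is significant (within-method FDR
#' below `fdr_cutoff`) in at least `min_methods` methods; its direction is
#' the sign of the mean log2 fold change over the significant methods
#' (positive = male-biased).  Genes whose significant methods disagree in
#' direction are dropped with a reason.
#'
#' @param results Long data frame from [run_de_methods()] (or imported
#'   external results): `gene`, `method`, `p`, `log2FC`, optional `q`.
#' @param min_methods Minimum number of agreeing methods (default 2).
#' @param fdr_cutoff Within-method FDR cutoff (default 1e-4).
#' @return One row per gene: `n_methods_significant`, `consensus`,
#'   `direction` (`"male"`/`"female"`/`NA`), `min_q`, `dropped_conflict`.
#' @export
consensus_vote <- function(results, min_methods = 2, fdr_cutoff = 1e-4) {
  methods <- unique(results$method)
  if (length(methods) < 2L) {
    stop("at least two methods are required for a consensus", call. = FALSE)
  }
  gene_sets <- lapply(methods, function(m) results$gene[results$method == m])
  common <- Reduce(intersect, gene_sets)
  if (length(common) == 0L) {
    stop("methods report disjoint gene sets", call. = FALSE)
  }
  if (is.null(results$q)) {
    results$q <- NA_real_
    for (m in methods) {
      i <- results$method == m
      results$q[i] <- bh_fdr(results$p[i])
    }
  }
  res <- results[results$gene %in% common, ]
  sig <- res$q < fdr_cutoff
  by_gene <- split(seq_len(nrow(res)), res$gene)
  rows <- lapply(names(by_gene), function(g) {
    i <- by_gene[[g]]
    s <- i[sig[i]]
    n_sig <- length(s)
    consensus <- n_sig >= min_methods
    direction <- NA_character_
    dropped <- FALSE
    if (consensus) {
      signs <- sign(res$log2FC[s])
      if (all(signs > 0)) direction <- "male"
      else if (all(signs < 0)) direction <- "female"
      else {
        consensus <- FALSE
        dropped <- TRUE
      }
    }
    data.frame(gene = g, n_methods_significant = n_sig,
               consensus = consensus, direction = direction,
               min_q = min(res$q[i]), dropped_conflict = dropped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_drop <- sum(out$dropped_conflict)
  if (n_drop > 0L) {
    message(n_drop, " gene(s) dropped: significant methods disagree in ",
            "direction")
  }
  rownames(out) <- NULL
  out
}

#' Sex-bias enrichment by chromosome class
#'
#' Summarizes consensus sex-bias calls per segregation class (sex-linked =
#' X/Y plus X-hemizygous; X/Y; X-hemizygous; autosomal) and tests
#' enrichment of sex-biased genes on sex-linked and on X-hemizygous contigs
#' against autosomal contigs with two-tailed Fisher exact tests,
#' BH-adjusted across the comparisons performed.
#'
#' @param calls Output of [consensus_vote()].
#' @param assignments Contig assignment table (`contig`, `assigned_type`).
#' @return List with `classes` (per-class biased counts, totals and
#'   percentages to two decimals) and `tests` (comparison, p, q).
#' @export
enrichment_summary <- function(calls, assignments) {
  type <- setNames(assignments$assigned_type, assignments$contig)
  calls <- calls[calls$gene %in% names(type), , drop = FALSE]
  if (nrow(calls) == 0L) {
    stop("no called gene has a segregation assignment", call. = FALSE)
  }
  cls <- unname(type[calls$gene])
  biased <- calls$consensus

  class_members <- list(
    sex_linked = cls %in% c("XY", "X_hemizygous"),
    XY = cls == "XY",
    X_hemizygous = cls == "X_hemizygous",
    autosomal = cls == "autosomal"
  )
  classes <- do.call(rbind, lapply(names(class_members), function(nm) {
    sel <- class_members[[nm]]
    data.frame(class = nm, n_biased = sum(biased & sel), n_total = sum(sel),
               percent = if (sum(sel) > 0)
                 as_percent(sum(biased & sel), sum(sel)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (classes$n_total[classes$class == "autosomal"] == 0L) {
    stop("no autosomal genes available as the reference class",
         call. = FALSE)
  }

  fisher_vs_auto <- function(sel) {
    auto <- class_members$autosomal
    tab <- matrix(c(sum(biased & sel), sum(!biased & sel),
                    sum(biased & auto), sum(!biased & auto)), nrow = 2L)
    fisher.test(tab, alternative = "two.sided")$p.value
  }
  tests <- data.frame(
    comparison = c("sex_linked_vs_autosomal", "X_hemizygous_vs_autosomal"),
    p = c(fisher_vs_auto(class_members$sex_linked),
          fisher_vs_auto(class_members$X_hemizygous)),
    stringsAsFactors = FALSE)
  tests$q <- bh_fdr(tests$p)
  list(classes = classes, tests = tests)
}

#' Import external differential-expression results
#'
#' Reads a per-method result TSV (columns `gene`, `p`, `log2FC`, `method`,
#' optional `q`) so results from external tools can enter
#' [consensus_vote()].
#'
#' @param path TSV file.
#' @return Data frame in the [run_de_methods()] layout.
#' @export
import_method_results <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "p", "log2FC", "method")
  if (!all(need %in% names(d))) {
    stop("result file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$q)) {
    for (m in unique(d$method)) {
      i <- d$method == m
      d$q[i] <- bh_fdr(d$p[i])
    }
  }
  d
}
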