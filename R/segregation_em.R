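#' Fit the segregation-type mixture model by EM
#'
#' Infers per-contig segregation types (autosomal, X/Y, X-hemizygous) from
#' family genotypes.  Each contig's likelihood under a type is the product
#' over its SNPs of [snp_likelihood()]; the E-step computes per-contig type
#' posteriors under mixture proportions `pi`, and the M-step updates `pi`
#' (mean posterior) and the genotyping-error rate `epsilon` (1-D numerical
#' maximization of the expected complete-data log-likelihood).  The default
#' is deterministic EM; `stochastic = TRUE` samples hard type assignments in
#' the E-step (stochastic EM) using `seed`.
#'
#' @param dataset A [cross_dataset()].
#' @param init List with starting values `pi` (length-3) and `epsilon`.
#' @param tol Convergence tolerance on the observed-data log-likelihood.
#' @param max_iter Maximum EM iterations (warns, does not error, when hit).
#' @param stochastic Sample contig types in the E-step instead of using
#'   soft posteriors.
#' @param seed Seed for the stochastic E-step (ignored otherwise).
#' @return An object of class `segregation_fit`: mixture proportions `pi`,
#'   error rate `epsilon`, the log-likelihood `trace`, per-contig posteriors,
#'   a per-SNP table (posteriors, best sex-linked configuration, error-free
#'   flag, Y allele and summed male Y-allele depth), and the default contig
#'   `assignments` from [assign_contigs()].
#' @export
em_fit <- function(dataset, init = list(pi = c(0.8, 0.15, 0.05),
                                        epsilon = 0.05),
                   tol = 1e-6, max_iter = 200L,
                   stochastic = FALSE, seed = NULL) {
  stopifnot(inherits(dataset, "cross_dataset"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (stochastic && !is.null(seed)) set.seed(seed)

  model <- build_likelihood_tables(dataset)
  contig <- factor(dataset$snps$contig, levels = unique(dataset$snps$contig))
  n_contig <- nlevels(contig)

  pi_cur <- init$pi / sum(init$pi)
  eps_cur <- max(init$epsilon, 1e-8)

  snp_ll <- snp_loglik_all(model, eps_cur)          # n_snps x 3
  cll <- rowsum(snp_ll, contig, reorder = FALSE)     # n_contigs x 3
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    lp <- sweep(cll, 2L, log(pi_cur), `+`)
    post_ls <- row_posterior(lp)
    ll <- sum(post_ls$logsum)
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at iteration ", iter, call. = FALSE)
    }
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    w <- post_ls$post
    if (stochastic) {
      z <- apply(w, 1L, function(p) sample.int(3L, 1L, prob = p))
      w <- matrix(0, n_contig, 3L)
      w[cbind(seq_len(n_contig), z)] <- 1
    }
    pi_cur <- pmax(colMeans(w), 1e-12)
    pi_cur <- pi_cur / sum(pi_cur)
    # expected complete-data log-likelihood in epsilon, maximized exactly
    q_fun <- function(e) {
      sll <- snp_loglik_all(model, e)
      sum(w * rowsum(sll, contig, reorder = FALSE))
    }
    eps_cur <- optimize(q_fun, interval = c(1e-8, 0.4), maximum = TRUE,
                        tol = 1e-9)$maximum
    snp_ll <- snp_loglik_all(model, eps_cur)
    cll <- rowsum(snp_ll, contig, reorder = FALSE)
  }
  if (!converged) {
    warning("EM reached max_iter = ", max_iter, " without converging",
            call. = FALSE)
  }

  lp <- sweep(cll, 2L, log(pi_cur), `+`)
  post_ls <- row_posterior(lp)
  contig_posterior <- data.frame(contig = levels(contig),
                                 P_auto = post_ls$post[, 1L],
                                 P_XY = post_ls$post[, 2L],
                                 P_hemi = post_ls$post[, 3L],
                                 stringsAsFactors = FALSE)

  snp_table <- build_snp_table(dataset, model, snp_ll, pi_cur, eps_cur)

  fit <- structure(list(pi = setNames(pi_cur, TYPE_LEVELS),
                        epsilon = eps_cur,
                        trace = trace,
                        converged = converged,
                        contig_posterior = contig_posterior,
                        snp_table = snp_table),
                   class = "segregation_fit")
  fit$assignments <- assign_contigs(fit)
  fit
}

#' @export
print.segregation_fit <- function(x, ...) {
  cat("Segregation mixture fit\n")
  cat(sprintf("  pi (auto/XY/hemi): %s\n",
              paste(sprintf("%.4f", x$pi), collapse = " / ")))
  cat(sprintf("  epsilon: %.5f   iterations: %d   converged: %s\n",
              x$epsilon, length(x$trace), x$converged))
  if (!is.null(x$assignments)) {
    print(table(x$assignments$assigned_type))
  }
  invisible(x)
}

# Precomputes, per type and configuration, the per-SNP counts of individuals
# at each distinct match probability, so the log-likelihood at any epsilon
# is a small matrix product.  P(obs | config, eps) factorizes over
# individuals as (1-eps) * p + (eps/2) * (1-p) with p = P(true == observed),
# and p takes only a handful of values (0, 1/4, 1/2, 1).
build_likelihood_tables <- function(dataset) {
  gt <- dataset$gt
  cls <- role_class(dataset$samples$role)
  n_snp <- nrow(gt)
  n_ind <- ncol(gt)
  cls_mat <- matrix(cls, n_snp, n_ind, byrow = TRUE)

  all_cfgs <- lapply(1:3, type_configs)
  pvals <- sort(unique(unlist(lapply(all_cfgs, function(cfgs) {
    lapply(cfgs, function(cf) as.vector(cf$pmatch))
  }))))

  counts <- lapply(all_cfgs, function(cfgs) {
    lapply(cfgs, function(cf) {
      idx <- cbind(as.vector(cls_mat), as.vector(gt))
      p <- matrix(cf$pmatch[idx], n_snp, n_ind)
      cnt <- vapply(pvals, function(v) {
        rowSums(p == v, na.rm = TRUE)
      }, numeric(n_snp))
      matrix(cnt, nrow = n_snp)
    })
  })
  list(counts = counts, pvals = pvals, configs = all_cfgs, n_snp = n_snp)
}

# n_snps x 3 matrix of per-SNP log-likelihoods at a given epsilon.
snp_loglik_all <- function(model, eps) {
  logterm <- log(pmax((1 - eps) * model$pvals +
                        (eps / 2) * (1 - model$pvals), 1e-300))
  out <- matrix(0, model$n_snp, 3L)
  for (t in 1:3) {
    ll_k <- vapply(model$counts[[t]], function(C) as.vector(C %*% logterm),
                   numeric(model$n_snp))
    out[, t] <- log_row_mean_exp(matrix(ll_k, nrow = model$n_snp))
  }
  out
}

# Per-config log-likelihoods for one type at a given epsilon.
config_logliks <- function(model, type_idx, eps) {
  logterm <- log(pmax((1 - eps) * model$pvals +
                        (eps / 2) * (1 - model$pvals), 1e-300))
  vapply(model$counts[[type_idx]], function(C) as.vector(C %*% logterm),
         numeric(model$n_snp))
}

# Per-SNP posteriors plus the best sex-linked configuration and the derived
# flags used by the assignment rules and the allelic-expression stage.
build_snp_table <- function(dataset, model, snp_ll, pi_cur, eps) {
  n_snp <- model$n_snp
  lp <- sweep(snp_ll, 2L, log(pi_cur), `+`)
  post <- row_posterior(lp)$post

  ll_xy <- matrix(config_logliks(model, 2L, eps), nrow = n_snp)
  ll_hemi <- matrix(config_logliks(model, 3L, eps), nrow = n_snp)

  # best sex-linked type per SNP, weighted by the fitted proportions
  sl_xy <- log(pi_cur[2L]) + snp_ll[, 2L]
  sl_hemi <- log(pi_cur[3L]) + snp_ll[, 3L]
  best_type <- ifelse(sl_xy >= sl_hemi, 2L, 3L)

  best_k_xy <- max.col(ll_xy, ties.method = "first")
  best_k_hemi <- max.col(ll_hemi, ties.method = "first")

  zero_idx <- which(model$pvals == 0)
  errorfree_for <- function(type_idx, k_vec) {
    vapply(seq_len(n_snp), function(i) {
      model$counts[[type_idx]][[k_vec[i]]][i, zero_idx] == 0
    }, logical(1))
  }
  ef_xy <- errorfree_for(2L, best_k_xy)
  ef_hemi <- errorfree_for(3L, best_k_hemi)

  cfg_xy <- model$configs[[2L]]
  cfg_hemi <- model$configs[[3L]]
  mother_het <- logical(n_snp)
  errorfree <- logical(n_snp)
  y_allele <- rep(NA_integer_, n_snp)
  diagnostic <- logical(n_snp)
  for (i in seq_len(n_snp)) {
    if (best_type[i] == 2L) {
      cf <- cfg_xy[[best_k_xy[i]]]
      mother_het[i] <- cf$mother_het
      errorfree[i] <- ef_xy[i]
      y_allele[i] <- cf$father_y
      diagnostic[i] <- cf$diagnostic
    } else {
      cf <- cfg_hemi[[best_k_hemi[i]]]
      mother_het[i] <- cf$mother_het
      errorfree[i] <- ef_hemi[i]
    }
  }

  male <- dataset$samples$sex == "male"
  y_depth_males <- numeric(n_snp)
  use_y <- best_type == 2L & diagnostic
  if (any(use_y)) {
    dy <- ifelse(matrix(y_allele[use_y] == 1L, sum(use_y), sum(male)),
                 dataset$d1[use_y, male, drop = FALSE],
                 dataset$d2[use_y, male, drop = FALSE])
    y_depth_males[use_y] <- rowSums(matrix(dy, nrow = sum(use_y)))
  }

  data.frame(contig = dataset$snps$contig, pos = dataset$snps$pos,
             post_auto = post[, 1L], post_xy = post[, 2L],
             post_hemi = post[, 3L],
             best_sl_type = TYPE_LEVELS[best_type],
             mother_het_sl = mother_het,
             errorfree_sl = errorfree,
             diagnostic_xy = diagnostic,
             y_allele = y_allele,
             y_depth_males = y_depth_males,
             stringsAsFactors = FALSE)
}

#' Assign contigs to segregation types
#'
#' Applies the assignment rules to a fitted mixture: SNPs whose posterior of
#' being autosomal or sex-linked exceeds `posterior_threshold` are retained
#' as informative; a contig is called sex-linked when its probability of
#' being sex-linked exceeds that of being autosomal *and* it has at least
#' one sex-linked SNP explainable with zero genotyping errors; sex-linked
#' contigs with zero summed male Y-allele depth over the retained sex-linked
#' SNPs are X-hemizygous, the rest X/Y.  Contigs failing the rules are
#' autosomal, or unassigned when no SNP is informative.  Ties between the
#' sex-linked and autosomal probabilities go to autosomal (conservative).
#'
#' @param fit A `segregation_fit` from [em_fit()].
#' @param posterior_threshold Per-SNP posterior threshold for an informative
#'   SNP (default 0.8).
#' @return Data frame with one row per contig: posteriors, SNP counts,
#'   the `has_x_polymorphism`, `has_errorfree_sexlinked_snp` and
#'   `zero_y_expression` flags, and `assigned_type`.
#' @export
assign_contigs <- function(fit, posterior_threshold = 0.8) {
  stopifnot(inherits(fit, "segregation_fit"))
  st <- fit$snp_table
  p_sl <- st$post_xy + st$post_hemi
  retained <- pmax(st$post_auto, p_sl) > posterior_threshold
  sl_snp <- retained & (p_sl > st$post_auto)

  contigs <- sort(unique(st$contig))
  n_snps <- as.vector(table(st$contig)[contigs])
  n_informative <- as.vector(tapply(retained, st$contig, sum)[contigs])
  has_ef <- as.vector(tapply(sl_snp & st$errorfree_sl, st$contig,
                             any)[contigs])
  has_xpoly <- as.vector(tapply(sl_snp & st$mother_het_sl, st$contig,
                                any)[contigs])
  y_depth <- as.vector(tapply(ifelse(sl_snp & st$best_sl_type == "XY" &
                                       st$diagnostic_xy,
                                     st$y_depth_males, 0),
                              st$contig, sum)[contigs])

  cp <- fit$contig_posterior[match(contigs, fit$contig_posterior$contig), ]
  p_sl_contig <- cp$P_XY + cp$P_hemi
  sex_linked <- p_sl_contig > cp$P_auto & has_ef
  assigned <- ifelse(n_informative == 0L, "unassigned",
                     ifelse(sex_linked,
                            ifelse(y_depth == 0, "X_hemizygous", "XY"),
                            "autosomal"))

  data.frame(contig = contigs,
             P_auto = cp$P_auto, P_XY = cp$P_XY, P_hemi = cp$P_hemi,
             n_snps = n_snps, n_informative = n_informative,
             has_x_polymorphism = has_xpoly,
             has_errorfree_sexlinked_snp = has_ef,
             zero_y_expression = y_depth == 0,
             assigned_type = assigned,
             stringsAsFactors = FALSE)
}

#' Segregation-type percentages
#'
#' Expresses counts of autosomal, X/Y and X-hemizygous contigs as
#' percentages of their total, to two decimals.
#'
#' @param counts Length-3 vector `(n_autosomal, n_XY, n_hemizygous)`.
#' @return Named length-3 numeric vector of percentages.
#' @examples
#' segregation_percentages(c(3706, 1196, 168))
#' @export
segregation_percentages <- function(counts) {
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be 3 non-negative values", call. = FALSE)
  }
  if (sum(counts) == 0) stop("total count is zero", call. = FALSE)
  setNames(as_percent(counts), TYPE_LEVELS)
}
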