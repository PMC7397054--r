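#' Simulate an RNA-seq family cross with known truth labels
#'
#' Generates a two-parent cross with sexed F1 offspring in which each contig
#' follows one of three segregation types:
#'
#' * **autosomal** — both parental alleles segregate Mendelian in both sexes;
#' * **X/Y** — the father carries one X and one Y allele; every son receives
#'   the Y allele plus one maternal X, every daughter the paternal X plus one
#'   maternal X; the Y allele never appears in the mother or daughters
#'   (before genotyping error);
#' * **X-hemizygous** — no Y copy exists; sons carry a single maternal X
#'   (observed as homozygous), daughters the paternal plus one maternal X.
#'
#' Each observed genotype is independently corrupted with the configured
#' genotyping-error probability (replacement by a uniformly chosen different
#' genotype).  Per-allele read depths are negative-binomial, scaled by
#' library size and per-contig expression; Y-allele depth is scaled by the
#' contig's true Y/X factor, and for dosage-compensated contigs the male X
#' depth is scaled up so the male total matches the female total.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_family` with elements
#'   * `dataset` — a [cross_dataset()] (genotypes, allele depths, counts,
#'     realized library sizes);
#'   * `truth` — one row per contig: true segregation type, Y/X factor,
#'     compensation status, sex-bias status and fold change, maternal
#'     X polymorphism, realized dS and premature-stop injections;
#'   * `haplotypes` — `hap_pair` list for X/Y contigs.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n_sons <- config$n_sons
  n_daughters <- config$n_daughters
  individuals <- c("mother", "father",
                   paste0("son", seq_len(n_sons)),
                   paste0("daughter", seq_len(n_daughters)))
  role <- c("mother", "father", rep("son", n_sons),
            rep("daughter", n_daughters))
  sex <- ifelse(role %in% c("father", "son"), "male", "female")
  n_ind <- length(individuals)
  male <- sex == "male"

  n_c <- config$n_contigs
  contig_ids <- sprintf("contig%05d", seq_len(n_c))
  type <- sample.int(3L, n_c, replace = TRUE, prob = config$type_proportions)
  x_poly <- runif(n_c) < config$x_polymorphism_rate
  x_poly[type == 1L] <- NA
  n_snps <- sample(seq(config$snps_per_contig$min, config$snps_per_contig$max),
                   n_c, replace = TRUE)
  yx <- rep(NA_real_, n_c)
  yx[type == 2L] <- rbeta(sum(type == 2L), config$yx_decay_distribution$shape1,
                          config$yx_decay_distribution$shape2)
  yx[type == 3L] <- 0
  comp <- rep(NA, n_c)
  comp[type != 1L] <- runif(sum(type != 1L)) < config$compensated_fraction

  # sex-biased genes; "hub" genes are autosomal, extremely male-expressed
  # organ genes that genuinely inflate male library sizes
  sb <- config$sex_bias_spec
  u <- runif(n_c)
  bias <- rep("none", n_c)
  bias[u < sb$male_frac] <- "male"
  bias[u >= sb$male_frac & u < sb$male_frac + sb$female_frac] <- "female"
  hub_pool <- which(bias == "none" & type == 1L)
  n_hub <- min(length(hub_pool), round(sb$hub_frac * n_c))
  hub <- if (n_hub > 0) sample(hub_pool, n_hub) else integer(0)
  bias[hub] <- "male"
  bias_fc <- ifelse(bias == "none", 1, sb$fold_change)
  bias_fc[hub] <- sb$hub_fold_change
  male_mult <- ifelse(bias == "male", bias_fc, 1)
  female_mult <- ifelse(bias == "female", bias_fc, 1)

  b <- rlnorm(n_c, config$base_expression_distribution$meanlog,
              config$base_expression_distribution$sdlog)

  # library scaling: expected unbiased total per individual hits its target,
  # so hub genes push realized male libraries above target (the normalization
  # artifact the autosomal correction removes)
  ls <- config$library_sizes
  target <- ls$mean * rlnorm(n_ind, -ls$sdlog^2 / 2, ls$sdlog)
  f_ind <- target / sum(2 * n_snps * b)

  eps <- config$genotyping_error
  disp <- config$dispersion
  has_snps <- !(type == 3L & !isTRUE_vec(x_poly))

  snp_list <- vector("list", n_c)
  gt_list <- vector("list", n_c)
  d1_list <- vector("list", n_c)
  d2_list <- vector("list", n_c)
  counts <- matrix(0, nrow = n_c, ncol = n_ind,
                   dimnames = list(contig_ids, individuals))
  haplotypes <- list()
  realized_ds <- rep(NA_real_, n_c)
  y_stop <- rep(NA, n_c)
  x_stop <- rep(NA, n_c)

  orf <- config$orf_length_distribution
  dst <- config$ds_target_distribution
  sense_codons <- setdiff(names(codon_aa()), STOP_CODONS)

  for (i in seq_len(n_c)) {
    ns <- n_snps[i]
    mult <- ifelse(male, male_mult[i], female_mult[i])
    m_ind <- b[i] * f_ind * mult  # per-copy expected depth, per individual

    if (!has_snps[i]) {
      # monomorphic in the family: counts only (two expressed copies)
      counts[i, ] <- rnbinom(n_ind, size = disp * ns, mu = 2 * ns * m_ind)
      next
    }

    sim <- simulate_contig(type[i], ns, isTRUE(x_poly[i]), yx[i],
                           isTRUE(comp[i]), m_ind, male, role, eps, disp)
    snp_list[[i]] <- data.frame(contig = contig_ids[i], pos = seq_len(ns),
                                allele1 = "A", allele2 = "G",
                                stringsAsFactors = FALSE)
    gt_list[[i]] <- sim$gt
    d1_list[[i]] <- sim$d1
    d2_list[[i]] <- sim$d2
    counts[i, ] <- colSums(sim$d1 + sim$d2)

    if (type[i] == 2L) {
      k <- sample(seq(orf$min, orf$max), 1L)
      anc <- paste(c("ATG", sample(sense_codons, k - 1L, replace = TRUE)),
                   collapse = "")
      pair <- mutate_haplotypes(anc, runif(1, dst$min, dst$max),
                                stop_probability = config$stop_probability$y,
                                contig = contig_ids[i])
      xs <- FALSE
      if (config$stop_probability$x > 0 && k > 2L &&
          runif(1) < config$stop_probability$x) {
        cods <- split_codons(pair$x)
        cods[sample(2:(k - 1L), 1L)] <- STOP_CODONS[sample.int(3L, 1L)]
        pair$x <- paste(cods, collapse = "")
        xs <- TRUE
      }
      haplotypes[[contig_ids[i]]] <- pair
      realized_ds[i] <- pair$realized_ds
      y_stop[i] <- pair$y_premature_stop
      x_stop[i] <- xs
    }
  }

  keep <- which(has_snps)
  snps <- do.call(rbind, snp_list[keep])
  gt <- do.call(rbind, gt_list[keep])
  d1 <- do.call(rbind, d1_list[keep])
  d2 <- do.call(rbind, d2_list[keep])

  samples <- data.frame(individual = individuals, sex = sex, role = role,
                        library_size = colSums(counts),
                        stringsAsFactors = FALSE)
  dataset <- cross_dataset(samples, snps, gt, d1, d2, counts = counts)

  truth <- data.frame(
    contig = contig_ids,
    type = TYPE_LEVELS[type],
    x_polymorphism = x_poly,
    has_snps = has_snps,
    n_snps = n_snps,
    yx_factor = yx,
    compensation = ifelse(type == 1L, NA,
                          ifelse(comp, "compensated", "non_compensated")),
    sex_bias = bias,
    bias_fold_change = bias_fc,
    realized_ds = realized_ds,
    x_premature_stop = x_stop,
    y_premature_stop = y_stop,
    stringsAsFactors = FALSE
  )

  structure(list(dataset = dataset, truth = truth, haplotypes = haplotypes,
                 config = config),
            class = "sim_family")
}

isTRUE_vec <- function(x) !is.na(x) & x

# One contig: parental setup, transmission, genotyping error, depths.
# Alleles are "A" (allele1) and "G" (allele2); genotype codes 1/2/3.
simulate_contig <- function(type, ns, x_poly, yx, comp, m_ind, male, role,
                            eps, disp) {
  n_ind <- length(m_ind)
  son_cols <- which(role == "son")
  dau_cols <- which(role == "daughter")
  mo <- which(role == "mother")
  fa <- which(role == "father")
  pair_code <- function(a, b) ifelse(a == b, ifelse(a == 1L, 1L, 3L), 2L)

  gt_true <- matrix(NA_integer_, ns, n_ind)
  mu1 <- matrix(0, ns, n_ind)
  mu2 <- matrix(0, ns, n_ind)
  add_copy <- function(cols, allele, weight = 1) {
    # allele: matrix/vector of 1/2 codes aligned with (ns x length(cols))
    a <- matrix(allele, ns, length(cols))
    w <- matrix(m_ind[cols], ns, length(cols), byrow = TRUE) * weight
    mu1[, cols] <<- mu1[, cols] + w * (a == 1L)
    mu2[, cols] <<- mu2[, cols] + w * (a == 2L)
  }
  draw_from <- function(gt) {
    # one allele drawn per SNP from a parent's genotype codes (length ns)
    out <- ifelse(gt == 1L, 1L, 2L)
    het <- gt == 2L
    out[het] <- sample(1:2, sum(het), replace = TRUE)
    out
  }

  if (type == 1L) {
    combos <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L), c(2L, 2L), c(2L, 3L),
                    c(3L, 1L), c(3L, 2L))
    pick <- combos[sample.int(nrow(combos), ns, replace = TRUE), , drop = FALSE]
    mgt <- pick[, 1L]
    fgt <- pick[, 2L]
    gt_true[, mo] <- mgt
    gt_true[, fa] <- fgt
    for (j in c(son_cols, dau_cols)) {
      mat <- draw_from(mgt)
      pat <- draw_from(fgt)
      gt_true[, j] <- pair_code(mat, pat)
    }
    # depths follow the true genotype: two expressed copies
    tg <- gt_true
    m_mat <- matrix(m_ind, ns, n_ind, byrow = TRUE)
    mu1 <- m_mat * (2 * (tg == 1L) + (tg == 2L))
    mu2 <- m_mat * (2 * (tg == 3L) + (tg == 2L))
  } else if (type == 2L) {
    # X/Y: diagnostic SNPs have mother A/A, father X = A, Y = G; with
    # maternal X polymorphism the first SNP is mother A/G, X = A, Y = G
    mgt <- rep(1L, ns)
    fx <- rep(1L, ns)
    fy <- rep(2L, ns)
    if (x_poly) mgt[1L] <- 2L
    gt_true[, mo] <- mgt
    gt_true[, fa] <- pair_code(fx, fy)
    w_x <- if (comp) 2 - yx else 1
    add_copy(fa, fx, w_x)
    add_copy(fa, fy, yx)
    # mother's two copies
    add_copy(mo, ifelse(mgt == 3L, 2L, 1L))
    add_copy(mo, ifelse(mgt == 1L, 1L, 2L))
    for (j in son_cols) {
      mat <- draw_from(mgt)
      gt_true[, j] <- pair_code(mat, fy)
      add_copy(j, mat, w_x)
      add_copy(j, fy, yx)
    }
    for (j in dau_cols) {
      mat <- draw_from(mgt)
      gt_true[, j] <- pair_code(mat, fx)
      add_copy(j, mat)
      add_copy(j, fx)
    }
  } else {
    # X-hemizygous: only generated with maternal X polymorphism (otherwise
    # the contig is monomorphic in the family and emits no SNPs)
    mgt <- rep(2L, ns)
    fx <- sample(1:2, ns, replace = TRUE)
    gt_true[, mo] <- mgt
    gt_true[, fa] <- ifelse(fx == 1L, 1L, 3L)
    w_x <- if (comp) 2 else 1
    add_copy(fa, fx, w_x)
    add_copy(mo, rep(1L, ns))
    add_copy(mo, rep(2L, ns))
    for (j in son_cols) {
      mat <- draw_from(mgt)
      gt_true[, j] <- ifelse(mat == 1L, 1L, 3L)  # single X observed hom
      add_copy(j, mat, w_x)
    }
    for (j in dau_cols) {
      mat <- draw_from(mgt)
      gt_true[, j] <- pair_code(mat, fx)
      add_copy(j, mat)
      add_copy(j, fx)
    }
  }

  # per-genotype error: replacement by a uniformly chosen different genotype
  gt_obs <- gt_true
  if (eps > 0) {
    err <- matrix(runif(ns * n_ind) < eps, ns, n_ind)
    n_err <- sum(err)
    if (n_err > 0) {
      shift <- sample(1:2, n_err, replace = TRUE)
      gt_obs[err] <- ((gt_true[err] - 1L + shift) %% 3L) + 1L
    }
  }

  d1 <- matrix(rnbinom(ns * n_ind, size = disp, mu = mu1), ns, n_ind)
  d2 <- matrix(rnbinom(ns * n_ind, size = disp, mu = mu2), ns, n_ind)
  list(gt = gt_obs, d1 = d1, d2 = d2)
}
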