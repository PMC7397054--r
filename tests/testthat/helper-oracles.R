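# Independent brute-force oracles, written against first principles and kept
# structurally different from the package implementation: genotypes are
# represented as sorted allele pairs and likelihoods are obtained by
# exhaustive enumeration over parental configurations x true-genotype
# assignments.

# All unordered pairs from alleles {1, 2}
oracle_pairs <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))

oracle_pair_code <- function(pair) {
  if (pair[1] == pair[2]) ifelse(pair[1] == 1L, 1L, 3L) else 2L
}

# Distribution over genotype codes from two transmitted-allele sets
oracle_offspring_dist <- function(maternal_alleles, paternal_alleles) {
  d <- numeric(3)
  for (ma in maternal_alleles) {
    for (pa in paternal_alleles) {
      code <- oracle_pair_code(sort(c(ma, pa)))
      d[code] <- d[code] + 1 / (length(maternal_alleles) *
                                  length(paternal_alleles))
    }
  }
  d
}

# Enumerate configurations for a type; each element: mother/father observed
# codes plus son and daughter genotype-code distributions.
oracle_enumerate <- function(type) {
  out <- list()
  if (type == "autosomal") {
    for (mp in oracle_pairs) {
      for (fp in oracle_pairs) {
        d <- oracle_offspring_dist(mp, fp)
        out[[length(out) + 1]] <- list(mother = oracle_pair_code(mp),
                                       father = oracle_pair_code(fp),
                                       son = d, daughter = d)
      }
    }
  } else if (type == "XY") {
    for (mp in oracle_pairs) {
      for (fx in 1:2) {
        for (fy in 1:2) {
          out[[length(out) + 1]] <- list(
            mother = oracle_pair_code(mp),
            father = oracle_pair_code(sort(c(fx, fy))),
            son = oracle_offspring_dist(mp, fy),
            daughter = oracle_offspring_dist(mp, fx))
        }
      }
    }
  } else {
    for (mp in oracle_pairs) {
      for (fx in 1:2) {
        son <- numeric(3)
        for (ma in mp) {  # single maternal X observed homozygous
          son[oracle_pair_code(c(ma, ma))] <-
            son[oracle_pair_code(c(ma, ma))] + 1 / length(mp)
        }
        out[[length(out) + 1]] <- list(
          mother = oracle_pair_code(mp),
          father = oracle_pair_code(c(fx, fx)),
          son = son,
          daughter = oracle_offspring_dist(mp, fx))
      }
    }
  }
  out
}

# Likelihood by exhaustive enumeration over configurations and over every
# assignment of true genotypes to the scored individuals.
oracle_snp_likelihood <- function(genotypes, roles, type, epsilon) {
  scored <- which(!is.na(genotypes))
  cfgs <- oracle_enumerate(type)
  err <- function(obs, true) {
    if (obs == true) 1 - epsilon else epsilon / 2
  }
  total <- 0
  for (cfg in cfgs) {
    grid <- expand.grid(rep(list(1:3), length(scored)))
    cfg_lik <- 0
    for (r in seq_len(nrow(grid))) {
      p <- 1
      for (j in seq_along(scored)) {
        i <- scored[j]
        true_g <- grid[r, j]
        p_true <- switch(roles[i],
                         mother = as.numeric(true_g == cfg$mother),
                         father = as.numeric(true_g == cfg$father),
                         son = cfg$son[true_g],
                         daughter = cfg$daughter[true_g])
        p <- p * p_true * err(genotypes[i], true_g)
        if (p == 0) break
      }
      cfg_lik <- cfg_lik + p
    }
    total <- total + cfg_lik / length(cfgs)
  }
  total
}

# Two-tailed Fisher exact p by exhaustive enumeration over all 2x2 tables
# with the observed margins, summing probabilities <= that of the observed
# table.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  probs <- vapply(max(0, k - n):min(k, m), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Step-up BH by direct transcription of the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Exact permutation p for a two-group difference of mean log2(CPM + 0.5),
# by an explicit loop over every split.
oracle_perm_p <- function(counts_row, lib, groups) {
  lcpm <- log2(counts_row / lib * 1e6 + 0.5)
  g2 <- which(groups == sort(unique(groups))[2])
  stat <- function(idx2) {
    mean(lcpm[idx2]) - mean(lcpm[-idx2])
  }
  obs <- stat(g2)
  splits <- combn(length(lcpm), length(g2))
  hits <- 0
  for (s in seq_len(ncol(splits))) {
    if (abs(stat(splits[, s])) >= abs(obs) - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}
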