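# Parental-haplotype configurations per segregation type and the implied
# offspring genotype distributions.  For a bi-allelic SNP the three
# observable genotypes are coded 1 (hom allele1), 2 (het), 3 (hom allele2).

allele_dist <- function(code) {
  # P(maternal/paternal transmitted allele) for a diploid genotype code
  switch(code, c(1, 0), c(0.5, 0.5), c(0, 1))
}

cross_dist <- function(pm, fixed_allele) {
  # offspring genotype distribution: maternal draw pm (over alleles 1/2)
  # combined with a fixed second allele
  out <- numeric(3)
  for (a in 1:2) {
    code <- if (a == fixed_allele) ifelse(a == 1L, 1L, 3L) else 2L
    out[code] <- out[code] + pm[a]
  }
  out
}

mendel_dist <- function(pm, pf) {
  out <- numeric(3)
  out[1] <- pm[1] * pf[1]
  out[2] <- pm[1] * pf[2] + pm[2] * pf[1]
  out[3] <- pm[2] * pf[2]
  out
}

hom_code <- function(allele) ifelse(allele == 1L, 1L, 3L)

# Internal configuration list for a type: each element carries the parents'
# observed genotype codes, offspring distributions, and bookkeeping used by
# the assignment rules (maternal heterozygosity, the Y allele, whether the
# SNP is X/Y-diagnostic: Y allele distinct from all X alleles in play).
type_configs <- function(type) {
  configs <- list()
  add <- function(mother, father_obs, son, daughter, mother_het,
                  father_x = NA_integer_, father_y = NA_integer_,
                  diagnostic = FALSE) {
    pm <- rbind(mother = as.numeric(1:3 == mother),
                father = as.numeric(1:3 == father_obs),
                son = son, daughter = daughter)
    configs[[length(configs) + 1L]] <<- list(
      mother = mother, father_obs = father_obs, son = son,
      daughter = daughter, pmatch = pm, mother_het = mother_het,
      father_x = father_x, father_y = father_y, diagnostic = diagnostic)
  }
  if (type == 1L) {
    for (m in 1:3) for (f in 1:3) {
      d <- mendel_dist(allele_dist(m), allele_dist(f))
      add(m, f, d, d, mother_het = m == 2L)
    }
  } else if (type == 2L) {
    for (m in 1:3) for (fx in 1:2) for (fy in 1:2) {
      son <- cross_dist(allele_dist(m), fy)
      dau <- cross_dist(allele_dist(m), fx)
      fo <- if (fx == fy) hom_code(fx) else 2L
      maternal <- switch(m, 1L, c(1L, 2L), 2L)
      diagnostic <- !(fy %in% maternal) && fx %in% maternal
      add(m, fo, son, dau, mother_het = m == 2L, father_x = fx,
          father_y = fy, diagnostic = diagnostic)
    }
  } else {
    for (m in 1:3) for (fx in 1:2) {
      pm <- allele_dist(m)
      son <- c(pm[1], 0, pm[2])  # single maternal X observed homozygous
      dau <- cross_dist(pm, fx)
      add(m, hom_code(fx), son, dau, mother_het = m == 2L, father_x = fx)
    }
  }
  configs
}

#' Enumerate parental configurations for a segregation type
#'
#' Lists every distinct assignment of the two alleles of a bi-allelic SNP to
#' parental haplotypes under a segregation type, with the implied probability
#' distribution over true son and daughter genotypes (Mendelian draws from
#' the mother; paternal contribution sex-determined for sex-linked types).
#'
#' @param type One of `"autosomal"`, `"XY"`, `"X_hemizygous"`.
#' @param alleles Character vector of the two alleles (labels only).
#' @return A data frame with one row per configuration: parental genotypes,
#'   the father's observed genotype, the Y allele (X/Y type), and the
#'   son/daughter genotype distributions over (`hom1`, `het`, `hom2`).
#' @examples
#' enumerate_configurations("XY", c("A", "B"))
#' @export
enumerate_configurations <- function(type, alleles = c("A", "B")) {
  type <- match.arg(type, TYPE_LEVELS)
  if (length(alleles) != 2L) {
    stop("only bi-allelic SNPs are supported (got ", length(alleles),
         " alleles)", call. = FALSE)
  }
  cfgs <- type_configs(match(type, TYPE_LEVELS))
  gt_label <- function(code) {
    c(paste0(alleles[1], "/", alleles[1]),
      paste0(alleles[1], "/", alleles[2]),
      paste0(alleles[2], "/", alleles[2]))[code]
  }
  df <- do.call(rbind, lapply(cfgs, function(cf) {
    data.frame(
      mother = gt_label(cf$mother),
      father = if (type == "autosomal") gt_label(cf$father_obs) else
        paste0("X=", alleles[cf$father_x],
               if (!is.na(cf$father_y)) paste0(";Y=", alleles[cf$father_y])
               else ""),
      father_observed = gt_label(cf$father_obs),
      y_allele = if (is.na(cf$father_y)) NA_character_ else
        alleles[cf$father_y],
      son_hom1 = cf$son[1], son_het = cf$son[2], son_hom2 = cf$son[3],
      daughter_hom1 = cf$daughter[1], daughter_het = cf$daughter[2],
      daughter_hom2 = cf$daughter[3],
      stringsAsFactors = FALSE
    )
  }))
  rownames(df) <- NULL
  df
}

#' Likelihood of one SNP's observed genotypes under a segregation type
#'
#' Sums over the type's parental configurations (uniform prior within the
#' type) the product over individuals of the observation probability
#' `P(observed | true)`, where an observed genotype equals the true one with
#' probability `1 - epsilon` and each of the two other genotypes with
#' probability `epsilon / 2`.  Missing genotypes contribute a factor of 1.
#'
#' @param genotypes Integer vector of observed genotype codes (1/2/3/NA),
#'   one per individual.
#' @param roles Character vector of family roles aligned with `genotypes`
#'   (`"mother"`, `"father"`, `"son"`, `"daughter"`).
#' @param type Segregation type (`"autosomal"`, `"XY"`, `"X_hemizygous"`).
#' @param epsilon Genotyping-error rate in `[0, 1)`.
#' @return The likelihood (a probability, not a log).
#' @export
snp_likelihood <- function(genotypes, roles, type, epsilon) {
  type <- match.arg(type, TYPE_LEVELS)
  if (epsilon < 0 || epsilon >= 1) {
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  }
  scored <- !is.na(genotypes)
  if (!any(scored)) {
    stop("SNP has no scored individuals", call. = FALSE)
  }
  cls <- role_class(roles)
  if (any(is.na(cls))) stop("unknown role", call. = FALSE)
  cfgs <- type_configs(match(type, TYPE_LEVELS))
  lik <- vapply(cfgs, function(cf) {
    p <- cf$pmatch[cbind(cls[scored], genotypes[scored])]
    prod((1 - epsilon) * p + (epsilon / 2) * (1 - p))
  }, numeric(1))
  mean(lik)
}
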