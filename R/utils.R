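#' Express counts as percentages of their total
#'
#' Small reporting helper used for the headline accounting statistics
#' (segregation-type percentages, sex-bias percentages, ...).
#'
#' @param n Numeric vector of non-negative counts.
#' @param total Single total to divide by; defaults to `sum(n)`.
#' @param digits Decimal places to round to.
#' @return Numeric vector `100 * n / total`, rounded.
#' @examples
#' as_percent(c(3706, 1196, 168))
#' @export
as_percent <- function(n, total = sum(n), digits = 2) {
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(total) || total <= 0) {
    stop("total must be positive", call. = FALSE)
  }
  round(100 * n / total, digits)
}

# Row-wise log(mean(exp(x))) for a matrix of per-configuration log-likelihoods.
# Uniform prior over configurations => likelihood is the mean over columns.
log_row_mean_exp <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  m <- x[, 1L]
  if (ncol(x) > 1L) for (k in 2L:ncol(x)) m <- pmax(m, x[, k])
  finite <- is.finite(m)
  s <- rep(0, nrow(x))
  for (k in seq_len(ncol(x))) {
    d <- x[, k] - m
    d[!finite] <- -Inf
    s <- s + exp(d)
  }
  out <- m + log(s / ncol(x))
  out[!finite] <- -Inf
  out
}

# Row-wise softmax in log space; returns list(post = matrix, logsum = vector).
row_posterior <- function(logp) {
  m <- logp[, 1L]
  for (k in 2L:ncol(logp)) m <- pmax(m, logp[, k])
  e <- exp(logp - m)
  s <- rowSums(e)
  list(post = e / s, logsum = m + log(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child-seed derivation: keeps every derived seed a valid
# 32-bit integer whatever the user passes on the command line.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563) + 1L
}
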