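# Numerical helpers shared across the package. Everything likelihood-shaped
# is computed in the log domain and exponentiated only at the interface.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-domain values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' log(mean(exp(x))) with a delta-method standard error on the log scale
#'
#' Used for Monte-Carlo marginal-likelihood estimates: if `x` are i.i.d.
#' log-likelihood draws, the estimate is `log E[exp(x)]` and the reported
#' error is `sd(exp(x)) / (sqrt(n) * mean(exp(x)))`, evaluated stably.
#'
#' @keywords internal
log_mean_exp <- function(x, se = FALSE) {
  n <- length(x)
  lm1 <- log_sum_exp(x) - log(n)
  if (!se) return(lm1)
  if (n < 2L || !is.finite(lm1)) return(list(estimate = lm1, se = NA_real_))
  # second moment in log domain -> relative variance of the mean
  lm2 <- log_sum_exp(2 * x) - log(n)
  lvar <- lm2 + log1p(-exp(pmin(2 * lm1 - lm2, 0)))  # log Var(exp(x)) + log corr
  rel_se <- exp(0.5 * (lvar - log(n)) - lm1)
  list(estimate = lm1, se = rel_se)
}

#' Normalize log weights to probabilities
#' @keywords internal
normalize_log_weights <- function(log_w) {
  p <- exp(log_w - log_sum_exp(log_w))
  p / sum(p)
}

#' Effective sample size of a weighted ensemble
#' @param log_w log weights (unnormalized).
#' @keywords internal
ess_from_log_weights <- function(log_w) {
  p <- normalize_log_weights(log_w)
  1 / sum(p^2)
}

#' Weighted quantile (inverse of the weighted empirical CDF)
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Derive a child RNG seed from a base seed and an index
#'
#' Keeps derived seeds inside the 32-bit integer range so the same base
#' seed always yields the same, non-overlapping stream labels.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}
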