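#' Utility of an option under additive feature utilities
#'
#' An option's utility is the sum of the utilities of its features: the
#' inner product of the agent's utility vector `w` with the option's feature
#' vector `f`. Utilities are on a log-odds scale: a one-unit difference in
#' utility makes an option `e` times more likely to be chosen from a pair.
#'
#' @param w numeric utility vector (one entry per feature).
#' @param f numeric feature vector of the same length, or a matrix with one
#'   option per row.
#' @return a numeric utility (or one per row of `f`).
#' @examples
#' option_utility(c(1, 2), c(1, 0))
#' @export
option_utility <- function(w, f) {
  if (is.matrix(f)) {
    if (ncol(f) != length(w)) {
      stop("feature dimension (", ncol(f), ") does not match utility vector (",
           length(w), ")", call. = FALSE)
    }
    return(drop(f %*% w))
  }
  if (length(f) != length(w)) {
    stop("feature dimension (", length(f), ") does not match utility vector (",
         length(w), ")", call. = FALSE)
  }
  sum(w * f)
}

#' Luce-Shepard choice probabilities over an option pool
#'
#' The probability of choosing option `i` from a pool is proportional to
#' `m_i * exp(u_i)`, where `u_i` is the option's utility under `w` and `m_i`
#' its token multiplicity. With equal utilities this reduces to the pool
#' frequencies; with unit multiplicities it is the softmax of the utilities.
#' Computed with log-sum-exp, so utilities up to around +/-700 are safe.
#'
#' @param options a data frame with columns `option`, optional
#'   `multiplicity`, and numeric feature columns.
#' @param w utility vector, in the order of the feature columns (a named `w`
#'   is matched to the feature names).
#' @return a tibble with columns `option` and `prob`, summing to one.
#' @examples
#' opts <- tibble::tibble(option = c("a", "b"), multiplicity = c(18, 82),
#'                        red = c(1, 0), blue = c(0, 1))
#' choice_prob(opts, c(red = 0, blue = 0))
#' @export
choice_prob <- function(options, w) {
  options <- tibble::as_tibble(options)
  if (nrow(options) == 0) stop("option pool is empty", call. = FALSE)
  if (!"multiplicity" %in% names(options)) options$multiplicity <- 1
  feats <- feature_names(options)
  if (!is.null(names(w))) {
    if (!setequal(names(w), feats)) {
      stop("names of w do not match the feature columns", call. = FALSE)
    }
    w <- w[feats]
  }
  u <- option_utility(w, as.matrix(options[feats]))
  lp <- log(options$multiplicity) + u
  tibble::tibble(option = options$option, prob = exp(lp - log_sum_exp(lp)))
}

#' Log-likelihood of a choice dataset under a utility vector
#'
#' Choices are independent given `w`, so the log-likelihood is the sum over
#' events of the log Luce-Shepard probability of the chosen option. An empty
#' dataset has log-likelihood 0; single-option (forced) events contribute 0.
#'
#' @param data a [choice_data()] object.
#' @param w utility vector (named or in feature-column order).
#' @return a single log-probability.
#' @export
log_likelihood <- function(data, w) {
  feats <- feature_names(data)
  if (nrow(data) == 0) return(0)
  if (!is.null(names(w))) {
    if (!setequal(names(w), feats)) {
      stop("names of w do not match the feature columns", call. = FALSE)
    }
    w <- w[feats]
  }
  mats <- as_choice_matrices(data, feats)
  sum(chosen_logprob_matrix(mats, matrix(w, nrow = 1)))
}

# Chosen-option log-probabilities for a draw matrix W (n_draws x d):
# returns an n_events x n_draws matrix; column j is the per-event log
# choice probability under draw j. Chunks over draws to bound memory.
chosen_logprob_matrix <- function(mats, W, chunk = NULL) {
  n_draws <- nrow(W)
  n_rows <- nrow(mats$F)
  if (mats$n_events == 0L) return(matrix(0, 0, n_draws))
  if (is.null(chunk)) chunk <- max(1L, min(n_draws, floor(2e7 / max(n_rows, 1L))))
  out <- matrix(0, mats$n_events, n_draws)
  log_m <- log(mats$mult)
  start <- 1L
  while (start <= n_draws) {
    cols <- start:min(start + chunk - 1L, n_draws)
    U <- mats$F %*% t(W[cols, , drop = FALSE])       # options x draws
    LU <- U + log_m
    # per-event log-sum-exp down the option rows; the cheap path needs no
    # per-event stabilization because exp() cannot overflow there
    r <- range(LU)
    if (r[2] < 600 && r[1] > -600) {
      logS <- log(rowsum(exp(LU), mats$event))
    } else {
      M <- rowsum_max(LU, mats$event, mats$n_events)
      logS <- M + log(rowsum(exp(LU - M[mats$event, , drop = FALSE]), mats$event))
    }
    out[, cols] <- LU[mats$chosen_rows, , drop = FALSE] - logS
    start <- start + chunk
  }
  out
}

# Per-group column-wise maximum (groups indexed 1..n_groups).
rowsum_max <- function(X, group, n_groups) {
  M <- matrix(-Inf, n_groups, ncol(X))
  for (i in seq_len(nrow(X))) {
    g <- group[i]
    M[g, ] <- pmax(M[g, ], X[i, ])
  }
  M
}
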