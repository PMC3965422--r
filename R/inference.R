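#' Gaussian prior over feature utilities
#'
#' Each feature utility is a priori independent Gaussian with standard
#' deviation `sigma` and mean `mean` (scalar, recycled, or one value per
#' feature). The default zero mean encodes no a-priori attraction to any
#' feature; `sigma = 1` sets the scale of plausible preferences and has
#' little influence on the scenario fits shipped with the package.
#'
#' @param sigma positive standard deviation.
#' @param mean prior mean (default 0).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(sigma = 1, mean = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  structure(list(sigma = sigma, mean = mean), class = "prior_spec")
}

prior_mean_vector <- function(prior, d) {
  m <- rep_len(prior$mean, d)
  if (!all(is.finite(m))) stop("prior mean must be finite", call. = FALSE)
  m
}

# Draw the shared n x d Gaussian proposal matrix for a seed. Every routine
# that needs prior draws goes through this so that, at a fixed seed, the
# same draws back marginal likelihoods, posteriors and predictives.
prior_draws <- function(prior, d, n, seed) {
  mu <- prior_mean_vector(prior, d)
  withr::with_seed(seed, {
    matrix(stats::rnorm(n * d, sd = prior$sigma), n, d)
  }) + matrix(mu, n, d, byrow = TRUE)
}

new_posterior_ensemble <- function(draws, log_weights, features, method,
                                   seed, prior, log_evidence = NA_real_) {
  colnames(draws) <- features
  structure(
    list(
      draws = draws, log_weights = log_weights, features = features,
      n_draws = nrow(draws), ess = ess_from_log_weights(log_weights),
      method = method, seed = seed, prior = prior, log_evidence = log_evidence
    ),
    class = "posterior_ensemble"
  )
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat("<posterior_ensemble> ", x$n_draws, " draws over ",
      length(x$features), " features (", x$method, "), ESS = ",
      round(x$ess, 1), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Draw an ensemble from the utility prior
#'
#' @param features feature names (or a single integer dimension).
#' @param n number of draws.
#' @param prior a [prior_spec()].
#' @param seed integer RNG seed.
#' @return a `posterior_ensemble` with uniform weights.
#' @export
sample_prior <- function(features, n, prior = prior_spec(), seed = 1L) {
  if (is.numeric(features) && length(features) == 1) {
    features <- paste0("f", seq_len(features))
  }
  d <- length(features)
  if (n < 1 || d < 1) stop("need n >= 1 draws and d >= 1 features", call. = FALSE)
  draws <- prior_draws(prior, d, n, seed)
  new_posterior_ensemble(draws, rep(0, n), features, "prior", seed, prior)
}

#' Posterior over utility vectors given observed choices
#'
#' Applies Bayes' rule to the Luce-Shepard likelihood of the observed
#' choices under the Gaussian utility prior. Two representations are
#' available:
#'
#' * `"importance"` (default): `n` prior draws weighted by their likelihood.
#'   Adequate here because the likelihood is bounded and the feature spaces
#'   are small; the effective sample size is reported and a warning issued
#'   when it falls below `ess_warn`.
#' * `"grid"`: deterministic quadrature on a lattice spanning the prior mean
#'   +/- 5 sigma with `grid_points` nodes per axis, available for up to
#'   three features. Slow but exact to lattice resolution; used as the
#'   reference oracle in the package's own validation.
#'
#' With no events the posterior equals the prior (uniform weights).
#'
#' @param data a [choice_data()] object.
#' @param prior a [prior_spec()].
#' @param n number of importance draws.
#' @param seed integer RNG seed (importance method).
#' @param method `"importance"` or `"grid"`.
#' @param grid_points lattice nodes per axis for the grid method.
#' @param ess_warn warn if the effective sample size falls below this.
#' @return a `posterior_ensemble`; its `log_evidence` is the log marginal
#'   likelihood estimate implied by the representation.
#' @export
posterior <- function(data, prior = prior_spec(), n = 50000L, seed = 1L,
                      method = c("importance", "grid"), grid_points = 201L,
                      ess_warn = 500) {
  method <- match.arg(method)
  feats <- feature_names(data)
  d <- length(feats)
  if (d == 0) stop("data has no feature columns", call. = FALSE)
  mats <- as_choice_matrices(data, feats)
  if (method == "importance") {
    draws <- prior_draws(prior, d, n, seed)
    log_w <- if (mats$n_events == 0L) rep(0, n) else
      colSums(chosen_logprob_matrix(mats, draws))
    log_ev <- log_mean_exp(log_w)
    out <- new_posterior_ensemble(draws, log_w, feats, "importance",
                                  seed, prior, log_ev)
    if (out$ess < ess_warn) {
      warning("importance posterior has low effective sample size (",
              round(out$ess, 1), " < ", ess_warn,
              "); consider more draws", call. = FALSE)
    }
    return(out)
  }
  if (d > 3) {
    stop("the grid method is an exact oracle for small problems only (d <= 3)",
         call. = FALSE)
  }
  mu <- prior_mean_vector(prior, d)
  axes <- lapply(seq_len(d), function(j) {
    seq(mu[j] - 5 * prior$sigma, mu[j] + 5 * prior$sigma,
        length.out = grid_points)
  })
  grid <- as.matrix(expand.grid(axes))
  log_prior <- rowSums(vapply(seq_len(d), function(j) {
    stats::dnorm(grid[, j], mu[j], prior$sigma, log = TRUE)
  }, numeric(nrow(grid))))
  log_lik <- if (mats$n_events == 0L) rep(0, nrow(grid)) else
    colSums(chosen_logprob_matrix(mats, grid))
  cell <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  log_w <- log_prior + log_lik
  new_posterior_ensemble(grid, log_w, feats, "grid", NA_integer_, prior,
                         log_evidence = log_sum_exp(log_w) + log(cell))
}

#' Weighted posterior summaries
#'
#' @param post a `posterior_ensemble`.
#' @return `posterior_mean()` returns the named vector of weighted means.
#' @export
posterior_mean <- function(post) {
  p <- normalize_log_weights(post$log_weights)
  drop(p %*% post$draws)
}

#' @rdname posterior_mean
#' @param probs quantile levels.
#' @return `posterior_quantile()` returns a features x probs matrix.
#' @export
posterior_quantile <- function(post, probs = c(0.05, 0.95)) {
  p <- normalize_log_weights(post$log_weights)
  t(apply(post$draws, 2, weighted_quantile, w = p, probs = probs))
}

#' @describeIn posterior_mean broom-style per-feature summary: weighted
#'   mean, standard deviation and 90% credible interval.
#' @exportS3Method generics::tidy
tidy.posterior_ensemble <- function(x, ...) {
  p <- normalize_log_weights(x$log_weights)
  mu <- drop(p %*% x$draws)
  sdv <- sqrt(pmax(drop(p %*% x$draws^2) - mu^2, 0))
  q <- posterior_quantile(x, c(0.05, 0.95))
  tibble::tibble(
    term = x$features, estimate = mu, std.error = sdv,
    conf.low = q[, 1], conf.high = q[, 2]
  )
}

#' @describeIn posterior_mean one-row diagnostics: draws, effective sample
#'   size, log evidence, method and seed.
#' @exportS3Method generics::glance
glance.posterior_ensemble <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, ess = x$ess, log_evidence = x$log_evidence,
    method = x$method, seed = x$seed, sigma = x$prior$sigma
  )
}

#' Posterior-predictive choice probabilities for an offer
#'
#' Averages the Luce-Shepard choice probabilities over the posterior
#' ensemble (`rule = "luce"`): the probability that an agent with
#' preferences drawn from the posterior would pick each option. With
#' `rule = "max"` it instead reports the posterior probability that each
#' option has the highest utility in the offer — the answer to "which
#' option does the agent like best?". Both report a Monte-Carlo standard
#' error per option.
#'
#' @param post a `posterior_ensemble`.
#' @param offer a data frame of options (as in [choice_prob()]).
#' @param rule `"luce"` (softmax average, default) or `"max"`.
#' @return a tibble with columns `option`, `prob`, `se`.
#' @export
predictive_choice <- function(post, offer, rule = c("luce", "max")) {
  rule <- match.arg(rule)
  offer <- tibble::as_tibble(offer)
  if (nrow(offer) == 0) stop("offer is empty", call. = FALSE)
  if (!"multiplicity" %in% names(offer)) offer$multiplicity <- 1
  feats <- post$features
  missing <- setdiff(feats, names(offer))
  bad <- setdiff(feature_names(offer), feats)
  if (length(missing) > 0 || length(bad) > 0) {
    stop("offer feature columns must match the ensemble's features",
         call. = FALSE)
  }
  U <- post$draws %*% t(as.matrix(offer[, feats, drop = FALSE]))  # draws x options
  LU <- U + matrix(log(offer$multiplicity), nrow(U), ncol(U), byrow = TRUE)
  if (rule == "luce") {
    m <- apply(LU, 1, max)
    E <- exp(LU - m)
    P <- E / rowSums(E)
  } else {
    mx <- apply(LU, 1, max)
    P <- (LU == mx) * 1
    P <- P / rowSums(P)  # split exact ties evenly
  }
  w <- normalize_log_weights(post$log_weights)
  est <- drop(w %*% P)
  se <- sqrt(drop(w^2 %*% (P - matrix(est, nrow(P), ncol(P), byrow = TRUE))^2))
  tibble::tibble(option = offer$option, prob = est, se = se)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a posterior ensemble as per-feature intervals
#'
#' @param object a `posterior_ensemble`.
#' @param ... unused.
#' @return a ggplot: posterior mean and 90% credible interval per feature.
#' @exportS3Method ggplot2::autoplot
autoplot.posterior_ensemble <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "feature utility (posterior mean, 90% CI)", y = NULL)
}
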