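#' Monte-Carlo log marginal likelihood of a choice dataset
#'
#' Two hypotheses about a population of agents are compared throughout the
#' package:
#'
#' * **shared** (Model 1): every agent chooses with the same utility vector,
#'   drawn once from the Gaussian prior;
#' * **individual** (Model 2): each agent has her own utility vector, drawn
#'   independently from the same prior.
#'
#' Both marginal likelihoods are simple Monte-Carlo averages of the
#' likelihood over `n` prior draws. The same draws (per seed) are used for
#' both models — and, under the individual model, for every agent — which
#' reduces the variance of the model comparison and makes the
#' individual-model estimate decompose exactly into per-agent terms. The
#' returned `mc_se` is a delta-method standard error on the log scale.
#'
#' @param data a [choice_data()] object (empty data gives log ML 0).
#' @param model `"shared"` or `"individual"`.
#' @param prior a [prior_spec()].
#' @param n number of Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return a list with `log_ml`, `mc_se`, `model`, `n_draws`.
#' @export
log_marginal_likelihood <- function(data, model = c("shared", "individual"),
                                    prior = prior_spec(), n = 5000L, seed = 1L) {
  model <- match.arg(model)
  feats <- feature_names(data)
  if (nrow(data) == 0 || length(feats) == 0) {
    return(list(log_ml = 0, mc_se = 0, model = model, n_draws = n))
  }
  mats <- as_choice_matrices(data, feats)
  draws <- prior_draws(prior, length(feats), n, seed)
  L <- chosen_logprob_matrix(mats, draws)
  res <- marginal_from_logprob(L, mats$agent_of_event, model)
  c(res, list(model = model, n_draws = n))
}

marginal_from_logprob <- function(L, agent_of_event, model) {
  if (model == "shared") {
    lme <- log_mean_exp(colSums(L), se = TRUE)
    return(list(log_ml = lme$estimate, mc_se = lme$se))
  }
  per_agent <- lapply(split(seq_len(nrow(L)), agent_of_event), function(rows) {
    log_mean_exp(colSums(L[rows, , drop = FALSE]), se = TRUE)
  })
  list(
    log_ml = sum(vapply(per_agent, `[[`, numeric(1), "estimate")),
    mc_se = sqrt(sum(vapply(per_agent, `[[`, numeric(1), "se")^2))
  )
}

#' Posterior probabilities of the shared- vs individual-preference model
#'
#' Bayes' rule over the two Monte-Carlo marginal likelihoods of
#' [log_marginal_likelihood()], computed from shared prior draws. With a
#' small dataset the simpler shared model tends to win even when agents
#' differ (the Bayesian Occam's razor); as evidence accumulates from
#' genuinely different agents the individual model takes over.
#'
#' @param data a [choice_data()] object.
#' @param prior_m1 prior probability of the shared model, strictly in (0, 1).
#' @param prior a [prior_spec()].
#' @param n Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return a `model_comparison` object with the two log marginal
#'   likelihoods, their MC errors, and prior/posterior model probabilities.
#' @export
model_posterior <- function(data, prior_m1 = 0.5, prior = prior_spec(),
                            n = 5000L, seed = 1L) {
  if (!is.numeric(prior_m1) || prior_m1 <= 0 || prior_m1 >= 1) {
    stop("prior_m1 must be strictly between 0 and 1", call. = FALSE)
  }
  m1 <- log_marginal_likelihood(data, "shared", prior, n, seed)
  m2 <- log_marginal_likelihood(data, "individual", prior, n, seed)
  post <- posterior_model_probs(m1$log_ml, m2$log_ml, prior_m1)
  structure(
    list(
      log_ml_m1 = m1$log_ml, log_ml_m2 = m2$log_ml,
      mc_error_m1 = m1$mc_se, mc_error_m2 = m2$mc_se,
      prior_m1 = prior_m1,
      posterior_m1 = post[1], posterior_m2 = post[2],
      n_draws = n, seed = seed
    ),
    class = "model_comparison"
  )
}

posterior_model_probs <- function(log_ml_m1, log_ml_m2, prior_m1) {
  log_odds <- log(prior_m1) - log1p(-prior_m1) + log_ml_m1 - log_ml_m2
  p1 <- stats::plogis(log_odds)
  c(p1, 1 - p1)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn model_posterior one row per model: log marginal likelihood,
#'   MC error, prior and posterior probability.
#' @param x a `model_comparison` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  tibble::tibble(
    model = c("shared", "individual"),
    log_marginal = c(x$log_ml_m1, x$log_ml_m2),
    mc_error = c(x$mc_error_m1, x$mc_error_m2),
    prior = c(x$prior_m1, 1 - x$prior_m1),
    posterior = c(x$posterior_m1, x$posterior_m2)
  )
}

#' @describeIn model_posterior one-row summary with the log Bayes factor
#'   (shared over individual).
#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    log_bayes_factor = x$log_ml_m1 - x$log_ml_m2,
    posterior_m1 = x$posterior_m1, posterior_m2 = x$posterior_m2,
    prior_m1 = x$prior_m1, n_draws = x$n_draws
  )
}

#' Plot a model comparison
#' @param object a `model_comparison` object.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  td <- tidy(object) |>
    tidyr::pivot_longer(c("prior", "posterior"),
                        names_to = "stage", values_to = "probability")
  td$stage <- factor(td$stage, levels = c("prior", "posterior"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$stage, y = .data$probability,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "model probability")
}

#' Model-averaged prediction of an agent's next choice
#'
#' Predicts the probability that `actor` picks each option of `offer`,
#' averaging over the shared- and individual-preference models weighted by
#' their posterior probabilities. Under the shared model the predictive
#' conditions on every observed event pooled across agents; under the
#' individual model it conditions only on `actor`'s own events (an actor
#' with no recorded events gets the prior predictive). All quantities reuse
#' one set of prior draws per seed, so the mixture decomposition
#' `prob = posterior_m1 * prob_shared + posterior_m2 * prob_individual`
#' holds exactly.
#'
#' `prior_m1` may be pinned to 0 or 1 to read off a single model's
#' prediction.
#'
#' @param data a [choice_data()] object of observed events.
#' @param actor label of the agent whose next choice is predicted (may be
#'   absent from `data`).
#' @param offer a data frame of options (as in [choice_prob()]).
#' @param prior_m1 prior probability of the shared model, in `[0, 1]`.
#' @param prior a [prior_spec()].
#' @param n Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return a tibble with columns `option`, `prob`, `prob_shared`,
#'   `prob_individual`, `posterior_m1`.
#' @export
predict_next_choice <- function(data, actor, offer, prior_m1 = 0.5,
                                prior = prior_spec(), n = 5000L, seed = 1L) {
  offer <- tibble::as_tibble(offer)
  if (nrow(offer) == 0) stop("offer is empty", call. = FALSE)
  if (!is.numeric(prior_m1) || prior_m1 < 0 || prior_m1 > 1) {
    stop("prior_m1 must lie in [0, 1]", call. = FALSE)
  }
  feats <- feature_names(data)
  if (length(feats) == 0) feats <- feature_names(offer)
  mats <- as_choice_matrices(data, feats)
  draws <- prior_draws(prior, length(feats), n, seed)
  L <- chosen_logprob_matrix(mats, draws)

  ens <- function(log_w) new_posterior_ensemble(draws, log_w, feats,
                                                "importance", seed, prior)
  lw_shared <- if (nrow(L)) colSums(L) else rep(0, n)
  actor_rows <- which(mats$agent_of_event == actor)
  lw_actor <- if (length(actor_rows)) {
    colSums(L[actor_rows, , drop = FALSE])
  } else {
    rep(0, n)
  }
  p_shared <- predictive_choice(ens(lw_shared), offer)$prob
  p_indiv <- predictive_choice(ens(lw_actor), offer)$prob

  post_m1 <- if (prior_m1 == 0) 0 else if (prior_m1 == 1) 1 else {
    if (nrow(L) == 0) {
      prior_m1
    } else {
      ml1 <- marginal_from_logprob(L, mats$agent_of_event, "shared")
      ml2 <- marginal_from_logprob(L, mats$agent_of_event, "individual")
      posterior_model_probs(ml1$log_ml, ml2$log_ml, prior_m1)[1]
    }
  }
  tibble::tibble(
    option = offer$option,
    prob = post_m1 * p_shared + (1 - post_m1) * p_indiv,
    prob_shared = p_shared,
    prob_individual = p_indiv,
    posterior_m1 = post_m1
  )
}
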