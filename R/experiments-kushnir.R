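# Statistical preference inference from non-random sampling: a puppet picks
# five target toys from a box whose composition varies by condition, and
# children are asked which of three toys (target, the box's alternative, a
# novel distractor) the puppet likes.

#' Observed target-offer proportions in the box-sampling study
#'
#' Children offered the target toy 0.96, 1.29 and 1.67 times out of 2 in
#' the 100%, 50% and 18% conditions — proportions 0.48, 0.645 and 0.835.
#' @return a named numeric vector over conditions `"100"`, `"50"`, `"18"`.
#' @export
kushnir_observed <- function() {
  c("100" = 0.48, "50" = 0.645, "18" = 0.835)
}

#' Build one box-sampling condition as choice data plus an offer
#'
#' The box is represented type-level: one target option and (except in the
#' 100% condition) one alternative option with integer multiplicities out
#' of 100 (100/0, 50/50, 18/82), which yields the same Luce-Shepard
#' probabilities as a pool of individual tokens. Each of `n_choices` events
#' records the puppet picking the target. With `opt_out = TRUE`, every
#' event also contains one never-offered option with its own indicator
#' feature (orthogonal to the toys' features), encoding that the puppet
#' could have declined to pick a toy.
#'
#' @param condition percent of target toys in the box: 100, 50 or 18.
#' @param n_choices observed target choices (default 5).
#' @param opt_out add the unobserved extra option to each event.
#' @return a list with `data` ([choice_data()]) and `offer` (a three-option
#'   tibble: target, alternative, distractor).
#' @export
kushnir_scenario <- function(condition = c(100, 50, 18), n_choices = 5L,
                             opt_out = FALSE) {
  condition <- as.numeric(match.arg(as.character(condition[1]),
                                    c("100", "50", "18")))
  feats <- c("target", "alternative", "distractor",
             if (opt_out) "declined")
  one_hot <- function(option, multiplicity) {
    row <- as.list(stats::setNames(as.numeric(feats == option), feats))
    dplyr::bind_cols(tibble::tibble(option = option,
                                    multiplicity = multiplicity),
                     tibble::as_tibble(row))
  }
  m_target <- condition
  m_alt <- 100 - condition
  box <- dplyr::bind_rows(
    one_hot("target", m_target),
    if (m_alt > 0) one_hot("alternative", m_alt),
    if (opt_out) one_hot("declined", 1)
  )
  events <- purrr::map(seq_len(n_choices), function(i) {
    choice_event(agent = "puppet", options = box, chosen = "target", event = i)
  })
  offer <- dplyr::bind_rows(
    one_hot("target", 1), one_hot("alternative", 1), one_hot("distractor", 1)
  )
  list(data = bind_events(!!!events), offer = offer,
       condition = condition, opt_out = opt_out)
}

#' Predicted offer probabilities for one box-sampling condition
#'
#' Infers the puppet's feature utilities from the observed picks and
#' predicts which toy children should offer. The children were asked to
#' pick the toy the puppet *liked*, so the default offer rule is `"max"`:
#' the posterior probability that each toy has the highest utility.
#' `rule = "luce"` gives the softmax-averaged predictive instead.
#'
#' @inheritParams kushnir_scenario
#' @param prior a [prior_spec()].
#' @param n importance draws.
#' @param seed integer RNG seed.
#' @param rule offer rule passed to [predictive_choice()].
#' @return a tibble with `option`, `prob`, `se` and `expected_of_2`
#'   (the implied number of target offers out of two trials).
#' @export
kushnir_predict <- function(condition = c(100, 50, 18), prior = prior_spec(),
                            n = 50000L, seed = 1L, opt_out = FALSE,
                            n_choices = 5L, rule = c("max", "luce")) {
  rule <- match.arg(rule)
  sc <- kushnir_scenario(condition, n_choices = n_choices, opt_out = opt_out)
  post <- posterior(sc$data, prior, n = n, seed = seed, ess_warn = 0)
  pred <- predictive_choice(post, sc$offer, rule = rule)
  pred$expected_of_2 <- 2 * pred$prob
  pred
}

#' Model fit to the children's target-offer proportions
#'
#' Mean squared error between the predicted probability of offering the
#' target and the observed proportions across the three box conditions.
#' Per-option predictions for all three offers are returned alongside, but
#' the error is computed over the three target cells, the only cells whose
#' observed proportions are reported.
#'
#' @inheritParams kushnir_predict
#' @param predictions optional named vector of target-offer probabilities
#'   over conditions `"100"`, `"50"`, `"18"`; when supplied, the model run
#'   is skipped and the MSE of these numbers is returned (useful for
#'   baselines).
#' @return a list with `mse`, `predictions` (tibble over conditions), and
#'   `observed`.
#' @export
kushnir_mse <- function(prior = prior_spec(), n = 50000L, seed = 1L,
                        opt_out = FALSE, rule = c("max", "luce"),
                        predictions = NULL) {
  obs <- kushnir_observed()
  if (!is.null(predictions)) {
    predictions <- predictions[names(obs)]
    return(list(
      mse = mean((predictions - obs)^2),
      predictions = tibble::tibble(condition = names(obs),
                                   predicted = unname(predictions),
                                   observed = unname(obs)),
      observed = obs
    ))
  }
  rule <- match.arg(rule)
  per_cond <- purrr::map(c(100, 50, 18), function(cond) {
    kushnir_predict(cond, prior = prior, n = n,
                    seed = derive_seed(seed, cond), opt_out = opt_out,
                    rule = rule)
  })
  p_target <- vapply(per_cond, function(p) p$prob[p$option == "target"],
                     numeric(1))
  list(
    mse = mean((p_target - obs)^2),
    predictions = tibble::tibble(
      condition = names(obs), predicted = p_target, observed = unname(obs)
    ),
    per_option = stats::setNames(per_cond, names(obs)),
    observed = obs
  )
}
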