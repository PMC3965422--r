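# The developmental shift in preference understanding: a child who has
# mostly observed her own (cracker-loving) choices plus some choices by
# household members sees a new actor choose broccoli over goldfish
# crackers, and must decide what to offer. With little background data the
# shared-preference model wins (offer crackers, like a 14-month-old); with
# much data the individual-preference model wins (offer broccoli, like an
# 18-month-old).

#' Synthetic household food world (fixture)
#'
#' Eight foods described by six binary features (salty, sweet, crunchy,
#' vegetable, dairy, grain) and ground-truth utilities for the child and
#' two household agents. These are synthetic fixture constants, chosen so
#' that the child strongly prefers goldfish crackers over broccoli (+2 on
#' the cracker's distinguishing feature, -2 on the vegetable feature) and
#' that the household agents' utilities are the child's plus fixed Gaussian
#' perturbations (sd 0.5) — preferences broadly similar within the
#' household, but not identical.
#'
#' @param prior_m1 prior probability of the shared-preference model used by
#'   downstream simulations.
#' @param n_reps default replicate count for [repacholi_trajectory()].
#' @param options_per_event foods available at each background choice event.
#' @param child_multiplier how many of the child's own events are observed
#'   per observed event of another household agent.
#' @return a list with `foods` (option tibble), `true_utils` (named list of
#'   utility vectors), `offer` (broccoli vs cracker), and the simulation
#'   settings above.
#' @export
repacholi_world <- function(prior_m1 = 0.5, n_reps = 15L,
                            options_per_event = 4L, child_multiplier = 10L) {
  feats <- c("salty", "sweet", "crunchy", "vegetable", "dairy", "grain")
  foods <- tibble::tribble(
    ~option,    ~salty, ~sweet, ~crunchy, ~vegetable, ~dairy, ~grain,
    "cracker",       1,      0,        1,          0,      0,      1,
    "broccoli",      0,      0,        0,          1,      0,      0,
    "cookie",        0,      1,        0,          0,      0,      1,
    "chips",         1,      0,        1,          0,      0,      0,
    "grapes",        0,      1,        0,          0,      0,      0,
    "spinach",       0,      0,        0,          1,      0,      0,
    "cheese",        1,      0,        0,          0,      1,      0,
    "yogurt",        0,      1,        0,          0,      1,      0
  )
  foods$multiplicity <- 1
  child <- c(salty = 2, sweet = 1, crunchy = 0.5, vegetable = -2,
             dairy = 0.3, grain = 0.5)
  # child + N(0, 0.5^2) perturbations, drawn once and frozen as constants
  parent <- c(salty = 2.512, sweet = 1.567, crunchy = 0.736,
              vegetable = -2.355, dairy = -0.381, grain = 0.434)
  sibling <- c(salty = 2.418, sweet = 0.453, crunchy = 0.602,
               vegetable = -2.145, dairy = 0.665, grain = 0.178)
  list(
    foods = foods[c("option", "multiplicity", feats)],
    features = feats,
    true_utils = list(child = child, parent = parent, sibling = sibling),
    offer = foods[foods$option %in% c("broccoli", "cracker"),
                  c("option", "multiplicity", feats)],
    prior_m1 = prior_m1, n_reps = as.integer(n_reps),
    options_per_event = as.integer(options_per_event),
    child_multiplier = as.integer(child_multiplier)
  )
}

#' Simulate one household observation history plus the actor's demonstration
#'
#' Background events are forward-simulated from the ground-truth utilities
#' (four foods drawn uniformly per event; choice by the Luce-Shepard rule):
#' `n_background` events each for the two household agents and
#' `child_multiplier * n_background` for the child. One final event encodes
#' the new actor's demonstration: broccoli chosen over the cracker.
#'
#' @param world a [repacholi_world()].
#' @param n_background background events per non-child agent.
#' @param seed integer RNG seed.
#' @return a [choice_data()] object; the demonstration is the last event,
#'   by agent `"actor"`.
#' @export
repacholi_simulate <- function(world, n_background, seed = 1L) {
  background <- if (n_background > 0) {
    spec <- population_spec(
      agents = world$true_utils,
      option_pool = world$foods,
      options_per_event = world$options_per_event,
      events_per_agent = c(world$child_multiplier * n_background,
                           n_background, n_background),
      seed = seed
    )
    generate_dataset(spec)
  } else {
    NULL
  }
  demo <- choice_event("actor", world$offer, chosen = "broccoli")
  bind_events(background, demo)
}

#' Model-averaged offer predictions along a background-data trajectory
#'
#' For each value of `n_background` and each replicate, simulates a
#' household history, appends the actor's broccoli demonstration, and
#' computes the model-averaged probability that the actor would next choose
#' broccoli over the cracker ([predict_next_choice()]); the child is
#' assumed to offer what she predicts the actor would choose.
#'
#' @param world a [repacholi_world()].
#' @param n_background integer grid of background event counts.
#' @param prior_m1 prior probability of the shared model (defaults to the
#'   world's).
#' @param n_reps replicates per grid point (defaults to the world's).
#' @param n Monte-Carlo draws per marginal likelihood / predictive.
#' @param prior a [prior_spec()].
#' @param seed integer RNG seed.
#' @return a `preference_trajectory`: tibble of per-replicate results with
#'   a [tidy()] summary (mean and standard error per grid point) and an
#'   [autoplot()] method.
#' @export
repacholi_trajectory <- function(world = repacholi_world(),
                                 n_background = c(0, 5, 10, 20, 50, 100, 200, 500),
                                 prior_m1 = world$prior_m1,
                                 n_reps = world$n_reps, n = 2000L,
                                 prior = prior_spec(), seed = 1L) {
  grid <- tidyr::expand_grid(n_background = as.integer(n_background),
                             rep = seq_len(n_reps))
  raw <- purrr::pmap_dfr(grid, function(n_background, rep) {
    s <- derive_seed(seed, n_background * 101L + rep)
    data <- repacholi_simulate(world, n_background, seed = s)
    pred <- predict_next_choice(data, "actor", world$offer,
                                prior_m1 = prior_m1, prior = prior,
                                n = n, seed = derive_seed(s, 1))
    b <- pred$option == "broccoli"
    tibble::tibble(
      n_background = n_background, rep = rep,
      p_broccoli = pred$prob[b],
      p_broccoli_shared = pred$prob_shared[b],
      p_broccoli_individual = pred$prob_individual[b],
      posterior_m1 = pred$posterior_m1[1]
    )
  })
  structure(
    list(results = raw, prior_m1 = prior_m1, n_reps = n_reps, seed = seed),
    class = "preference_trajectory"
  )
}

#' @export
print.preference_trajectory <- function(x, ...) {
  cat("<preference_trajectory> prior_m1 = ", x$prior_m1, ", ",
      x$n_reps, " replicates\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn repacholi_trajectory per-grid-point summary: mean and
#'   standard error of the broccoli-offer probability and of the
#'   shared-model posterior.
#' @param x a `preference_trajectory`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.preference_trajectory <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$n_background) |>
    dplyr::summarise(
      p_broccoli_mean = mean(.data$p_broccoli),
      p_broccoli_se = stats::sd(.data$p_broccoli) / sqrt(dplyr::n()),
      p_goldfish_mean = 1 - mean(.data$p_broccoli),
      posterior_m1_mean = mean(.data$posterior_m1),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot an offer trajectory
#' @param object a `preference_trajectory`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.preference_trajectory <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$n_background,
                                   y = .data$p_broccoli_mean)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p_broccoli_mean - .data$p_broccoli_se,
                   ymax = .data$p_broccoli_mean + .data$p_broccoli_se),
      alpha = 0.2
    ) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "background events per household agent",
                  y = "P(offer broccoli)",
                  subtitle = paste0("prior P(shared model) = ",
                                    object$prior_m1))
}
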