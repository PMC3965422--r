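# Preference generalization to hidden objects: two actors display opposite
# preferences over four object pairs, then react emotionally to hidden
# objects of a similar or different category, and the child picks one
# hidden object. Prediction chains actor-preference inference, reaction
# constraints on the hidden objects' features, and the child's own inferred
# preferences.

#' Build the two-actor training phase as choice data
#'
#' Four object pairs are drawn from the trained category of `cat` (fixed by
#' `seed`). Each actor's reaction pattern — liking her own object and
#' disliking the other — is encoded as the actor choosing her own object
#' in a two-option event, giving four events per actor. The child's play
#' preferences are encoded the same way: `"4of4"` children chose Actor 1's
#' object in all four events, `"3of4"` children in three.
#'
#' @param child_pattern `"4of4"` or `"3of4"`.
#' @param cat a [category_model()].
#' @param seed integer RNG seed fixing the training objects.
#' @return a list with `actor1`, `actor2`, `child` ([choice_data()]
#'   objects) and `objects` (features of the four pairs).
#' @export
fawcett_training <- function(child_pattern = c("4of4", "3of4"),
                             cat = default_category_model(), seed = 1L) {
  child_pattern <- match.arg(child_pattern)
  trained <- names(cat$blocks)[1]
  F1 <- sample_category_objects(cat, trained, 4L, seed = derive_seed(seed, 11))
  F2 <- sample_category_objects(cat, trained, 4L, seed = derive_seed(seed, 12))
  pair_tbl <- function(k) {
    dplyr::bind_cols(
      tibble::tibble(option = c(paste0("a1_obj", k), paste0("a2_obj", k)),
                     multiplicity = 1),
      tibble::as_tibble(rbind(F1[k, ], F2[k, ]))
    )
  }
  events_for <- function(agent, picks) {
    purrr::map(1:4, function(k) {
      tbl <- pair_tbl(k)
      choice_event(agent, tbl, chosen = tbl$option[picks[k]])
    })
  }
  child_picks <- if (child_pattern == "4of4") rep(1L, 4) else c(1L, 1L, 1L, 2L)
  list(
    actor1 = bind_events(!!!events_for("actor1", rep(1L, 4))),
    actor2 = bind_events(!!!events_for("actor2", rep(2L, 4))),
    child = bind_events(!!!events_for("child", child_picks)),
    objects = list(actor1 = F1, actor2 = F2),
    child_pattern = child_pattern
  )
}

#' Predicted choice between two hidden objects
#'
#' Runs the full generalization chain for one experimental cell: infer each
#' actor's utilities from training, constrain the hidden objects' features
#' by the actors' reactions (`positive` reads as "my favorite of its
#' category", `negative` as dislike, `indifferent` as no information),
#' infer the child's own utilities from her play choices, and average the
#' two-option Luce-Shepard probability that the child picks Actor 1's
#' hidden object.
#'
#' @param condition `"positive"`, `"negative"`, or `"indifferent"`.
#' @param similarity hidden objects from the trained category
#'   (`"similar"`) or the other category (`"different"`).
#' @param child_pattern `"4of4"` or `"3of4"` training preference.
#' @param prior a [prior_spec()].
#' @param n importance draws for the three posteriors.
#' @param seed integer RNG seed.
#' @param cat a [category_model()].
#' @param n_hidden joint draws for the hidden-object posteriors and the
#'   final prediction.
#' @param n_candidates comparison pool size for the favorite constraint.
#' @return a one-row tibble: `condition`, `similarity`, `child_pattern`,
#'   `prob` (child picks Actor 1's hidden object), `se`.
#' @export
fawcett_predict <- function(condition = c("positive", "negative", "indifferent"),
                            similarity = c("similar", "different"),
                            child_pattern = c("4of4", "3of4"),
                            prior = prior_spec(), n = 20000L, seed = 1L,
                            cat = default_category_model(),
                            n_hidden = 20000L, n_candidates = 10L) {
  condition <- match.arg(condition)
  similarity <- match.arg(similarity)
  child_pattern <- match.arg(child_pattern)
  tr <- fawcett_training(child_pattern, cat, seed)
  post1 <- posterior(tr$actor1, prior, n = n, seed = derive_seed(seed, 21),
                     ess_warn = 0)
  post2 <- posterior(tr$actor2, prior, n = n, seed = derive_seed(seed, 22),
                     ess_warn = 0)
  postc <- posterior(tr$child, prior, n = n, seed = derive_seed(seed, 23),
                     ess_warn = 0)
  kind <- switch(condition, positive = "favorite", negative = "dislike",
                 indifferent = "none")
  category <- if (similarity == "similar") names(cat$blocks)[1] else
    names(cat$blocks)[2]
  h1 <- hidden_object_posterior(post1, kind, cat, category, n = n_hidden,
                                seed = derive_seed(seed, 31),
                                n_candidates = n_candidates)
  h2 <- hidden_object_posterior(post2, kind, cat, category, n = n_hidden,
                                seed = derive_seed(seed, 32),
                                n_candidates = n_candidates)
  pred <- predict_hidden_choice(postc, h1, h2, n = n_hidden,
                                seed = derive_seed(seed, 33))
  tibble::tibble(
    condition = condition, similarity = similarity,
    child_pattern = child_pattern, prob = pred$prob, se = pred$se
  )
}
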