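#' Specification of a synthetic population of choosing agents
#'
#' Describes agents with known utility vectors choosing repeatedly from a
#' pool of options: the forward direction of the Luce-Shepard choice rule,
#' used to generate validation data with known ground truth.
#'
#' @param agents named list of utility vectors (one per agent), all of the
#'   feature dimension of `option_pool`.
#' @param option_pool a data frame of options (as in [choice_prob()]).
#' @param options_per_event options sampled (without replacement, uniformly)
#'   from the pool at each event.
#' @param events_per_agent events per agent; scalar or one value per agent.
#' @param seed integer RNG seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(agents, option_pool, options_per_event = 2L,
                            events_per_agent = 10L, seed = 1L) {
  option_pool <- tibble::as_tibble(option_pool)
  if (!"multiplicity" %in% names(option_pool)) option_pool$multiplicity <- 1
  feats <- feature_names(option_pool)
  if (options_per_event > nrow(option_pool)) {
    stop("options_per_event exceeds the pool size", call. = FALSE)
  }
  if (any(events_per_agent < 0)) {
    stop("events_per_agent must be non-negative", call. = FALSE)
  }
  bad <- vapply(agents, function(w) length(w) != length(feats), logical(1))
  if (any(bad)) {
    stop("every agent's utility vector must have one entry per feature",
         call. = FALSE)
  }
  structure(
    list(agents = agents, option_pool = option_pool,
         options_per_event = as.integer(options_per_event),
         events_per_agent = rep_len(as.integer(events_per_agent),
                                    length(agents)),
         features = feats, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Simulate a choice dataset from a known population
#'
#' For each event, `options_per_event` distinct options are drawn uniformly
#' from the pool and the choice is sampled from the Luce-Shepard
#' probabilities under the agent's true utilities. Reproducible per seed.
#'
#' @param spec a [population_spec()].
#' @return a [choice_data()] object.
#' @export
generate_dataset <- function(spec) {
  pool <- spec$option_pool
  feats <- spec$features
  Fm <- as.matrix(pool[feats])
  k <- spec$options_per_event
  pieces <- list()
  withr::with_seed(spec$seed, {
    offset <- 0L
    for (a in seq_along(spec$agents)) {
      w <- spec$agents[[a]]
      label <- names(spec$agents)[a]
      n_ev <- spec$events_per_agent[a]
      if (n_ev == 0L) next
      # k x n_ev matrix of pool row indices, one column per event
      rows <- vapply(seq_len(n_ev),
                     function(i) sample.int(nrow(pool), k), integer(k))
      rows <- matrix(rows, nrow = k)
      u <- matrix(drop(Fm[as.vector(rows), , drop = FALSE] %*% w), nrow = k)
      lp <- log(pool$multiplicity[as.vector(rows)]) + as.vector(u)
      lp <- matrix(lp, nrow = k)
      p <- exp(sweep(lp, 2, apply(lp, 2, max)))
      p <- sweep(p, 2, colSums(p), "/")
      cum <- apply(p, 2, cumsum)
      pick <- colSums(matrix(cum, nrow = k) <
                        rep(stats::runif(n_ev), each = k)) + 1L
      flat <- as.vector(rows)
      pieces[[length(pieces) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          event = offset + rep(seq_len(n_ev), each = k),
          agent = label,
          option = pool$option[flat],
          multiplicity = pool$multiplicity[flat],
          chosen = rep(pick, each = k) == rep(seq_len(k), n_ev)
        ),
        pool[flat, feats]
      )
      offset <- offset + n_ev
    }
  })
  if (length(pieces) == 0) return(bind_events())
  choice_data(dplyr::bind_rows(pieces))
}

#' Parameter-recovery harness for the posterior machinery
#'
#' Simulates datasets of increasing size from a known utility vector and
#' reports how well the importance-sampling posterior recovers it: the
#' Euclidean error of the posterior mean and the empirical coverage of the
#' per-feature 90% credible intervals, aggregated over replicates.
#'
#' The default option pool contains one single-feature option per feature
#' plus a featureless option, so that comparisons against the zero-utility
#' baseline identify the utilities absolutely (within an event, the
#' Luce-Shepard rule is invariant to a constant shift in utilities).
#'
#' @param true_w named numeric vector of ground-truth feature utilities.
#' @param n_events integer grid of dataset sizes.
#' @param prior a [prior_spec()].
#' @param seed integer RNG seed.
#' @param n_reps replicate datasets per grid point.
#' @param n_draws importance draws per posterior.
#' @param option_pool optional custom pool.
#' @return a tibble with one row per (`n_events`, replicate):
#'   posterior-mean error and credible-interval coverage, plus per-grid
#'   summaries via `dplyr::summarise` downstream.
#' @export
recover_parameters <- function(true_w, n_events = c(20, 50, 100, 200),
                               prior = prior_spec(), seed = 1L, n_reps = 10L,
                               n_draws = 5000L, option_pool = NULL) {
  d <- length(true_w)
  feats <- names(true_w)
  if (is.null(feats)) feats <- paste0("f", seq_len(d))
  if (is.null(option_pool)) {
    option_pool <- dplyr::bind_cols(
      tibble::tibble(option = c(feats, "baseline"), multiplicity = 1),
      tibble::as_tibble(rbind(diag(d), rep(0, d)), .name_repair = ~feats)
    )
  }
  grid <- tidyr::expand_grid(n_events = as.integer(n_events),
                             rep = seq_len(n_reps))
  res <- purrr::pmap_dfr(grid, function(n_events, rep) {
    s <- derive_seed(seed, n_events * 1000L + rep)
    spec <- population_spec(stats::setNames(list(true_w), "agent"),
                            option_pool, options_per_event = 2L,
                            events_per_agent = n_events, seed = s)
    data <- generate_dataset(spec)
    if (nrow(data) == 0) {
      post <- sample_prior(feats, n_draws, prior, seed = derive_seed(s, 1))
    } else {
      post <- posterior(data, prior, n = n_draws, seed = derive_seed(s, 1),
                        ess_warn = 0)
    }
    mu <- posterior_mean(post)
    q <- posterior_quantile(post, c(0.05, 0.95))
    tibble::tibble(
      n_events = n_events, rep = rep,
      error = sqrt(sum((mu - true_w)^2)),
      coverage = mean(true_w >= q[, 1] & true_w <= q[, 2])
    )
  })
  res
}
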