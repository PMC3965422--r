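#' Category structure over binary object features
#'
#' Objects belong to categories; each category has its own block of
#' category-specific features, and all categories share a common block of
#' cross-category features. An object drawn from a category can only
#' activate features in its own block or the shared block, each
#' independently with probability `feature_rate`. The shared block is the
#' only pathway by which preferences learned in one category can inform
#' predictions about objects of another.
#'
#' @param blocks named list of integer index vectors, one per category.
#' @param shared integer indices of the cross-category features.
#' @param feature_rate probability that an applicable feature is active.
#' @return an object of class `category_model` with total dimension `d`.
#' @export
category_model <- function(blocks, shared = integer(), feature_rate = 0.5) {
  idx <- c(unlist(blocks, use.names = FALSE), shared)
  d <- length(idx)
  if (d == 0 || !setequal(idx, seq_len(d)) || anyDuplicated(idx)) {
    stop("blocks and shared must partition the feature indices 1..d",
         call. = FALSE)
  }
  if (feature_rate < 0 || feature_rate > 1) {
    stop("feature_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(d = d, blocks = lapply(blocks, as.integer),
         shared = as.integer(shared), feature_rate = feature_rate,
         features = paste0("f", seq_len(d))),
    class = "category_model"
  )
}

#' Default two-category feature space
#'
#' Twelve binary features: four specific to each of two categories and four
#' shared across them — a balance between within-category structure and a
#' cross-category transfer pathway. `shared_k` trims the shared block (for
#' sensitivity analyses; `shared_k = 0` removes the transfer pathway
#' entirely).
#'
#' @param shared_k number of shared features to keep (0..4).
#' @export
default_category_model <- function(shared_k = 4) {
  stopifnot(shared_k >= 0, shared_k <= 4)
  category_model(
    blocks = list(trained = 1:4, novel = 5:8),
    shared = if (shared_k > 0) 8 + seq_len(shared_k) else integer(),
    feature_rate = 0.5
  )
}

#' Sample objects from a category's feature prior
#'
#' @param cat a [category_model()].
#' @param category category label (a name of `cat$blocks`).
#' @param n number of objects.
#' @param seed integer RNG seed.
#' @return an `n x d` binary matrix with feature names as columns.
#' @export
sample_category_objects <- function(cat, category, n, seed = 1L) {
  if (!category %in% names(cat$blocks)) {
    stop("unknown category '", category, "'", call. = FALSE)
  }
  active <- c(cat$blocks[[category]], cat$shared)
  F <- matrix(0, n, cat$d, dimnames = list(NULL, cat$features))
  withr::with_seed(seed, {
    F[, active] <- stats::rbinom(n * length(active), 1, cat$feature_rate)
  })
  F
}

#' Posterior over a hidden object's features given an actor's reaction
#'
#' A hidden object of a known category is described only by the actor's
#' emotional reaction to it. Reactions are read as utility constraints on
#' the actor's (inferred) preferences:
#'
#' * `"dislike"` — the object's utility to the actor is negative;
#' * `"favorite"` — the object's utility is at least as high as that of any
#'   of `n_candidates` other objects drawn from the same category (and of
#'   the object itself, trivially); `n_candidates = 0` therefore carries no
#'   information;
#' * `"none"` — no reaction; the feature distribution is the category prior.
#'
#' Implemented by rejection: joint draws of (actor utilities, hidden-object
#' features) from the actor's posterior ensemble and the category prior are
#' kept when they satisfy the constraint.
#'
#' @param actor_post the actor's `posterior_ensemble` (dimension `cat$d`).
#' @param kind `"dislike"`, `"favorite"`, or `"none"`.
#' @param cat a [category_model()].
#' @param category the hidden object's category.
#' @param n number of joint draws.
#' @param seed integer RNG seed.
#' @param n_candidates comparison objects for `"favorite"`.
#' @return an object of class `hidden_object_posterior`: kept feature
#'   samples, matching actor-utility samples, and the acceptance rate.
#' @export
hidden_object_posterior <- function(actor_post, kind = c("none", "dislike", "favorite"),
                                    cat, category, n = 20000L, seed = 1L,
                                    n_candidates = 10L) {
  kind <- match.arg(kind)
  if (length(actor_post$features) != cat$d) {
    stop("actor posterior dimension does not match the category model",
         call. = FALSE)
  }
  fs <- sample_category_objects(cat, category, n, seed = derive_seed(seed, 1))
  wp <- normalize_log_weights(actor_post$log_weights)
  idx <- withr::with_seed(derive_seed(seed, 2), {
    sample.int(actor_post$n_draws, n, replace = TRUE, prob = wp)
  })
  W <- actor_post$draws[idx, , drop = FALSE]
  u <- rowSums(W * fs)
  keep <- switch(kind,
    none = rep(TRUE, n),
    dislike = u < 0,
    favorite = {
      if (n_candidates == 0L) {
        rep(TRUE, n)
      } else {
        cands <- sample_category_objects(cat, category, n * n_candidates,
                                         seed = derive_seed(seed, 3))
        uc <- matrix(rowSums(
          W[rep(seq_len(n), each = n_candidates), , drop = FALSE] * cands
        ), n, n_candidates, byrow = TRUE)
        u >= apply(uc, 1, max)
      }
    }
  )
  if (!any(keep)) {
    stop("reaction constraint was never satisfied in ", n,
         " draws; increase n", call. = FALSE)
  }
  structure(
    list(
      feature_samples = fs[keep, , drop = FALSE],
      actor_samples = W[keep, , drop = FALSE],
      kind = kind, category = category,
      acceptance = mean(keep), n_kept = sum(keep)
    ),
    class = "hidden_object_posterior"
  )
}

#' @export
print.hidden_object_posterior <- function(x, ...) {
  cat("<hidden_object_posterior> ", x$n_kept, " samples (", x$kind,
      ", category '", x$category, "', acceptance ",
      signif(x$acceptance, 3), ")\n", sep = "")
  invisible(x)
}

#' Predicted probability that the child picks the first hidden object
#'
#' Averages the two-option Luce-Shepard probability over joint draws of the
#' child's utilities (from her posterior) and the two hidden objects'
#' features (from their reaction-constrained posteriors).
#'
#' @param child_post the child's `posterior_ensemble`.
#' @param hidden_a1,hidden_a2 [hidden_object_posterior()] objects for the
#'   two hidden objects.
#' @param n number of Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return a one-row tibble with `prob` (of choosing object 1) and `se`.
#' @export
predict_hidden_choice <- function(child_post, hidden_a1, hidden_a2,
                                  n = 20000L, seed = 1L) {
  d <- length(child_post$features)
  if (ncol(hidden_a1$feature_samples) != d ||
      ncol(hidden_a2$feature_samples) != d) {
    stop("hidden-object posteriors do not match the child's feature space",
         call. = FALSE)
  }
  wp <- normalize_log_weights(child_post$log_weights)
  draws <- withr::with_seed(derive_seed(seed, 4), {
    list(
      w = sample.int(child_post$n_draws, n, replace = TRUE, prob = wp),
      f1 = sample.int(nrow(hidden_a1$feature_samples), n, replace = TRUE),
      f2 = sample.int(nrow(hidden_a2$feature_samples), n, replace = TRUE)
    )
  })
  W <- child_post$draws[draws$w, , drop = FALSE]
  du <- rowSums(W * hidden_a1$feature_samples[draws$f1, , drop = FALSE]) -
    rowSums(W * hidden_a2$feature_samples[draws$f2, , drop = FALSE])
  p <- stats::plogis(du)
  tibble::tibble(prob = mean(p), se = stats::sd(p) / sqrt(n))
}
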