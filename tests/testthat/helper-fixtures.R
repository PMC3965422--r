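# Small in-code fixtures shared across test files.

# One-hot option table: one indicator feature per option label.
one_hot_options <- function(labels, multiplicity = 1) {
  dplyr::bind_cols(
    tibble::tibble(option = labels, multiplicity = multiplicity),
    tibble::as_tibble(stats::setNames(
      as.data.frame(diag(length(labels))), labels
    ))
  )
}

# n repeated two-option events with a fixed chosen label.
repeat_events <- function(agent, options, chosen, n) {
  ev <- lapply(seq_len(n), function(i) {
    choice_event(agent, options, chosen = chosen, event = i)
  })
  bind_events(!!!ev)
}

# Two-feature pool with a featureless baseline, used for recovery and
# model-selection simulations.
baseline_pool <- function() {
  tibble::tibble(
    option = c("p", "q", "null"), multiplicity = 1,
    f1 = c(1, 0, 0), f2 = c(0, 1, 0)
  )
}
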