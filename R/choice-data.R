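#' Choice data: one row per option per choice event
#'
#' A `choice_data` object is a tibble in long format describing a sequence of
#' observed choice events. The reserved columns are:
#'
#' * `event` — integer event index (shared by all options of one event),
#' * `agent` — label of the agent who chose,
#' * `option` — option label, unique within an event,
#' * `multiplicity` — positive count of identical tokens of this option in
#'   the pool (type-level representation of, e.g., a box with 18 of one toy
#'   and 82 of another),
#' * `chosen` — logical, `TRUE` for exactly one option per event.
#'
#' Every remaining column is interpreted as a numeric feature; an option's
#' utility to an agent is the inner product of its feature row with the
#' agent's utility vector. Binary indicator features are typical but any
#' finite real values are allowed. Single-option events are legal: they are
#' forced choices and contribute zero log-likelihood.
#'
#' @param x a data frame with the columns described above.
#' @return `x` as a tibble with class `choice_data`, validated.
#' @examples
#' choice_data(tibble::tibble(
#'   event = c(1, 1), agent = "kid", option = c("apple", "pear"),
#'   multiplicity = 1, chosen = c(TRUE, FALSE), apple = c(1, 0), pear = c(0, 1)
#' ))
#' @export
choice_data <- function(x) {
  x <- tibble::as_tibble(x)
  reserved <- c("event", "agent", "option", "multiplicity", "chosen")
  missing_cols <- setdiff(reserved, names(x))
  if (length(missing_cols) > 0) {
    stop("choice data must have columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  feats <- setdiff(names(x), reserved)
  if (!all(vapply(x[feats], is.numeric, logical(1)))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  if (length(feats) > 0 && !all(is.finite(as.matrix(x[feats])))) {
    stop("feature values must be finite", call. = FALSE)
  }
  if (nrow(x) > 0) {
    if (any(x$multiplicity < 1) || any(x$multiplicity != floor(x$multiplicity))) {
      stop("multiplicity must be a positive integer", call. = FALSE)
    }
    n_chosen <- tapply(x$chosen, x$event, sum)
    if (any(n_chosen != 1L)) {
      stop("each event must have exactly one chosen option (event ",
           names(n_chosen)[which(n_chosen != 1L)[1]], ")", call. = FALSE)
    }
    dup <- duplicated(x[c("event", "option")])
    if (any(dup)) {
      stop("option labels must be unique within an event (event ",
           x$event[which(dup)[1]], ")", call. = FALSE)
    }
    ea <- unique(x[c("event", "agent")])
    if (anyDuplicated(ea$event)) {
      stop("all rows of one event must share an agent (event ",
           ea$event[which(duplicated(ea$event))[1]], ")", call. = FALSE)
    }
  }
  class(x) <- c("choice_data", class(x))
  x
}

#' Build one choice event as a tibble
#'
#' @param agent agent label.
#' @param options a data frame with columns `option`, optional
#'   `multiplicity` (default 1), and feature columns.
#' @param chosen label of the chosen option.
#' @param event event index (default 1; renumbered by [bind_events()]).
#' @return a one-event tibble suitable for [choice_data()].
#' @export
choice_event <- function(agent, options, chosen, event = 1L) {
  options <- tibble::as_tibble(options)
  if (!"multiplicity" %in% names(options)) options$multiplicity <- 1
  if (!chosen %in% options$option) {
    stop("chosen option '", chosen, "' is not among the options", call. = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(event = as.integer(event), agent = agent),
    options[c("option", "multiplicity")],
    options[setdiff(names(options), c("option", "multiplicity"))]
  ) |>
    dplyr::mutate(chosen = .data$option == !!chosen, .after = "multiplicity")
}

#' Stack event tibbles into one validated dataset, renumbering events
#'
#' @param ... event tibbles (from [choice_event()]) or multi-event tibbles.
#' @return a [choice_data()] object with consecutive event indices.
#' @export
bind_events <- function(...) {
  pieces <- purrr::compact(rlang::list2(...))
  if (length(pieces) == 0) {
    return(choice_data(tibble::tibble(
      event = integer(), agent = character(), option = character(),
      multiplicity = numeric(), chosen = logical()
    )))
  }
  renumbered <- vector("list", length(pieces))
  offset <- 0L
  for (i in seq_along(pieces)) {
    p <- tibble::as_tibble(pieces[[i]])
    ids <- match(p$event, unique(p$event))
    p$event <- offset + ids
    offset <- offset + length(unique(ids))
    renumbered[[i]] <- p
  }
  choice_data(dplyr::bind_rows(renumbered))
}

#' Names of the feature columns of a choice dataset or option table
#' @param x a `choice_data` object or an options tibble.
#' @export
feature_names <- function(x) {
  setdiff(names(x), c("event", "agent", "option", "multiplicity", "chosen"))
}

# Internal dense representation used by the likelihood code: feature matrix,
# multiplicities, event grouping and chosen-row indices.
as_choice_matrices <- function(data, features = NULL) {
  if (is.null(features)) features <- feature_names(data)
  event_ids <- unique(data$event)
  event <- match(data$event, event_ids)
  chosen_rows <- which(data$chosen)[order(event[data$chosen])]
  list(
    F = as.matrix(data[features]),
    mult = as.numeric(data$multiplicity),
    event = event,
    n_events = length(event_ids),
    chosen_rows = chosen_rows,
    agent_of_event = data$agent[chosen_rows],
    features = features
  )
}

#' Write / read choice data as JSON lines
#'
#' One JSON object per event: agent label, options with named feature maps
#' and multiplicities, and the 1-based index of the chosen option. The
#' round-trip is lossless. On reading, the feature set is taken from the
#' first record and enforced for all others; malformed records are rejected
#' with the offending line number.
#'
#' @param data a [choice_data()] object.
#' @param path file path.
#' @return `write_choice_data()` returns `path` invisibly;
#'   `read_choice_data()` returns a [choice_data()] object.
#' @export
write_choice_data <- function(data, path) {
  feats <- feature_names(data)
  lines <- vapply(split(seq_len(nrow(data)), data$event), function(idx) {
    rows <- data[idx, ]
    opts <- lapply(seq_len(nrow(rows)), function(i) {
      list(
        id = rows$option[i],
        features = as.list(rows[i, feats, drop = FALSE]),
        multiplicity = rows$multiplicity[i]
      )
    })
    jsonlite::toJSON(
      list(agent = rows$agent[1], options = opts, chosen = which(rows$chosen)),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(bind_events())
  }
  feats <- NULL
  events <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
      error = function(e) stop("line ", ln, ": malformed JSON record (",
                               conditionMessage(e), ")", call. = FALSE)
    )
    if (is.null(rec$agent) || is.null(rec$options) || is.null(rec$chosen)) {
      stop("line ", ln, ": record must have agent, options and chosen",
           call. = FALSE)
    }
    n_opts <- length(rec$options)
    chosen <- rec$chosen
    if (!is.numeric(chosen) || chosen < 1 || chosen > n_opts) {
      stop("line ", ln, ": chosen index ", chosen, " out of range 1..",
           n_opts, call. = FALSE)
    }
    f0 <- names(rec$options[[1]]$features)
    if (is.null(feats)) feats <- f0
    for (o in rec$options) {
      if (!identical(names(o$features), feats)) {
        stop("line ", ln, ": feature names differ from the first record",
             call. = FALSE)
      }
    }
    opt_tbl <- purrr::map_dfr(rec$options, function(o) {
      dplyr::bind_cols(
        tibble::tibble(option = o$id, multiplicity = o$multiplicity %||% 1),
        tibble::as_tibble(lapply(o$features, as.numeric))
      )
    })
    events[[ln]] <- choice_event(
      agent = rec$agent, options = opt_tbl,
      chosen = opt_tbl$option[[chosen]], event = ln
    )
  }
  choice_data(dplyr::bind_rows(events))
}

#' Export choice data as a flat CSV (long format)
#'
#' Convenience export for downstream analysis; the JSON-lines format of
#' [write_choice_data()] is the canonical lossless one.
#' @inheritParams write_choice_data
#' @export
write_choice_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
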