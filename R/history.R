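# Replicate joint biogeographic histories: container, validation, JSON format.
#
# A mapped history enumerates branches (indexed consistently with the tree's
# traversal order), capturing start/end states and ages, and a structured list
# of typed, timed events per branch.  The JSON serialization is versioned and
# extensible: unknown fields are preserved on read and written back.

HISTORY_FORMAT_VERSION <- "1.0"
EVENT_KINDS <- c("ANAGENETIC", "CLADOGENETIC_NODE", "CLADOGENETIC_HIDDEN")

#' Construct a mapped history
#'
#' @param branches list of branch records; each a list with `branch_index`,
#'   `parent_node`, `child_node`, `start_age`, `end_age`, `start_state`,
#'   `end_state`, and `events` (a list of event records with `age`, `kind`,
#'   `move_class`, `from_state`, `to_states`, `state_changed`).  Extra fields
#'   (e.g. `extinct`, `sibling_state`) are preserved.
#' @param root_state state index at the root.
#' @param root_age age of the root, Ma.
#' @param root_event optional cladogenetic event record at the root node (used
#'   by the stochastic mapper, where the root is not carried by any branch).
#' @param space optional `state_space` for validation against state indices.
#' @param validate check internal consistency (default `TRUE`).
#' @return an object of class `mapped_history`.
#' @export
mapped_history <- function(branches, root_state, root_age, root_event = NULL,
                           space = NULL, validate = TRUE) {
  h <- structure(list(format_version = HISTORY_FORMAT_VERSION,
                      root_state = as.integer(root_state),
                      root_age = as.numeric(root_age),
                      root_event = root_event,
                      branches = branches),
                 class = "mapped_history")
  if (validate) validate_history(h, space)
  h
}

#' @export
print.mapped_history <- function(x, ...) {
  n_ev <- sum(vapply(x$branches, function(b) length(b$events), integer(1)))
  cat("Mapped history:", length(x$branches), "branches,", n_ev,
      "events, root age", format(x$root_age), "Ma\n")
  invisible(x)
}

#' Validate a mapped history
#'
#' Checks that ages decrease tip-ward along each branch, that consecutive
#' event states chain (each event's `from_state` equals the previous event's
#' outcome), that branch start/end states are consistent with the first/last
#' events, and (when a `state_space` is given) that all states are members of
#' the space.  Errors name the offending branch and event.
#'
#' @param history a `mapped_history`.
#' @param space optional `state_space`.
#' @return the history, invisibly.
#' @export
validate_history <- function(history, space = NULL) {
  stopifnot(inherits(history, "mapped_history"))
  check_state <- function(s, where) {
    if (!is.null(space) && (anyNA(s) || any(s < 1L) || any(s > space$n_states)))
      stop("state outside state space at ", where)
  }
  check_state(history$root_state, "root")
  for (b in history$branches) {
    id <- b$branch_index
    if (b$start_age < b$end_age)
      stop("branch ", id, ": start_age must not be younger than end_age")
    check_state(c(b$start_state, b$end_state), paste("branch", id))
    cur <- b$start_state
    last_age <- b$start_age
    n_ev <- length(b$events)
    for (k in seq_len(n_ev)) {
      ev <- b$events[[k]]
      if (!ev$kind %in% EVENT_KINDS)
        stop("branch ", id, " event ", k, ": unknown kind '", ev$kind, "'")
      if (ev$age > last_age + 1e-9 || ev$age < b$end_age - 1e-9)
        stop("branch ", id, " event ", k, ": age outside branch interval")
      if (ev$from_state != cur)
        stop("branch ", id, " event ", k, ": broken state chaining (from_state ",
             ev$from_state, ", expected ", cur, ")")
      check_state(c(ev$from_state, ev$to_states), paste("branch", id, "event", k))
      expected_change <- any(ev$to_states != ev$from_state)
      if (!identical(as.logical(ev$state_changed), expected_change))
        stop("branch ", id, " event ", k, ": state_changed flag inconsistent")
      if (ev$kind == "CLADOGENETIC_NODE") {
        if (k != n_ev)
          stop("branch ", id, " event ", k, ": node event not at branch end")
        if (length(ev$to_states) != 2L)
          stop("branch ", id, " event ", k, ": node event needs two daughters")
      } else {
        if (length(ev$to_states) != 1L)
          stop("branch ", id, " event ", k, ": expected a single target state")
        cur <- ev$to_states
      }
      last_age <- ev$age
    }
    if (cur != b$end_state)
      stop("branch ", id, ": end_state ", b$end_state,
           " inconsistent with event chain (reached ", cur, ")")
  }
  invisible(history)
}

# -- JSON serialization -------------------------------------------------------

history_to_jsonable <- function(h) {
  x <- unclass(h)
  x$branches <- lapply(x$branches, function(b) {
    b$events <- lapply(b$events, function(ev) {
      ev$to_states <- I(as.integer(ev$to_states))  # keep arrays as arrays
      ev
    })
    b
  })
  if (is.null(x$root_event)) x$root_event <- NULL
  x
}

jsonable_to_history <- function(x, validate = TRUE, space = NULL) {
  as_event <- function(ev) {
    ev$age <- as.numeric(ev$age)
    ev$from_state <- as.integer(ev$from_state)
    ev$to_states <- as.integer(unlist(ev$to_states))
    ev$state_changed <- as.logical(ev$state_changed)
    if (!is.null(ev$sibling_state)) ev$sibling_state <- as.integer(ev$sibling_state)
    if (is.null(ev$move_class) || is.na(ev$move_class[1]))
      ev$move_class <- NA_character_
    ev
  }
  branches <- lapply(x$branches, function(b) {
    for (f in c("branch_index", "parent_node", "child_node"))
      b[[f]] <- as.integer(b[[f]])
    for (f in c("start_age", "end_age")) b[[f]] <- as.numeric(b[[f]])
    b$start_state <- as.integer(b$start_state)
    b$end_state <- as.integer(b$end_state)
    if (!is.null(b$extinct)) b$extinct <- as.logical(b$extinct)
    b$events <- lapply(b$events, as_event)
    b
  })
  root_event <- x$root_event
  if (!is.null(root_event)) root_event <- as_event(root_event)
  h <- structure(list(format_version = as.character(x$format_version),
                      root_state = as.integer(x$root_state),
                      root_age = as.numeric(x$root_age),
                      root_event = root_event,
                      branches = branches),
                 class = "mapped_history")
  extra <- setdiff(names(x), names(h))
  h[extra] <- x[extra]   # unknown top-level fields preserved
  if (validate) validate_history(h, space)
  h
}

#' Write replicate histories to a JSON file
#'
#' @param histories a single `mapped_history` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_histories()]
#' @export
write_histories <- function(histories, path) {
  if (inherits(histories, "mapped_history")) histories <- list(histories)
  lapply(histories, validate_history)
  payload <- list(format_version = HISTORY_FORMAT_VERSION,
                  n_histories = length(histories),
                  histories = lapply(histories, history_to_jsonable))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read replicate histories from a JSON file
#'
#' The inverse of [write_histories()]: `read_histories(write_histories(h))`
#' reproduces `h` exactly.  Schema violations raise errors that name the
#' offending branch and event.
#'
#' @param path JSON file written by [write_histories()] (or conforming to the
#'   same schema).
#' @param space optional `state_space` to validate state indices against.
#' @return list of `mapped_history` objects.
#' @export
read_histories <- function(path, space = NULL) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$histories))
    stop("file does not contain a 'histories' field")
  lapply(x$histories, jsonable_to_history, validate = TRUE, space = space)
}
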