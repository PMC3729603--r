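#' Injectable clocks
#'
#' Every timestamp the engine records comes from an injectable clock -- a
#' zero-argument function returning a `POSIXct` -- so tests can make exact
#' duration assertions.  `step_clock()` builds a deterministic clock that
#' starts at a given instant and advances a fixed number of seconds per
#' call; production code uses the default `Sys.time`.
#'
#' @param start first instant returned (ISO 8601 string or `POSIXct`).
#' @param step seconds added per subsequent call.
#' @return a clock function.
#' @export
step_clock <- function(start = "2026-01-01T00:00:00Z", step = 1) {
  t <- parse_iso8601(start)
  first <- TRUE
  function() {
    if (first) first <<- FALSE else t <<- t + step
    t
  }
}

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso8601 <- function(s) {
  if (inherits(s, "POSIXct")) return(s)
  as.POSIXct(s, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
}

the <- new.env(parent = emptyenv())
the$session_counter <- 0L

#' Start a respondent session
#'
#' Opens an in-progress session for one respondent, enforcing the
#' identifier policies: when `requireRespondentId` (or `requireVisitCode`)
#' is set, a missing identifier is a policy error naming the policy key.
#' Practice items shown before the test are never recorded here; only
#' scored test-item responses enter the record.
#'
#' @param instr an [instrument()].
#' @param respondent_id optional external identifier for the respondent.
#' @param visit_code optional visit identifier.
#' @param locale session locale tag used to resolve localized text.
#' @param clock injectable clock (see [step_clock()]).
#' @param session_id optional explicit id; defaults to a counter-based id.
#' @return a `session_record` with status `"in_progress"` and the item
#'   cursor at the first item.
#' @export
start_session <- function(instr, respondent_id = NULL, visit_code = NULL,
                          locale = "", clock = Sys.time, session_id = NULL) {
  stopifnot(inherits(instr, "instrument"))
  if (instr$policies$require_respondent_id && is.null(respondent_id)) {
    adaptest_error("policy",
      "policy requireRespondentId: a respondent id must be provided before starting",
      policy_key = "requireRespondentId")
  }
  if (instr$policies$require_visit_code && is.null(visit_code)) {
    adaptest_error("policy",
      "policy requireVisitCode: a visit code must be provided before starting",
      policy_key = "requireVisitCode")
  }
  if (is.null(session_id)) {
    the$session_counter <- the$session_counter + 1L
    session_id <- sprintf("session-%d", the$session_counter)
  }
  structure(list(
    session_id = session_id,
    respondent_id = respondent_id,
    visit_code = visit_code,
    locale = locale,
    responses = list(),
    start = clock(),
    end = NULL,
    duration = NULL,
    score = NULL,
    status = "in_progress",
    submitted = FALSE,
    cursor = 0L
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s  %s  %d response(s)%s\n", x$session_id,
              x$status, length(x$responses),
              if (is.null(x$score)) "" else sprintf("  score=%.4f", x$score)))
  invisible(x)
}

# The item the session expects next: static instruments walk the items in
# number order; instruments scored by a pre-computed adaptive tree follow
# the tree, so the expected item is the one at the current tree node.
current_item <- function(session, instr, assets = list()) {
  comp <- instr$computation
  if (!is.null(comp) && identical(comp$method, "cat_tree")) {
    tree <- assets$cat_tree
    if (is.null(tree)) {
      adaptest_error("missing_asset",
        "this instrument is scored by an adaptive tree; pass it via assets$cat_tree")
    }
    if (session$cursor >= tree$depth) return(NULL)
    node <- 1L
    for (r in session$responses) node <- 2L * node + as.integer(r$value)
    return(list(id = tree$item_id[node]))
  }
  items <- items_in_order(instr)
  if (session$cursor >= length(items)) return(NULL)
  items[[session$cursor + 1L]]
}

#' Record one response in a session
#'
#' Validates that the session is in progress, that `item_id` is the item
#' the session currently expects (items are administered strictly in
#' order), and that `response_id` is legal for the item's category; stores
#' the mapped numeric value with a timestamp and advances the cursor.
#' When the `requireVideoViewing` policy is set and the item carries media,
#' a `media_completed` presentation event must accompany the response.
#'
#' @param session an in-progress `session_record`.
#' @param instr the [instrument()] being administered.
#' @param item_id id of the item being answered.
#' @param response_id id of the selected response.
#' @param events character vector of presentation event kinds observed for
#'   this item (e.g. `c("media_started", "media_completed")`).
#' @param clock injectable clock.
#' @param assets extra artifacts the instrument references; for
#'   tree-scored instruments, `assets$cat_tree` must hold the
#'   [build_cat_tree()] object.
#' @return the updated `session_record`.
#' @export
record_response <- function(session, instr, item_id, response_id,
                            events = character(), clock = Sys.time,
                            assets = list()) {
  stopifnot(inherits(session, "session_record"))
  if (session$status != "in_progress") {
    adaptest_error("session_state",
      sprintf("cannot record a response in a %s session", session$status))
  }
  expected <- current_item(session, instr, assets)
  if (is.null(expected)) {
    adaptest_error("sequence",
      "all items are already answered; complete the session instead")
  }
  if (!identical(item_id, expected$id)) {
    adaptest_error("sequence",
      sprintf("out-of-order response: expected item '%s', got '%s'",
              expected$id, item_id))
  }
  item <- NULL
  for (it in instr$items) if (identical(it$id, item_id)) item <- it
  if (is.null(item)) {
    adaptest_error("sequence", sprintf("unknown item '%s'", item_id))
  }
  if (instr$policies$require_video_viewing && !is.null(item$media) &&
      !"media_completed" %in% events) {
    adaptest_error("policy",
      paste0("policy requireVideoViewing: item '", item_id,
             "' must have its media viewed to completion before a response"),
      policy_key = "requireVideoViewing")
  }
  category <- find_category(instr, item$scoring_category)
  value <- map_response(category, response_id)
  session$responses[[length(session$responses) + 1L]] <-
    list(item_id = item_id, response_id = response_id, value = value,
         timestamp = clock())
  session$cursor <- session$cursor + 1L
  session
}

# mapped response values of a session, in recorded (administration) order
session_values <- function(session) {
  vapply(session$responses, `[[`, numeric(1), "value")
}

#' Complete a session and compute its score
#'
#' Requires every item to be answered; sets the end timestamp and the
#' duration in whole seconds; computes the score through the instrument's
#' declared score computation, if any (lookup table, scoring expression,
#' or the leaf of the adaptive tree), and marks the session completed.
#' Instruments without a score computation complete with no score.
#'
#' @inheritParams record_response
#' @param assets list with optional entries `lookup_table` (a
#'   [lookup_table()]) and `cat_tree` (a [build_cat_tree()] tree); when a
#'   referenced asset is absent, `base_dir` is consulted to load it from
#'   the file named in the instrument's score computation.
#' @return the completed `session_record`.
#' @export
complete_session <- function(session, instr, assets = list(),
                             clock = Sys.time) {
  stopifnot(inherits(session, "session_record"))
  if (session$status != "in_progress") {
    adaptest_error("session_state",
      sprintf("cannot complete a %s session", session$status))
  }
  if (!is.null(current_item(session, instr, assets))) {
    adaptest_error("incomplete",
      sprintf("%d of %d items answered; a session completes only when every item is answered",
              length(session$responses), expected_length(instr, assets)))
  }
  session$end <- clock()
  session$duration <- as.integer(round(as.numeric(
    difftime(session$end, session$start, units = "secs"))))
  comp <- instr$computation
  if (!is.null(comp)) {
    session$score <- switch(comp$method,
      lookup_table = {
        table <- assets$lookup_table %||% read_lookup_table(
          file.path(assets$base_dir %||% ".", comp$lookup_table_file))
        score_lookup(table, session_values(session))
      },
      scoring_function = score_function(comp$scoring_expression,
                                        session_values(session)),
      cat_tree = {
        tree <- assets$cat_tree %||% read_cat_tree(
          file.path(assets$base_dir %||% ".", comp$cat_tree_file))
        state <- cat_start(tree)
        for (r in session$responses) {
          state <- cat_next(tree, state, as.integer(r$value))
        }
        state$score
      })
  }
  session$status <- "completed"
  session
}

expected_length <- function(instr, assets = list()) {
  comp <- instr$computation
  if (!is.null(comp) && identical(comp$method, "cat_tree") &&
      !is.null(assets$cat_tree)) {
    return(assets$cat_tree$depth)
  }
  length(instr$items)
}

#' Discard an in-progress session
#'
#' Discarded sessions are retained in the store (flagged, not deleted) but
#' excluded from export and submission.  Completed sessions cannot be
#' discarded.
#'
#' @param session an in-progress `session_record`.
#' @return the session with status `"discarded"`.
#' @export
discard_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  if (session$status != "in_progress") {
    adaptest_error("session_state",
      sprintf("cannot discard a %s session", session$status))
  }
  session$status <- "discarded"
  session
}

# ---------------------------------------------------------------------------
# Persistence

session_to_list <- function(s) {
  list(
    session_id = s$session_id,
    respondent_id = s$respondent_id,
    visit_code = s$visit_code,
    locale = s$locale,
    responses = lapply(s$responses, function(r) {
      list(item_id = r$item_id, response_id = r$response_id,
           value = r$value, timestamp = format_iso8601(r$timestamp))
    }),
    start = format_iso8601(s$start),
    end = if (is.null(s$end)) NULL else format_iso8601(s$end),
    duration = s$duration,
    score = s$score,
    status = s$status,
    submitted = s$submitted,
    cursor = s$cursor
  )
}

session_from_list <- function(x) {
  structure(list(
    session_id = x$session_id,
    respondent_id = x$respondent_id,
    visit_code = x$visit_code,
    locale = x$locale,
    responses = lapply(x$responses, function(r) {
      list(item_id = r$item_id, response_id = r$response_id,
           value = as.numeric(r$value), timestamp = parse_iso8601(r$timestamp))
    }),
    start = parse_iso8601(x$start),
    end = if (is.null(x$end)) NULL else parse_iso8601(x$end),
    duration = if (is.null(x$duration)) NULL else as.integer(x$duration),
    score = if (is.null(x$score)) NULL else as.numeric(x$score),
    status = x$status,
    submitted = isTRUE(x$submitted),
    cursor = as.integer(x$cursor)
  ), class = "session_record")
}

#' Persist and reload a session store
#'
#' The store is a single JSON document holding every session.  Each
#' `persist_store()` over an existing store first copies the previous file
#' to a timestamped backup (`<path>.bak-<stamp>`), so completed responses
#' already on disk survive a crash or a corrupted rewrite; a corrupt store
#' fails to load with a recovery hint naming the newest backup.
#'
#' @param sessions list of `session_record`s.
#' @param path store file path.
#' @param clock injectable clock used for backup stamps.
#' @return `persist_store()` returns `path` invisibly; `load_store()`
#'   returns the list of sessions.
#' @export
persist_store <- function(sessions, path, clock = Sys.time) {
  if (file.exists(path)) {
    stamp <- format(clock(), "%Y%m%dT%H%M%SZ", tz = "UTC")
    backup <- paste0(path, ".bak-", stamp)
    k <- 1L
    while (file.exists(backup)) {
      backup <- paste0(path, ".bak-", stamp, "-", k)
      k <- k + 1L
    }
    file.copy(path, backup, copy.date = TRUE)
  }
  payload <- list(store_version = 1L,
                  sessions = lapply(sessions, session_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname persist_store
#' @export
load_store <- function(path) {
  if (!file.exists(path)) {
    adaptest_error("missing_file", sprintf("session store not found: %s", path))
  }
  parsed <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      backups <- sort(Sys.glob(paste0(path, ".bak-*")), decreasing = TRUE)
      hint <- if (length(backups) > 0L) {
        sprintf("; newest backup: %s", backups[1])
      } else {
        "; no backups found"
      }
      adaptest_error("corrupt_store",
        sprintf("cannot read session store %s (%s)%s", path,
                conditionMessage(e), hint))
    })
  lapply(parsed$sessions, session_from_list)
}

#' Export completed sessions as a single analysis-ready table
#'
#' Writes one CSV row per completed session -- in-progress and discarded
#' sessions are excluded -- with columns `session_id`, `respondent_id`,
#' `visit_code`, `start` (ISO 8601), `duration_s`, one column per item id
#' holding the mapped response value (items in number order regardless of
#' administration order), and `score`.
#'
#' @param sessions list of `session_record`s.
#' @param instr the [instrument()] the sessions belong to.
#' @param path output CSV path.
#' @return the number of exported rows, invisibly.
#' @export
export_table <- function(sessions, instr, path) {
  items <- items_in_order(instr)
  item_ids <- vapply(items, `[[`, character(1), "id")
  completed <- Filter(function(s) s$status == "completed", sessions)
  rows <- lapply(completed, function(s) {
    values <- stats::setNames(rep(NA_real_, length(item_ids)), item_ids)
    for (r in s$responses) values[[r$item_id]] <- r$value
    c(list(session_id = s$session_id,
           respondent_id = s$respondent_id %||% NA_character_,
           visit_code = s$visit_code %||% NA_character_,
           start = format_iso8601(s$start),
           duration_s = s$duration),
      as.list(values),
      list(score = s$score %||% NA_real_))
  })
  header <- c("session_id", "respondent_id", "visit_code", "start",
              "duration_s", item_ids, "score")
  df <- if (length(rows) == 0L) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(header)),
                                  header), check.names = FALSE)
  } else {
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[header], check.names = FALSE, optional = TRUE)
    }))
  }
  names(df) <- header
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(length(rows))
}

# ---------------------------------------------------------------------------
# Submission queue

#' At-least-once submission of completed sessions
#'
#' Completed sessions of instruments with a `serverSubmissionURL` policy
#' are queued and flushed through a pluggable transport.  A session leaves
#' the queue only when the transport acknowledges the delivery; failed
#' attempts stay queued with the attempt logged, so a submission that
#' fails when the test completes is retried by a later flush.
#'
#' @return `submission_queue()` returns an empty queue.
#' @export
submission_queue <- function() {
  structure(list(pending = character(), attempts = list()),
            class = "submission_queue")
}

#' @rdname submission_queue
#' @param queue a `submission_queue`.
#' @param session a completed `session_record`.
#' @param instr the [instrument()]; when its policies carry no
#'   `serverSubmissionURL`, enqueueing is a no-op.
#' @export
enqueue_submission <- function(queue, session, instr) {
  stopifnot(inherits(queue, "submission_queue"))
  if (is.null(instr$policies$server_submission_url)) return(queue)
  if (session$status != "completed") {
    adaptest_error("session_state", "only completed sessions are submitted")
  }
  if (!session$session_id %in% queue$pending) {
    queue$pending <- c(queue$pending, session$session_id)
  }
  queue
}

# One session serialized as a self-contained submission payload.
session_payload <- function(session) {
  jsonlite::toJSON(list(payload_version = 1L,
                        session = session_to_list(session)),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname submission_queue
#' @param sessions named or unnamed list of `session_record`s covering the
#'   queued ids.
#' @param transport function `(url, payload_json)` returning `TRUE` on an
#'   acknowledged delivery; a `FALSE` return or an error counts as a
#'   failed attempt.
#' @param clock injectable clock for the attempt log.
#' @return `flush_queue()` returns a list with the updated `queue`, the
#'   updated `sessions` (successes marked `submitted`), and per-session
#'   logical `outcomes`.
#' @export
flush_queue <- function(queue, sessions, instr, transport,
                        clock = Sys.time) {
  stopifnot(inherits(queue, "submission_queue"), is.function(transport))
  url <- instr$policies$server_submission_url
  ids <- vapply(sessions, `[[`, character(1), "session_id")
  outcomes <- stats::setNames(logical(0), character(0))
  still_pending <- character()
  for (sid in queue$pending) {
    i <- match(sid, ids)
    if (is.na(i)) {
      still_pending <- c(still_pending, sid)
      next
    }
    ok <- tryCatch(isTRUE(transport(url, session_payload(sessions[[i]]))),
                   error = function(e) FALSE)
    queue$attempts[[sid]] <- c(queue$attempts[[sid]],
                               list(list(time = format_iso8601(clock()),
                                         ok = ok)))
    if (ok) {
      sessions[[i]]$submitted <- TRUE
    } else {
      still_pending <- c(still_pending, sid)
    }
    outcomes[[sid]] <- ok
  }
  queue$pending <- still_pending
  list(queue = queue, sessions = sessions, outcomes = outcomes)
}
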