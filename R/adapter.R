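#' Presentation adapters
#'
#' The engine never talks to a screen directly: administration goes through
#' a pluggable adapter, a list of four functions, so the same logic drives
#' a terminal, a GUI, or a test script.
#'
#' * `collect_identifiers(policies)` -- returns
#'   `list(respondent_id =, visit_code =)` (either may be `NULL`).
#' * `show_instructions(text, practice)` -- present instruction text and
#'   practice items; practice responses are never recorded.
#' * `present_item(item, category, locale)` -- present one item and return
#'   `list(response_id =, events =)`, where `events` is a character vector
#'   of presentation event kinds (`"media_started"`, `"media_completed"`).
#' * `show_score(score)` -- called only when the `showComputedScore`
#'   policy is set and a score was computed.
#'
#' `scripted_adapter()` replays a fixed vector of response ids (cycling
#' per call order) and reports full media viewing, which makes whole-session
#' tests deterministic.  `terminal_adapter()` reads responses
#' interactively from the console.
#'
#' @param response_ids character vector of response ids replayed in
#'   presentation order (practice items consume entries too).
#' @param respondent_id,visit_code identifiers the scripted respondent
#'   supplies.
#' @param watch_media whether the scripted respondent "views" item media to
#'   completion (controls the emitted presentation events).
#' @return an adapter list as described above.
#' @export
scripted_adapter <- function(response_ids, respondent_id = NULL,
                             visit_code = NULL, watch_media = TRUE) {
  i <- 0L
  seen <- new.env(parent = emptyenv())
  seen$score <- NULL
  seen$instructions <- NULL
  adapter <- list(
    collect_identifiers = function(policies) {
      list(respondent_id = respondent_id, visit_code = visit_code)
    },
    show_instructions = function(text, practice) {
      seen$instructions <- text
      invisible(NULL)
    },
    present_item = function(item, category, locale) {
      i <<- i + 1L
      id <- response_ids[((i - 1L) %% length(response_ids)) + 1L]
      events <- if (!is.null(item$media)) {
        if (watch_media) c("media_started", "media_completed") else "media_started"
      } else {
        character()
      }
      list(response_id = id, events = events)
    },
    show_score = function(score) {
      seen$score <- score
      invisible(NULL)
    },
    seen = seen
  )
  adapter
}

#' @rdname scripted_adapter
#' @export
terminal_adapter <- function() {
  list(
    collect_identifiers = function(policies) {
      rid <- if (policies$require_respondent_id) {
        readline("Respondent id: ")
      } else {
        NULL
      }
      vc <- if (policies$require_visit_code) readline("Visit code: ") else NULL
      list(respondent_id = rid, visit_code = vc)
    },
    show_instructions = function(text, practice) {
      cat(text, "\n")
      invisible(NULL)
    },
    present_item = function(item, category, locale) {
      cat("\n", resolve_text(item$description, locale), "\n", sep = "")
      ids <- vapply(category$responses, `[[`, character(1), "id")
      labels <- vapply(category$responses,
                       function(r) resolve_text(r$label, locale), character(1))
      for (k in seq_along(ids)) {
        cat(sprintf("  [%d] %s (%s)\n", k, labels[k], ids[k]))
      }
      repeat {
        pick <- suppressWarnings(as.integer(readline("Response number: ")))
        if (!is.na(pick) && pick >= 1L && pick <= length(ids)) break
        cat("Please enter a number between 1 and", length(ids), "\n")
      }
      list(response_id = ids[pick],
           events = if (!is.null(item$media)) {
             c("media_started", "media_completed")
           } else {
             character()
           })
    },
    show_score = function(score) {
      cat(sprintf("\nYour score: %.4f\n", score))
      invisible(NULL)
    }
  )
}

#' Administer one full session through an adapter
#'
#' Drives the complete lifecycle: identifier collection (as required by
#' policy), instructions and unscored practice items, the test items in
#' their prescribed -- static or adaptive -- order, completion and
#' scoring.  The computed score is revealed to the adapter only when the
#' `showComputedScore` policy allows it.
#'
#' @param instr a valid [instrument()].
#' @param adapter a presentation adapter (see [scripted_adapter()]).
#' @param locale session locale.
#' @param clock injectable clock.
#' @param assets score-computation artifacts, as in [complete_session()].
#' @param session_id optional explicit session id (defaults to a counter).
#' @return the completed `session_record`.
#' @export
administer_session <- function(instr, adapter, locale = "",
                               clock = Sys.time, assets = list(),
                               session_id = NULL) {
  ids <- adapter$collect_identifiers(instr$policies)
  session <- start_session(instr, respondent_id = ids$respondent_id,
                           visit_code = ids$visit_code, locale = locale,
                           clock = clock, session_id = session_id)
  if (!is.null(instr$instructions)) {
    adapter$show_instructions(
      resolve_text(instr$instructions$instruction_text, locale),
      instr$instructions$practice_items)
    for (p in instr$instructions$practice_items) {
      category <- find_category(instr, p$scoring_category)
      adapter$present_item(p, category, locale)  # presented, never recorded
    }
  }
  repeat {
    expected <- current_item(session, instr, assets)
    if (is.null(expected)) break
    item <- NULL
    for (it in instr$items) if (identical(it$id, expected$id)) item <- it
    category <- find_category(instr, item$scoring_category)
    answer <- adapter$present_item(item, category, locale)
    session <- record_response(session, instr, item$id, answer$response_id,
                               events = answer$events %||% character(),
                               clock = clock, assets = assets)
  }
  session <- complete_session(session, instr, assets = assets, clock = clock)
  if (instr$policies$show_computed_score && !is.null(session$score)) {
    adapter$show_score(session$score)
  }
  session
}
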