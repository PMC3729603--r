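answer_all <- function(session, instr, ids = c("yes", "yes", "no"),
                       clock = step_clock(), assets = list()) {
  items <- c("q1", "q2", "q3")
  for (k in seq_along(items)) {
    session <- record_response(session, instr, items[k], ids[k],
                               events = c("media_started", "media_completed"),
                               clock = clock, assets = assets)
  }
  session
}

test_that("identifier policies gate session start, naming the policy key", {
  open <- toy_instrument()
  s <- start_session(open, clock = step_clock())
  expect_identical(s$status, "in_progress")

  gated <- toy_instrument(policies = instrument_policies(require_respondent_id = TRUE))
  err <- tryCatch(start_session(gated), error = identity)
  expect_s3_class(err, "adaptest_policy")
  expect_match(conditionMessage(err), "requireRespondentId")
  ok <- start_session(gated, respondent_id = "R1")
  expect_identical(ok$respondent_id, "R1")

  visit <- toy_instrument(policies = instrument_policies(require_visit_code = TRUE))
  err <- tryCatch(start_session(visit, respondent_id = "R1"), error = identity)
  expect_match(conditionMessage(err), "requireVisitCode")
  expect_no_error(start_session(visit, visit_code = "V2"))
})

test_that("responses must arrive in order, legal, and policy-compliant", {
  instr <- toy_instrument()
  clock <- step_clock()
  s <- start_session(instr, clock = clock)
  expect_error(record_response(s, instr, "q3", "yes", clock = clock),
               class = "adaptest_sequence")
  s <- record_response(s, instr, "q1", "yes", clock = clock)
  expect_identical(s$cursor, 1L)
  expect_error(record_response(s, instr, "q2", "maybe", clock = clock),
               class = "adaptest_unknown_response")

  # video-viewing gate: same instrument, policy flipped on
  strict <- toy_instrument(policies = instrument_policies(require_video_viewing = TRUE))
  s2 <- start_session(strict, clock = clock)
  err <- tryCatch(record_response(s2, strict, "q1", "yes",
                                  events = "media_started", clock = clock),
                  error = identity)
  expect_s3_class(err, "adaptest_policy")
  expect_match(conditionMessage(err), "requireVideoViewing")
  expect_no_error(record_response(s2, strict, "q1", "yes",
                                  events = c("media_started", "media_completed"),
                                  clock = clock))
  # without the policy the same partial viewing is accepted
  expect_no_error(record_response(s, instr, "q2", "yes",
                                  events = "media_started", clock = clock))
})

test_that("completion requires every item, stamps duration, and scores", {
  instr <- toy_instrument()
  clock <- step_clock("2026-03-01T10:00:00Z", step = 30)
  s <- start_session(instr, clock = clock)
  expect_error(complete_session(s, instr, clock = clock),
               class = "adaptest_incomplete")
  s <- answer_all(s, instr, clock = clock)
  done <- complete_session(s, instr, clock = clock)
  expect_identical(done$status, "completed")
  # clock ticks: start, 3 responses, end -> 4 steps of 30 s
  expect_identical(done$duration, 120L)
  expect_null(done$score)  # no scoreComputation declared

  expect_error(record_response(done, instr, "q1", "yes", clock = clock),
               class = "adaptest_session_state")
})

test_that("the three scoring mechanisms agree with their modules", {
  bank <- toy_bank()
  tbl <- build_lookup_table(toy_instrument(), bank)

  with_lookup <- toy_instrument(score_computation(lookup_table_file = "scores.tsv"))
  s <- answer_all(start_session(with_lookup, clock = step_clock()), with_lookup)
  done <- complete_session(s, with_lookup, assets = list(lookup_table = tbl),
                           clock = step_clock())
  expect_identical(done$score, score_lookup(tbl, c(1, 1, 0)))

  with_fn <- toy_instrument(score_computation(scoring_expression = "value/2"))
  s <- answer_all(start_session(with_fn, clock = step_clock()), with_fn)
  done <- complete_session(s, with_fn, clock = step_clock())
  expect_identical(done$score, 1)  # (1+1+0)/2

  # adaptive instrument: the tree dictates item order and the leaf scores
  tree <- build_cat_tree(bank, 2)
  adaptive <- toy_instrument(score_computation(cat_tree_file = "tree.tsv"))
  assets <- list(cat_tree = tree)
  clock <- step_clock()
  s <- start_session(adaptive, clock = clock)
  for (k in 1:2) {
    expected <- adaptest:::current_item(s, adaptive, assets)
    s <- record_response(s, adaptive, expected$id, "yes", clock = clock,
                         assets = assets)
  }
  done <- complete_session(s, adaptive, assets = assets, clock = clock)
  st <- cat_start(tree)
  st <- cat_next(tree, st, 1)
  st <- cat_next(tree, st, 1)
  expect_identical(done$score, st$score)
})

test_that("discarded sessions are retained but never exported", {
  instr <- toy_instrument()
  clock <- step_clock()
  s1 <- complete_session(answer_all(start_session(instr, clock = clock),
                                    instr, clock = clock), instr, clock = clock)
  s2 <- complete_session(answer_all(start_session(instr, clock = clock),
                                    instr, c("no", "no", "no"), clock = clock),
                         instr, clock = clock)
  s3 <- discard_session(start_session(instr, clock = clock))
  expect_identical(s3$status, "discarded")
  expect_error(discard_session(s1), class = "adaptest_session_state")

  path <- withr::local_tempfile(fileext = ".csv")
  n <- export_table(list(s1, s2, s3), instr, path)
  expect_identical(n, 2L)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), 2L)
  expect_identical(names(df), c("session_id", "respondent_id", "visit_code",
                                "start", "duration_s", "q1", "q2", "q3",
                                "score"))
  expect_identical(df$q1, c(1L, 0L))

  # zero completed sessions -> header-only file
  n0 <- export_table(list(s3), instr, path)
  expect_identical(n0, 0L)
  expect_identical(nrow(utils::read.csv(path)), 0L)
})

test_that("item columns follow item numbers regardless of insertion order", {
  cat1 <- scoring_category("c1", list(response_option("no", "No"),
                                      response_option("yes", "Yes")))
  # declared out of order: numbers 1, 0
  instr <- instrument(list(instrument_item("later", 1L, "B?", "c1"),
                           instrument_item("first", 0L, "A?", "c1")),
                      list(cat1))
  clock <- step_clock()
  s <- start_session(instr, clock = clock)
  s <- record_response(s, instr, "first", "yes", clock = clock)
  s <- record_response(s, instr, "later", "no", clock = clock)
  s <- complete_session(s, instr, clock = clock)
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(list(s), instr, path)
  df <- utils::read.csv(path)
  expect_identical(names(df)[6:7], c("first", "later"))
})

test_that("stores persist with backups and recover after corruption", {
  instr <- toy_instrument()
  clock <- step_clock()
  sessions <- list(
    complete_session(answer_all(start_session(instr, respondent_id = "R1",
                                              clock = clock),
                                instr, clock = clock), instr, clock = clock),
    discard_session(start_session(instr, clock = clock)),
    start_session(instr, visit_code = "V9", clock = clock))
  dir <- withr::local_tempdir()
  store <- file.path(dir, "store.json")
  persist_store(sessions, store, clock = clock)
  back <- load_store(store)
  expect_equal(back, sessions, ignore_attr = FALSE)
  expect_identical(back[[2]]$status, "discarded")

  # second persist writes a backup of the first state
  persist_store(back[1], store, clock = clock)
  backups <- Sys.glob(paste0(store, ".bak-*"))
  expect_length(backups, 1L)
  expect_length(load_store(backups[1]), 3L)

  # corrupt store: load fails naming the newest backup
  writeLines("{ truncated", store)
  err <- tryCatch(load_store(store), error = identity)
  expect_s3_class(err, "adaptest_corrupt_store")
  expect_match(conditionMessage(err), basename(backups[1]), fixed = TRUE)
})

test_that("submission is at-least-once: failures stay queued, acks dequeue", {
  instr <- toy_instrument(policies = instrument_policies(
    server_submission_url = "https://collect.example.org/in"))
  clock <- step_clock()
  s <- complete_session(answer_all(start_session(instr, clock = clock), instr,
                                   clock = clock), instr, clock = clock)
  q <- enqueue_submission(submission_queue(), s, instr)
  expect_identical(q$pending, s$session_id)
  # enqueue is idempotent
  expect_identical(enqueue_submission(q, s, instr)$pending, s$session_id)

  failing <- function(url, payload) stop("network down")
  res <- flush_queue(q, list(s), instr, failing, clock = clock)
  expect_identical(res$queue$pending, s$session_id)
  expect_false(res$sessions[[1]]$submitted)
  expect_length(res$queue$attempts[[s$session_id]], 1L)

  succeeding <- function(url, payload) {
    stopifnot(grepl(s$session_id, payload))
    TRUE
  }
  res2 <- flush_queue(res$queue, res$sessions, instr, succeeding, clock = clock)
  expect_length(res2$queue$pending, 0L)
  expect_true(res2$sessions[[1]]$submitted)
  expect_length(res2$queue$attempts[[s$session_id]], 2L)

  # no submission URL -> enqueue is a no-op
  plain <- toy_instrument()
  s2 <- complete_session(answer_all(start_session(plain, clock = clock), plain,
                                    clock = clock), plain, clock = clock)
  expect_length(enqueue_submission(submission_queue(), s2, plain)$pending, 0L)
})

test_that("administration by adapter honors practice items and score display", {
  bank <- toy_bank()
  tbl <- build_lookup_table(toy_instrument(), bank)
  practice <- instrument_item("p1", 0L, "Practice?", "c1")
  shown <- toy_instrument(score_computation(lookup_table_file = "t.tsv"),
                          policies = instrument_policies(show_computed_score = TRUE))
  shown$instructions <- instrument_instructions("Do the practice first.",
                                                list(practice))
  adapter <- scripted_adapter(c("yes", "yes", "no", "no"))
  done <- administer_session(shown, adapter, clock = step_clock(),
                             assets = list(lookup_table = tbl))
  # the practice item consumed the first scripted response; only 3 recorded
  expect_length(done$responses, 3L)
  expect_identical(vapply(done$responses, `[[`, character(1), "response_id"),
                   c("yes", "no", "no"))
  expect_identical(adapter$seen$score, done$score)

  hidden <- shown
  hidden$policies$show_computed_score <- FALSE
  adapter2 <- scripted_adapter(c("yes", "yes", "no", "no"))
  done2 <- administer_session(hidden, adapter2, clock = step_clock(),
                              assets = list(lookup_table = tbl))
  expect_null(adapter2$seen$score)
  expect_identical(done2$score, done$score)
})
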