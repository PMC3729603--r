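#' Configuration for synthetic fixtures
#'
#' Describes the geometry of a synthetic study: `m` items sharing one
#' `K`-response category, a fixed adaptive test length `n`, a simulated
#' cohort of `N` respondents with latent traits drawn from
#' `Normal(theta_mean, theta_sd)`, optional extra locales, and the seed
#' that makes every stochastic output reproducible.  The defaults emulate
#' a short mobility-style instrument: 12 dichotomous items, cohort of 500,
#' standard-normal traits.
#'
#' @param m number of test items (`m >= n >= 1`).
#' @param K responses per item (`K >= 2`; 2 gives a dichotomous no/yes
#'   scale, 5 a graded difficulty scale).
#' @param n adaptive test length.
#' @param N cohort size.
#' @param locales extra locale tags beyond the default text.
#' @param theta_mean,theta_sd latent-trait distribution of the cohort.
#' @param seed integer seed; required, all generators derive their
#'   randomness from it.
#' @return a `fixture_config` object.
#' @export
fixture_config <- function(m = 12L, K = 2L, n = min(m, 12L), N = 500L,
                           locales = character(), theta_mean = 0,
                           theta_sd = 1, seed = 1L) {
  if (m < 1L || n < 1L || n > m) {
    adaptest_error("bad_config",
      sprintf("need m >= n >= 1, got m=%d, n=%d", m, n))
  }
  if (K < 2L) {
    adaptest_error("bad_config", "need at least K=2 responses per item")
  }
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    adaptest_error("bad_config", "an integer seed is required")
  }
  structure(list(m = as.integer(m), K = as.integer(K), n = as.integer(n),
                 N = as.integer(N), locales = locales,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

fixture_item_ids <- function(m) sprintf("i%03d", seq_len(m))

# Default response scales: no/yes for dichotomous items, a graded
# difficulty scale otherwise (extended with numbered middle levels when
# K exceeds the five stock labels).
fixture_response_labels <- function(K) {
  if (K == 2L) return(c("No", "Yes"))
  base <- c("Cannot do", "With much difficulty", "With some difficulty",
            "With a little difficulty", "Without any difficulty")
  if (K <= 5L) return(base[round(seq(1, 5, length.out = K))])
  c(base[1:4], paste("Level", seq_len(K - 5L) + 4L), base[5])
}

#' Generate a synthetic instrument and media manifest
#'
#' Builds a structurally realistic instrument: the requested number of
#' items in order, all sharing one response category, localized
#' descriptions and labels for every requested locale, an instructions
#' block with one unscored practice item, a media key per item, and a
#' manifest resolving each key for a `terminal` platform.  Output is fully
#' deterministic: generating twice with the same configuration yields
#' byte-identical XML.
#'
#' @param config a [fixture_config()].
#' @param policies an [instrument_policies()] to embed.
#' @param computation optional [score_computation()] to embed.
#' @param instructions include the instructions/practice block.
#' @return a list with `instrument` (an [instrument()]) and `manifest`
#'   (a media-manifest data frame).
#' @export
generate_instrument <- function(config, policies = instrument_policies(),
                                computation = NULL, instructions = TRUE) {
  stopifnot(inherits(config, "fixture_config"))
  loc_variant <- function(text) {
    if (length(config$locales) == 0L) return(character())
    stats::setNames(paste0("[", config$locales, "] ", text), config$locales)
  }
  labels <- fixture_response_labels(config$K)
  responses <- lapply(seq_len(config$K), function(k) {
    response_option(sprintf("r%d", k - 1L),
                    localized_text(labels[k], loc_variant(labels[k])))
  })
  category <- scoring_category("main", responses)

  ids <- fixture_item_ids(config$m)
  items <- lapply(seq_len(config$m), function(i) {
    text <- sprintf("Can you perform activity %d?", i)
    instrument_item(
      id = ids[i], number = i - 1L,
      description = localized_text(text, loc_variant(text)),
      scoring_category = "main",
      media = sprintf("clip%03d", i))
  })

  instr_block <- NULL
  if (isTRUE(instructions)) {
    text <- "Watch each animation, then choose the response that fits best."
    practice <- instrument_item(
      id = "practice001", number = 0L,
      description = localized_text("Practice: can you perform this activity?",
                                   loc_variant("Practice: can you perform this activity?")),
      scoring_category = "main", media = "clip-practice")
    instr_block <- instrument_instructions(
      localized_text(text, loc_variant(text)), list(practice))
  }

  instr <- instrument(items = items, categories = list(category),
                      policies = policies, instructions = instr_block,
                      computation = computation)

  keys <- c(vapply(items, `[[`, character(1), "media"),
            if (isTRUE(instructions)) "clip-practice")
  # one default row per key plus one row per extra locale
  locs <- c("*", config$locales)
  manifest <- data.frame(
    key = rep(keys, each = length(locs)),
    platform = "terminal",
    locale = rep(locs, times = length(keys)),
    path = paste0("media/", rep(keys, each = length(locs)), ".",
                  rep(ifelse(locs == "*", "default", locs),
                      times = length(keys)), ".ogv"),
    stringsAsFactors = FALSE)
  list(instrument = instr, manifest = manifest)
}

#' Generate a synthetic item bank
#'
#' Draws discriminations uniformly from \[1, 2\] and, for each item, `K - 1`
#' strictly increasing thresholds spread over \[-2, 2\] -- the parameter
#' ranges typical of a well-calibrated short instrument.  Item ids match
#' [generate_instrument()] so the bank aligns with the fixture instrument.
#' Consumes the global RNG after seeding with `config$seed`.
#'
#' @param config a [fixture_config()].
#' @return a list of [item_parameters()], one per item.
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  ids <- fixture_item_ids(config$m)
  lapply(seq_len(config$m), function(i) {
    a <- stats::runif(1, 1, 2)
    b <- sort(stats::runif(config$K - 1L, -2, 2))
    if (config$K > 2L) {
      # enforce a minimum gap so thresholds are strictly increasing even
      # under unlucky draws
      b <- b + seq(0, 1e-3, length.out = config$K - 1L)
    }
    item_parameters(ids[i], a, b)
  })
}

# Adapter for a simulated respondent with latent trait theta: responses are
# drawn from the item's IRT category probabilities at presentation time, so
# it works for static and adaptive administration alike.
simulated_adapter <- function(theta, bank, respondent_id = NULL,
                              visit_code = NULL) {
  bank_ids <- vapply(bank, `[[`, character(1), "item_id")
  list(
    collect_identifiers = function(policies) {
      list(respondent_id = respondent_id, visit_code = visit_code)
    },
    show_instructions = function(text, practice) invisible(NULL),
    present_item = function(item, category, locale) {
      j <- match(item$id, bank_ids)
      # practice items have no bank entry and are never scored; any legal
      # response will do
      k <- if (is.na(j)) 0L else simulate_response(theta, bank[[j]])
      list(response_id = category$responses[[k + 1L]]$id,
           events = if (!is.null(item$media)) {
             c("media_started", "media_completed")
           } else {
             character()
           })
    },
    show_score = function(score) invisible(NULL)
  )
}

#' Simulate a cohort of respondents through the full engine
#'
#' Draws `N` latent traits from the configured normal distribution, then
#' administers the instrument to each simulated respondent through the
#' session engine (start, per-item response simulated from the item bank,
#' completion and scoring), exactly as a live session would run.  Seeded by
#' `config$seed`, so repeated runs are identical.
#'
#' @param instr the [instrument()] to administer.
#' @param bank list of [item_parameters()] covering the instrument items.
#' @param config a [fixture_config()].
#' @param assets score-computation artifacts (see [complete_session()]).
#' @param clock injectable clock; defaults to a deterministic
#'   [step_clock()] so simulated timestamps are reproducible.
#' @return a list with `sessions` (completed `session_record`s) and
#'   `thetas` (the true latent traits).
#' @export
simulate_cohort <- function(instr, bank, config, assets = list(),
                            clock = step_clock()) {
  stopifnot(inherits(instr, "instrument"), inherits(config, "fixture_config"))
  align_bank(bank, vapply(items_in_order(instr), `[[`, character(1), "id"))
  set.seed(config$seed)
  thetas <- stats::rnorm(config$N, config$theta_mean, config$theta_sd)
  sessions <- vector("list", config$N)
  for (i in seq_len(config$N)) {
    adapter <- simulated_adapter(thetas[i], bank,
                                 respondent_id = sprintf("R%04d", i))
    sessions[[i]] <- administer_session(instr, adapter, clock = clock,
                                        assets = assets,
                                        session_id = sprintf("s%04d", i))
  }
  list(sessions = sessions, thetas = thetas)
}
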