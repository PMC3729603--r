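test_that("a minimal document parses into a fully linked instrument", {
  instr <- parse_instrument(minimal_instrument_xml())
  expect_length(instr$items, 1L)
  expect_null(instr$computation)
  expect_null(instr$instructions)
  expect_identical(instr$items[[1]]$scoring_category, "c1")
  expect_length(validate_instrument(instr), 0L)
})

test_that("structural defects are rejected at parse with the offending id", {
  bad <- sub("<scoringCategory>c1</scoringCategory>",
             "<scoringCategory>X</scoringCategory>",
             minimal_instrument_xml(), fixed = TRUE)
  err <- tryCatch(parse_instrument(bad), error = identity)
  expect_s3_class(err, "adaptest_schema_violation")
  expect_match(conditionMessage(err), "i1")
  expect_match(conditionMessage(err), "DANGLING_CATEGORY_REF")

  two_defaults <- defect_catalogue()$MULTIPLE_DEFAULT_TEXT(minimal_instrument_xml())
  expect_error(parse_instrument(two_defaults),
               class = "adaptest_schema_violation")

  expect_error(parse_instrument("<instrument><items></instrument>"),
               class = "adaptest_xml_malformed")
  expect_error(parse_instrument("<questionnaire/>"),
               class = "adaptest_schema_violation")
})

test_that("each seeded defect maps to exactly its violation code", {
  for (code in names(defect_catalogue())) {
    mutate <- defect_catalogue()[[code]]
    instr <- parse_instrument(mutate(minimal_instrument_xml()), check = FALSE)
    codes <- unique(vapply(validate_instrument(instr), `[[`, character(1),
                           "code"))
    expect_identical(codes, code)
  }
})

test_that("validate() checks programmatically built objects too", {
  cat1 <- scoring_category("c1", list(response_option("no", "No"),
                                      response_option("yes", "Yes")))
  ok <- instrument(list(instrument_item("i1", 0L, "Q?", "c1")), list(cat1))
  expect_length(validate_instrument(ok), 0L)

  gap <- instrument(list(instrument_item("i1", 0L, "Q?", "c1"),
                         instrument_item("i2", 2L, "Q?", "c1")), list(cat1))
  expect_identical(vapply(validate_instrument(gap), `[[`, character(1), "code"),
                   "NONCONTIGUOUS_NUMBERS")

  dup <- instrument(list(instrument_item("i1", 0L, "Q?", "c1"),
                         instrument_item("i1", 1L, "Q?", "c1")), list(cat1))
  expect_identical(vapply(validate_instrument(dup), `[[`, character(1), "code"),
                   "DUPLICATE_ITEM_ID")
})

test_that("serialization round-trips semantically and deterministically", {
  instr <- parse_instrument(minimal_instrument_xml())
  xml <- serialize_instrument(instr)
  expect_identical(parse_instrument(xml), instr)
  expect_identical(serialize_instrument(parse_instrument(xml)), xml)

  # a rich instrument: policies, locales, practice items, scoring function
  cfg <- fixture_config(m = 5, K = 5, N = 1, seed = 3, locales = c("es", "fr"))
  fx <- generate_instrument(cfg,
    policies = instrument_policies(require_respondent_id = TRUE,
                                   show_computed_score = TRUE,
                                   server_submission_url = "https://collect.example.org/mat"),
    computation = score_computation(scoring_expression = "value / 5"))
  xml2 <- serialize_instrument(fx$instrument)
  back <- parse_instrument(xml2)
  expect_identical(back, fx$instrument)
  expect_identical(serialize_instrument(back), xml2)

  # refuses to serialize invalid objects
  cat1 <- scoring_category("c1", list(response_option("no", "No")))
  broken <- instrument(list(instrument_item("i1", 5L, "Q?", "c1")), list(cat1))
  expect_error(serialize_instrument(broken), class = "adaptest_schema_violation")
})

test_that("three locales on one label survive the round trip", {
  label <- localized_text("Walk", c(es = "Caminar", fr = "Marcher",
                                    de = "Gehen"))
  cat1 <- scoring_category("c1", list(response_option("no", "No"),
                                      response_option("yes", label)))
  instr <- instrument(list(instrument_item("i1", 0L, "Q?", "c1")), list(cat1))
  xml <- serialize_instrument(instr)
  expect_identical(length(gregexpr("<label", xml)[[1]]), 4L)  # default + 3
  back <- parse_instrument(xml)
  lab <- back$categories[[1]]$responses[[2]]$label
  expect_identical(resolve_text(lab, "fr"), "Marcher")
  expect_identical(resolve_text(lab, "it"), "Walk")
  expect_identical(back, instr)
})

test_that("serialized documents conform to the shipped schema file", {
  skip_if_not_installed("xml2")
  xsd_path <- system.file("extdata", "instrument.xsd", package = "adaptest")
  if (!nzchar(xsd_path)) {
    xsd_path <- file.path(testthat::test_path(), "..", "..", "inst",
                          "extdata", "instrument.xsd")
  }
  schema <- xml2::read_xml(xsd_path)
  cfg <- fixture_config(m = 4, K = 2, N = 1, seed = 5, locales = "es")
  fx <- generate_instrument(cfg)
  doc <- xml2::read_xml(serialize_instrument(fx$instrument))
  expect_true(xml2::xml_validate(doc, schema))
})

test_that("localization resolves exact, prefix, then default", {
  txt <- localized_text("Walk", c(en = "Walk", es = "Caminar"))
  expect_identical(resolve_text(txt, "es"), "Caminar")
  expect_identical(resolve_text(txt, "fr"), "Walk")
  expect_identical(resolve_text(txt, "en-US"), "Walk")
  expect_identical(resolve_text(localized_text("W", c(`en-GB` = "Whilst")),
                                "en-GB-oxendict"), "Whilst")
  # totality: arbitrary junk tags never fail
  for (tag in c("", "zz", "x-y-z", "en-GB-x-private")) {
    expect_identical(resolve_text(txt, tag), if (tag == "en-GB-x-private") "Walk" else "Walk")
  }
})

test_that("media keys resolve by specificity and fail loudly when absent", {
  manifest <- data.frame(
    key = c("v1", "v1", "v1"),
    platform = c("terminal", "terminal", "*"),
    locale = c("es", "*", "*"),
    path = c("v1-es.ogv", "v1.ogv", "v1-any.ogv"),
    stringsAsFactors = FALSE)
  expect_identical(resolve_media("v1", manifest, "terminal", "es"), "v1-es.ogv")
  expect_identical(resolve_media("v1", manifest, "terminal", "fr"), "v1.ogv")
  expect_identical(resolve_media("v1", manifest, "ipad", "fr"), "v1-any.ogv")
  err <- tryCatch(resolve_media("zz", manifest, "terminal", "es"),
                  error = identity)
  expect_s3_class(err, "adaptest_missing_media")
  expect_match(conditionMessage(err), "zz")

  # manifest round trip through its file format
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_identical(read_media_manifest(path), manifest)
})
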