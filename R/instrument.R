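#' Localized, display-ready text
#'
#' Human-readable text shown to respondents carries one default variant (the
#' text used when the session locale has no better match) plus any number of
#' locale-tagged variants.  In the XML dialect these are repeated elements,
#' where the element without a `lang` attribute is the default; it is an
#' error for more than one element of a group to lack `lang`.
#'
#' @param default text shown when no variant matches the session locale.
#' @param variants named character vector, names are BCP-47 locale tags.
#' @return a `localized_text` object.
#' @export
localized_text <- function(default, variants = character()) {
  stopifnot(is.character(default), length(default) == 1L)
  variants <- as.character(variants) |> stats::setNames(names(variants))
  if (length(variants) > 0L) {
    if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
      adaptest_error("bad_localized_text", "variants must be named by locale tag")
    }
    variants <- variants[order(names(variants))]  # canonical storage order
  }
  structure(list(default = default, variants = variants),
            class = "localized_text")
}

#' Resolve localized text for a session locale
#'
#' Lookup order: exact locale match, then progressively shorter prefixes of
#' the requested tag (`"en-GB"` falls back to `"en"`), then the default
#' variant.  Total: never fails for any locale.
#'
#' @param text a [localized_text()].
#' @param locale BCP-47 locale tag, e.g. `"es"` or `"en-GB"`.
#' @return the resolved character string.
#' @export
resolve_text <- function(text, locale = "") {
  stopifnot(inherits(text, "localized_text"))
  if (is.null(locale) || !nzchar(locale)) return(text$default)
  tag <- locale
  repeat {
    if (tag %in% names(text$variants)) return(unname(text$variants[[tag]]))
    parts <- strsplit(tag, "-", fixed = TRUE)[[1]]
    if (length(parts) <= 1L) break
    tag <- paste(parts[-length(parts)], collapse = "-")
  }
  text$default
}

#' Instrument presentation policies
#'
#' A key-value set of switches controlling how an instrument is
#' administered: whether respondent and visit identifiers are mandatory,
#' whether an item's media must be viewed to completion before a response is
#' accepted, whether media starts automatically (a presentation hint),
#' where completed sessions are submitted, and whether the computed score is
#' shown to the respondent.
#'
#' @param require_respondent_id respondent must supply an id before starting.
#' @param require_visit_code respondent must supply a visit code.
#' @param require_video_viewing item media must complete before responding.
#' @param start_video_automatically hint to the presentation layer.
#' @param server_submission_url absolute URL for automatic submission, or
#'   `NULL` to disable submission.
#' @param show_computed_score whether the respondent sees the final score.
#' @return an `instrument_policies` object.
#' @export
instrument_policies <- function(require_respondent_id = FALSE,
                                require_visit_code = FALSE,
                                require_video_viewing = FALSE,
                                start_video_automatically = FALSE,
                                server_submission_url = NULL,
                                show_computed_score = FALSE) {
  structure(list(
    require_respondent_id = isTRUE(require_respondent_id),
    require_visit_code = isTRUE(require_visit_code),
    require_video_viewing = isTRUE(require_video_viewing),
    start_video_automatically = isTRUE(start_video_automatically),
    server_submission_url = server_submission_url,
    show_computed_score = isTRUE(show_computed_score)
  ), class = "instrument_policies")
}

# XML policy key <-> field name, in canonical serialization order
policy_keys <- c(
  requireRespondentId = "require_respondent_id",
  requireVisitCode = "require_visit_code",
  requireVideoViewing = "require_video_viewing",
  startVideoAutomatically = "start_video_automatically",
  serverSubmissionURL = "server_submission_url",
  showComputedScore = "show_computed_score"
)

#' One legal response within a scoring category
#'
#' @param id response identifier, unique within its category.
#' @param label a [localized_text()] or plain string (promoted to a
#'   default-only localized text).
#' @return a `response_option` object.
#' @export
response_option <- function(id, label) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.character(label)) label <- localized_text(label)
  stopifnot(inherits(label, "localized_text"))
  structure(list(id = id, label = label), class = "response_option")
}

#' A shared category of legal responses
#'
#' Most instruments present the same response scale for many items, so the
#' scale is declared once and referenced by item.  The base numeric value of
#' a response is its 0-based ordinal position in the category's response
#' list; an optional mapping function (see [parse_expression()]) rebases or
#' bins those values.
#'
#' @param id category identifier, unique within the instrument.
#' @param responses list of [response_option()], at least one.
#' @param mapping_function optional expression source text or
#'   `scoring_expression` applied to the base value.
#' @return a `scoring_category` object.
#' @export
scoring_category <- function(id, responses, mapping_function = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.list(responses))
  if (is.character(mapping_function)) {
    mapping_function <- parse_expression(mapping_function)
  }
  structure(list(id = id, responses = responses,
                 mapping_function = mapping_function),
            class = "scoring_category")
}

#' One test (or practice) item
#'
#' @param id arbitrary unique identifier string.
#' @param number 0-based presentation order index.
#' @param description a [localized_text()] or string: the question text.
#' @param scoring_category id of the category holding this item's legal
#'   responses.
#' @param media optional media key.  This is not a filename: the
#'   presentation layer resolves it to a platform- and locale-appropriate
#'   file through a media manifest (see [resolve_media()]).
#' @return an `instrument_item` object.
#' @export
instrument_item <- function(id, number, description, scoring_category,
                            media = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.character(description)) description <- localized_text(description)
  structure(list(id = id, number = as.integer(number),
                 description = description, media = media,
                 scoring_category = scoring_category),
            class = "instrument_item")
}

#' Instructions with optional practice items
#'
#' @param instruction_text a [localized_text()] or string.
#' @param practice_items list of [instrument_item()]; presented before the
#'   test proper, never scored or recorded.
#' @return an `instructions` object.
#' @export
instrument_instructions <- function(instruction_text, practice_items = list()) {
  if (is.character(instruction_text)) {
    instruction_text <- localized_text(instruction_text)
  }
  structure(list(instruction_text = instruction_text,
                 practice_items = practice_items),
            class = "instructions")
}

#' Declared score computation method
#'
#' Exactly one of the three mechanisms is populated: an exhaustive lookup
#' table file mapping every response pattern to a score, a runtime scoring
#' expression over the pattern's summed mapped values, or a pre-computed
#' adaptive-testing tree file.
#'
#' @param lookup_table_file path (relative to the instrument document) of a
#'   two-column lookup table.
#' @param scoring_expression expression source or `scoring_expression`.
#' @param cat_tree_file path of a serialized adaptive-testing tree.
#' @return a `score_computation` object with a `method` field in
#'   `c("lookup_table", "scoring_function", "cat_tree")`.
#' @export
score_computation <- function(lookup_table_file = NULL,
                              scoring_expression = NULL,
                              cat_tree_file = NULL) {
  if (is.character(scoring_expression)) {
    scoring_expression <- parse_expression(scoring_expression)
  }
  populated <- c(lookup_table = !is.null(lookup_table_file),
                 scoring_function = !is.null(scoring_expression),
                 cat_tree = !is.null(cat_tree_file))
  method <- if (sum(populated) == 1L) names(populated)[populated] else NA_character_
  structure(list(method = method,
                 lookup_table_file = lookup_table_file,
                 scoring_expression = scoring_expression,
                 cat_tree_file = cat_tree_file),
            class = "score_computation")
}

#' A complete psychometric instrument
#'
#' The root object: presentation policies, optional instructions with
#' practice items, the ordered test items, the shared response categories,
#' and an optional score computation.  Use [validate_instrument()] to check
#' the structural invariants and [serialize_instrument()] /
#' [parse_instrument()] to move between this object and its XML document.
#'
#' @param items list of [instrument_item()]; required, ordered by `number`.
#' @param categories list of [scoring_category()].
#' @param policies an [instrument_policies()].
#' @param instructions optional [instrument_instructions()].
#' @param computation optional [score_computation()].
#' @return an `instrument` object.
#' @export
instrument <- function(items, categories,
                       policies = instrument_policies(),
                       instructions = NULL, computation = NULL) {
  structure(list(policies = policies, instructions = instructions,
                 items = items, categories = categories,
                 computation = computation),
            class = "instrument")
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %d item(s), %d categor%s, scoring: %s\n",
              length(x$items), length(x$categories),
              if (length(x$categories) == 1L) "y" else "ies",
              if (is.null(x$computation)) "none" else x$computation$method))
  invisible(x)
}

find_category <- function(instr, id) {
  for (cat in instr$categories) if (identical(cat$id, id)) return(cat)
  NULL
}

items_in_order <- function(instr) {
  instr$items[order(vapply(instr$items, `[[`, integer(1), "number"))]
}

# ---------------------------------------------------------------------------
# Validation

#' Validate an instrument against its structural invariants
#'
#' Checks the invariants of the instrument model: at least one item; item
#' ids unique; item numbers a contiguous, duplicate-free 0..k-1 set; every
#' item's category reference resolving; category ids unique; every category
#' non-empty with unique response ids; practice-item ids unique and disjoint
#' from test-item ids; at most one populated score-computation method; a
#' well-formed absolute submission URL when present.  Violations recorded
#' while parsing the document (multiple default localizations, duplicate
#' locale tags, malformed policy values, unknown policy keys) are included.
#'
#' @param instr an `instrument`.
#' @return a list of [violation()] records; empty when the instrument is
#'   valid.  Violations are data, not errors.
#' @export
validate_instrument <- function(instr) {
  stopifnot(inherits(instr, "instrument"))
  v <- attr(instr, "parse_violations") %||% list()

  if (length(instr$items) == 0L) {
    v <- c(v, list(violation("NO_ITEMS", "instrument/items",
                             "an instrument must declare at least one item")))
  }
  ids <- vapply(instr$items, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)])) {
    v <- c(v, list(violation("DUPLICATE_ITEM_ID", paste0("items/item[@id='", dup, "']"),
                             sprintf("item id '%s' used more than once", dup))))
  }
  nums <- vapply(instr$items, `[[`, integer(1), "number")
  for (dup in unique(nums[duplicated(nums)])) {
    v <- c(v, list(violation("DUPLICATE_ITEM_NUMBER", "instrument/items",
                             sprintf("item number %d used more than once", dup))))
  }
  if (length(nums) > 0L && !anyDuplicated(nums) &&
      !identical(sort(nums), seq_along(nums) - 1L)) {
    v <- c(v, list(violation("NONCONTIGUOUS_NUMBERS", "instrument/items",
      sprintf("item numbers (%s) do not form a contiguous 0..%d set",
              paste(sort(nums), collapse = ","), length(nums) - 1L))))
  }

  cat_ids <- vapply(instr$categories, `[[`, character(1), "id")
  for (dup in unique(cat_ids[duplicated(cat_ids)])) {
    v <- c(v, list(violation("DUPLICATE_CATEGORY_ID",
                             paste0("scoring/categories/category[@id='", dup, "']"),
                             sprintf("category id '%s' used more than once", dup))))
  }
  all_items <- c(instr$items,
                 if (!is.null(instr$instructions)) instr$instructions$practice_items)
  for (it in all_items) {
    if (!it$scoring_category %in% cat_ids) {
      v <- c(v, list(violation("DANGLING_CATEGORY_REF",
        paste0("item[@id='", it$id, "']"),
        sprintf("item '%s' references undeclared category '%s'",
                it$id, it$scoring_category))))
    }
  }
  for (cat in instr$categories) {
    path <- paste0("scoring/categories/category[@id='", cat$id, "']")
    if (length(cat$responses) == 0L) {
      v <- c(v, list(violation("EMPTY_RESPONSES", path,
                               "category declares no responses")))
    }
    rids <- vapply(cat$responses, `[[`, character(1), "id")
    for (dup in unique(rids[duplicated(rids)])) {
      v <- c(v, list(violation("DUPLICATE_RESPONSE_ID", path,
        sprintf("response id '%s' duplicated in category '%s'", dup, cat$id))))
    }
  }

  if (!is.null(instr$instructions)) {
    pids <- vapply(instr$instructions$practice_items, `[[`, character(1), "id")
    bad <- unique(c(pids[duplicated(pids)], intersect(pids, ids)))
    for (dup in bad) {
      v <- c(v, list(violation("PRACTICE_ID_OVERLAP",
        paste0("instructions/practiceItems/item[@id='", dup, "']"),
        sprintf("practice item id '%s' is not unique across the instrument", dup))))
    }
  }

  if (!is.null(instr$computation) && is.na(instr$computation$method)) {
    v <- c(v, list(violation("AMBIGUOUS_SCORE_METHOD", "scoring/scoreComputation",
      "exactly one of lookupTable, scoringFunction, catTree must be populated")))
  }

  url <- instr$policies$server_submission_url
  if (!is.null(url) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*://.+", url)) {
    v <- c(v, list(violation("BAD_SUBMISSION_URL",
      "instrumentPolicies/serverSubmissionURL",
      sprintf("'%s' is not an absolute URL", url))))
  }
  v
}

# ---------------------------------------------------------------------------
# Parsing

#' Parse an instrument XML document
#'
#' Reads a document in the instrument dialect into a fully linked
#' [instrument()] object.  Parsing is strict about structure (well-formed
#' XML, required attributes, recognized elements) but lenient about element
#' order within a parent; [serialize_instrument()] always emits the
#' canonical order, so documents diff cleanly under version control.
#'
#' @param x a file path, or a character string of XML text.
#' @param check when `TRUE` (default), violations of the instrument
#'   invariants raise a `schema_violation` error listing every violation
#'   code and path; with `check = FALSE` the (possibly invalid) object is
#'   returned for inspection with [validate_instrument()].
#' @param strict when `TRUE` (default), unknown policy keys are a
#'   violation; otherwise they produce a warning and are ignored.
#' @return an [instrument()].
#' @export
parse_instrument <- function(x, check = TRUE, strict = TRUE) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) {
                    adaptest_error("xml_malformed",
                      sprintf("not well-formed XML: %s", conditionMessage(e)))
                  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "instrument") {
    adaptest_error("schema_violation",
      sprintf("root element is <%s>, expected <instrument>",
              xml2::xml_name(root)))
  }
  viol <- new.env(parent = emptyenv())
  viol$list <- list()
  note <- function(code, path, message) {
    viol$list <- c(viol$list, list(violation(code, path, message)))
  }

  policies <- instrument_policies()
  instructions <- NULL
  items <- list()
  categories <- list()
  computation <- NULL

  for (child in as.list(xml2::xml_children(root))) {
    name <- xml2::xml_name(child)
    if (name == "instrumentPolicies") {
      policies <- parse_policies(child, note, strict)
    } else if (name == "instructions") {
      instructions <- parse_instructions(child, note)
    } else if (name == "items") {
      items <- parse_item_list(child, "instrument/items", note)
    } else if (name == "scoring") {
      sc <- parse_scoring(child, note)
      categories <- sc$categories
      computation <- sc$computation
    } else {
      adaptest_error("schema_violation",
        sprintf("unexpected element <%s> under <instrument>", name))
    }
  }

  instr <- instrument(items = items, categories = categories,
                      policies = policies, instructions = instructions,
                      computation = computation)
  if (length(viol$list) > 0L) {
    attr(instr, "parse_violations") <- viol$list
  }
  if (check) {
    v <- validate_instrument(instr)
    if (length(v) > 0L) {
      adaptest_error("schema_violation",
        paste0("instrument document violates its schema:\n",
               paste(sprintf("  [%s] %s: %s",
                             violation_codes(v),
                             vapply(v, `[[`, character(1), "path"),
                             vapply(v, `[[`, character(1), "message")),
                     collapse = "\n")),
        violations = v)
    }
  }
  instr
}

parse_policies <- function(node, note, strict) {
  args <- list()
  for (child in as.list(xml2::xml_children(node))) {
    key <- xml2::xml_name(child)
    value <- xml2::xml_text(child)
    path <- paste0("instrumentPolicies/", key)
    if (!key %in% names(policy_keys)) {
      if (strict) {
        note("UNKNOWN_POLICY", path, sprintf("unknown policy key '%s'", key))
      } else {
        warning(sprintf("ignoring unknown policy key '%s'", key), call. = FALSE)
      }
      next
    }
    field <- policy_keys[[key]]
    if (field == "server_submission_url") {
      args[[field]] <- value
    } else {
      lowered <- tolower(trimws(value))
      if (!lowered %in% c("true", "false")) {
        note("BAD_POLICY_VALUE", path,
             sprintf("policy '%s' must be 'true' or 'false', got '%s'", key, value))
        next
      }
      args[[field]] <- identical(lowered, "true")
    }
  }
  do.call(instrument_policies, args)
}

# Collect a group of repeated localized elements into a localized_text.
# The element without a lang attribute is the default; more than one
# default, or a repeated locale tag, is recorded as a violation.
parse_localized <- function(nodes, path, note) {
  default <- NULL
  n_default <- 0L
  variants <- character()
  for (nd in nodes) {
    lang <- xml2::xml_attr(nd, "lang")
    txt <- xml2::xml_text(nd)
    if (is.na(lang)) {
      n_default <- n_default + 1L
      if (is.null(default)) default <- txt
    } else {
      if (lang %in% names(variants)) {
        note("DUPLICATE_LOCALE", path,
             sprintf("locale '%s' appears more than once", lang))
      } else {
        variants[[lang]] <- txt
      }
    }
  }
  if (n_default > 1L) {
    note("MULTIPLE_DEFAULT_TEXT", path,
         sprintf("%d elements lack a lang attribute; only one default is allowed",
                 n_default))
  }
  if (is.null(default)) {
    if (length(variants) == 0L) {
      note("MISSING_TEXT", path, "no text content")
      default <- ""
    } else {
      # no explicit default: first variant doubles as the fallback
      note("MISSING_DEFAULT_TEXT", path,
           "no element without a lang attribute; using the first variant")
      default <- unname(variants[[1]])
    }
  }
  localized_text(default, variants)
}

parse_item_list <- function(node, path, note) {
  items <- list()
  for (child in as.list(xml2::xml_children(node))) {
    if (xml2::xml_name(child) != "item") {
      adaptest_error("schema_violation",
        sprintf("%s: unexpected element <%s>", path, xml2::xml_name(child)))
    }
    items <- c(items, list(parse_item(child, path, note)))
  }
  items
}

parse_item <- function(node, parent_path, note) {
  id <- xml2::xml_attr(node, "id")
  number <- xml2::xml_attr(node, "number")
  if (is.na(id) || is.na(number)) {
    adaptest_error("schema_violation",
      sprintf("%s/item: required attributes id and number", parent_path))
  }
  path <- paste0(parent_path, "/item[@id='", id, "']")
  num <- suppressWarnings(as.integer(number))
  if (is.na(num) || num < 0L) {
    adaptest_error("schema_violation",
      sprintf("%s: number must be a nonnegative integer, got '%s'", path, number))
  }
  desc_nodes <- as.list(xml2::xml_find_all(node, "./description"))
  if (length(desc_nodes) == 0L) {
    adaptest_error("schema_violation", sprintf("%s: missing <description>", path))
  }
  description <- parse_localized(desc_nodes, paste0(path, "/description"), note)
  media_node <- xml2::xml_find_first(node, "./media")
  media <- if (inherits(media_node, "xml_missing")) NULL else xml2::xml_text(media_node)
  cat_node <- xml2::xml_find_first(node, "./scoringCategory")
  if (inherits(cat_node, "xml_missing")) {
    adaptest_error("schema_violation",
      sprintf("%s: missing <scoringCategory>", path))
  }
  instrument_item(id = id, number = num, description = description,
                  scoring_category = xml2::xml_text(cat_node), media = media)
}

parse_instructions <- function(node, note) {
  text_nodes <- as.list(xml2::xml_find_all(node, "./instructionText"))
  if (length(text_nodes) == 0L) {
    adaptest_error("schema_violation",
      "instructions: missing <instructionText>")
  }
  text <- parse_localized(text_nodes, "instructions/instructionText", note)
  practice_node <- xml2::xml_find_first(node, "./practiceItems")
  practice <- if (inherits(practice_node, "xml_missing")) list() else {
    parse_item_list(practice_node, "instructions/practiceItems", note)
  }
  instrument_instructions(text, practice)
}

parse_scoring <- function(node, note) {
  cats_node <- xml2::xml_find_first(node, "./categories")
  if (inherits(cats_node, "xml_missing")) {
    adaptest_error("schema_violation", "scoring: missing <categories>")
  }
  categories <- lapply(as.list(xml2::xml_children(cats_node)), function(cnode) {
    if (xml2::xml_name(cnode) != "category") {
      adaptest_error("schema_violation",
        sprintf("scoring/categories: unexpected element <%s>",
                xml2::xml_name(cnode)))
    }
    parse_category(cnode, note)
  })
  comp_node <- xml2::xml_find_first(node, "./scoreComputation")
  computation <- if (inherits(comp_node, "xml_missing")) NULL else {
    parse_score_computation(comp_node, note)
  }
  list(categories = categories, computation = computation)
}

parse_category <- function(node, note) {
  id <- xml2::xml_attr(node, "id")
  if (is.na(id)) {
    adaptest_error("schema_violation",
      "scoring/categories/category: required attribute id")
  }
  path <- paste0("scoring/categories/category[@id='", id, "']")
  resp_node <- xml2::xml_find_first(node, "./responses")
  responses <- if (inherits(resp_node, "xml_missing")) list() else {
    lapply(as.list(xml2::xml_children(resp_node)), function(rnode) {
      parse_response(rnode, path, note)
    })
  }
  map_node <- xml2::xml_find_first(node, "./mappingFunction")
  mapping <- NULL
  if (!inherits(map_node, "xml_missing")) {
    mapping <- tryCatch(parse_expression(xml2::xml_text(map_node)),
      adaptest_error = function(e) {
        note("BAD_EXPRESSION", paste0(path, "/mappingFunction"),
             conditionMessage(e))
        NULL
      })
  }
  structure(list(id = id, responses = responses, mapping_function = mapping),
            class = "scoring_category")
}

parse_response <- function(node, cat_path, note) {
  id <- xml2::xml_attr(node, "id")
  if (is.na(id)) {
    adaptest_error("schema_violation",
      sprintf("%s/responses/response: required attribute id", cat_path))
  }
  path <- paste0(cat_path, "/responses/response[@id='", id, "']")
  label_attr <- xml2::xml_attr(node, "label")
  label_nodes <- as.list(xml2::xml_find_all(node, "./label"))
  label <- if (length(label_nodes) > 0L) {
    lt <- parse_localized(label_nodes, paste0(path, "/label"), note)
    # an attribute label alongside children supplies the default
    if (!is.na(label_attr)) lt$default <- label_attr
    lt
  } else if (!is.na(label_attr)) {
    localized_text(label_attr)
  } else {
    note("MISSING_TEXT", paste0(path, "/label"), "response has no label")
    localized_text(id)
  }
  response_option(id, label)
}

parse_score_computation <- function(node, note) {
  lookup <- xml2::xml_find_first(node, "./lookupTable")
  fn <- xml2::xml_find_first(node, "./scoringFunction")
  tree <- xml2::xml_find_first(node, "./catTree")
  expr <- NULL
  if (!inherits(fn, "xml_missing")) {
    expr <- tryCatch(parse_expression(xml2::xml_text(fn)),
      adaptest_error = function(e) {
        note("BAD_EXPRESSION", "scoring/scoreComputation/scoringFunction",
             conditionMessage(e))
        NULL
      })
  }
  comp <- score_computation(
    lookup_table_file = if (inherits(lookup, "xml_missing")) NULL else xml2::xml_text(lookup),
    scoring_expression = expr,
    cat_tree_file = if (inherits(tree, "xml_missing")) NULL else xml2::xml_text(tree)
  )
  comp
}

# ---------------------------------------------------------------------------
# Serialization

#' Serialize an instrument to canonical XML
#'
#' Emits the instrument document in a fixed canonical element order
#' (policies, instructions, items by number, scoring), with localized
#' variants sorted by locale tag, so that serializing the same object twice
#' yields byte-identical output and instrument variations diff minimally
#' under version control.  Round trip:
#' `parse_instrument(serialize_instrument(x))` is semantically equal to `x`.
#'
#' @param instr a valid [instrument()]; serialization refuses instruments
#'   with violations.
#' @param path optional file path; when `NULL` the XML text is returned.
#' @return the XML text (invisibly, when `path` is given).
#' @export
serialize_instrument <- function(instr, path = NULL) {
  v <- validate_instrument(instr)
  if (length(v) > 0L) {
    adaptest_error("schema_violation",
      paste0("refusing to serialize an invalid instrument: ",
             paste(unique(violation_codes(v)), collapse = ", ")),
      violations = v)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<instrument>")
  lines <- c(lines, serialize_policies(instr$policies))
  if (!is.null(instr$instructions)) {
    lines <- c(lines, serialize_instructions(instr$instructions))
  }
  lines <- c(lines, "  <items>",
             unlist(lapply(items_in_order(instr), serialize_item, indent = 4L)),
             "  </items>")
  lines <- c(lines, serialize_scoring(instr))
  lines <- c(lines, "</instrument>")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

serialize_policies <- function(p) {
  lines <- "  <instrumentPolicies>"
  for (key in names(policy_keys)) {
    field <- policy_keys[[key]]
    val <- p[[field]]
    if (field == "server_submission_url") {
      if (!is.null(val)) {
        lines <- c(lines, sprintf("    <%s>%s</%s>", key, xml_escape(val), key))
      }
    } else {
      lines <- c(lines, sprintf("    <%s>%s</%s>", key,
                                if (val) "true" else "false", key))
    }
  }
  c(lines, "  </instrumentPolicies>")
}

serialize_localized <- function(text, element, indent) {
  pad <- strrep(" ", indent)
  lines <- sprintf("%s<%s>%s</%s>", pad, element, xml_escape(text$default), element)
  for (tag in sort(names(text$variants))) {
    lines <- c(lines, sprintf('%s<%s lang="%s">%s</%s>', pad, element,
                              xml_escape(tag), xml_escape(text$variants[[tag]]),
                              element))
  }
  lines
}

serialize_item <- function(item, indent) {
  pad <- strrep(" ", indent)
  lines <- sprintf('%s<item id="%s" number="%d">', pad, xml_escape(item$id),
                   item$number)
  lines <- c(lines, serialize_localized(item$description, "description",
                                        indent + 2L))
  if (!is.null(item$media)) {
    lines <- c(lines, sprintf("%s  <media>%s</media>", pad,
                              xml_escape(item$media)))
  }
  lines <- c(lines,
             sprintf("%s  <scoringCategory>%s</scoringCategory>", pad,
                     xml_escape(item$scoring_category)),
             sprintf("%s</item>", pad))
  lines
}

serialize_instructions <- function(instructions) {
  lines <- c("  <instructions>",
             serialize_localized(instructions$instruction_text,
                                 "instructionText", 4L))
  if (length(instructions$practice_items) > 0L) {
    ord <- order(vapply(instructions$practice_items, `[[`, integer(1), "number"))
    lines <- c(lines, "    <practiceItems>",
               unlist(lapply(instructions$practice_items[ord], serialize_item,
                             indent = 6L)),
               "    </practiceItems>")
  }
  c(lines, "  </instructions>")
}

serialize_scoring <- function(instr) {
  lines <- c("  <scoring>", "    <categories>")
  for (cat in instr$categories) {
    lines <- c(lines, sprintf('      <category id="%s">', xml_escape(cat$id)),
               "        <responses>")
    for (resp in cat$responses) {
      if (length(resp$label$variants) == 0L) {
        lines <- c(lines, sprintf('          <response id="%s" label="%s"/>',
                                  xml_escape(resp$id),
                                  xml_escape(resp$label$default)))
      } else {
        lines <- c(lines, sprintf('          <response id="%s">',
                                  xml_escape(resp$id)),
                   serialize_localized(resp$label, "label", 12L),
                   "          </response>")
      }
    }
    lines <- c(lines, "        </responses>")
    if (!is.null(cat$mapping_function)) {
      lines <- c(lines, sprintf("        <mappingFunction>%s</mappingFunction>",
                                xml_escape(cat$mapping_function$source)))
    }
    lines <- c(lines, "      </category>")
  }
  lines <- c(lines, "    </categories>")
  comp <- instr$computation
  if (!is.null(comp)) {
    inner <- switch(comp$method,
      lookup_table = sprintf("      <lookupTable>%s</lookupTable>",
                             xml_escape(comp$lookup_table_file)),
      scoring_function = sprintf("      <scoringFunction>%s</scoringFunction>",
                                 xml_escape(comp$scoring_expression$source)),
      cat_tree = sprintf("      <catTree>%s</catTree>",
                         xml_escape(comp$cat_tree_file)))
    lines <- c(lines, "    <scoreComputation>", inner, "    </scoreComputation>")
  }
  c(lines, "  </scoring>")
}

# ---------------------------------------------------------------------------
# Media manifests

#' Read a media manifest
#'
#' An item's `media` field is an identifying key, not a filename; the
#' manifest maps (key, platform, locale) triples to actual media paths,
#' with `"*"` as the wildcard for "any platform" / "any locale".
#' Tab-separated with a `key  platform  locale  path` header.
#'
#' @param path manifest file path.
#' @return a data frame with columns `key`, `platform`, `locale`, `path`.
#' @export
read_media_manifest <- function(path) {
  if (!file.exists(path)) {
    adaptest_error("missing_file", sprintf("media manifest not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  needed <- c("key", "platform", "locale", "path")
  if (!all(needed %in% names(df))) {
    adaptest_error("bad_manifest",
      sprintf("%s: expected columns %s", path, paste(needed, collapse = ", ")))
  }
  df[needed]
}

#' Resolve a media key to a file path
#'
#' The most specific manifest entry wins:
#' (key, platform, locale), then (key, platform, `*`), then (key, `*`, `*`).
#'
#' @param key media key from an item.
#' @param manifest data frame from [read_media_manifest()] (or built in
#'   code with the same columns).
#' @param platform platform identifier, e.g. `"terminal"`.
#' @param locale session locale tag.
#' @return the resolved media path.
#' @export
resolve_media <- function(key, manifest, platform, locale = "") {
  rows <- manifest[manifest$key == key, , drop = FALSE]
  if (nrow(rows) == 0L) {
    adaptest_error("missing_media", sprintf("no media entry for key '%s'", key))
  }
  for (probe in list(c(platform, locale), c(platform, "*"), c("*", "*"))) {
    hit <- rows[rows$platform == probe[1] & rows$locale == probe[2], , drop = FALSE]
    if (nrow(hit) > 0L) return(hit$path[[1]])
  }
  adaptest_error("missing_media",
    sprintf("no media entry for key '%s' on platform '%s' (locale '%s')",
            key, platform, locale))
}
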