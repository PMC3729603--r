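#' Map a response id to its numeric value
#'
#' The base numeric value of a response is its 0-based ordinal position in
#' the category's response list.  When the category declares a mapping
#' function, the base value is passed through it and the result is rounded
#' to the nearest integer (base R [round()]), which is what lets a mapping
#' such as `value / 2` bin a 5-option scale into 3 scored values.  Without
#' a mapping function the ordinal is returned unchanged.
#'
#' @param category a [scoring_category()].
#' @param response_id id of one of the category's responses.
#' @return the mapped numeric value.
#' @export
map_response <- function(category, response_id) {
  stopifnot(inherits(category, "scoring_category"))
  ids <- vapply(category$responses, `[[`, character(1), "id")
  ordinal <- match(response_id, ids)
  if (is.na(ordinal)) {
    adaptest_error("unknown_response",
      sprintf("category '%s' has no response '%s' (legal: %s)",
              category$id, response_id, paste(ids, collapse = ", ")))
  }
  base <- ordinal - 1L
  if (is.null(category$mapping_function)) return(as.numeric(base))
  round(eval_expression(category$mapping_function, base))
}

# number of legal responses for each item, in item-number order
item_response_counts <- function(instr) {
  vapply(items_in_order(instr), function(it) {
    cat <- find_category(instr, it$scoring_category)
    if (is.null(cat)) {
      adaptest_error("schema_violation",
        sprintf("item '%s' references undeclared category '%s'",
                it$id, it$scoring_category))
    }
    length(cat$responses)
  }, integer(1))
}

#' Canonical key for a response pattern
#'
#' Mapped values rendered as their shortest exact decimal form, joined with
#' commas, in item-number order.  This is the first column of a lookup
#' table file.
#'
#' @param values numeric vector of mapped response values.
#' @return a single key string, e.g. `"0,1,1"`.
#' @export
pattern_key <- function(values) {
  paste(vapply(as.numeric(values), as.character, character(1)), collapse = ",")
}

#' Enumerate every possible response pattern of an instrument
#'
#' Produces the exhaustive, lexicographically ordered (item-number-major:
#' the first item's response varies slowest) set of response combinations.
#' The pattern space has `prod(r_i)` rows for items with `r_i` legal
#' responses each; enumeration beyond `cap` rows is refused as intractable,
#' mirroring the exponential-growth limit of exhaustive pre-computation.
#'
#' @param instr a valid [instrument()].
#' @param cap maximum number of patterns (default `2^20`).
#' @return a list with elements `ordinals` (integer matrix, one row per
#'   pattern, 0-based response ordinals), `values` (numeric matrix of
#'   mapped values), and `item_ids`.
#' @export
enumerate_patterns <- function(instr, cap = 2^20) {
  counts <- item_response_counts(instr)
  total <- prod(as.numeric(counts))
  if (total > cap) {
    adaptest_error("intractable",
      sprintf("pattern space has %s combinations, exceeding the cap of %s",
              format(total, big.mark = ","), format(cap, big.mark = ",")))
  }
  items <- items_in_order(instr)
  # expand.grid varies the first factor fastest; reverse so the first item
  # is the most significant position
  grid <- expand.grid(rev(lapply(counts, function(r) seq_len(r) - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  ordinals <- as.matrix(grid[, rev(seq_along(counts)), drop = FALSE])
  dimnames(ordinals) <- NULL
  storage.mode(ordinals) <- "integer"

  values <- ordinals
  storage.mode(values) <- "double"
  for (j in seq_along(items)) {
    cat <- find_category(instr, items[[j]]$scoring_category)
    ids <- vapply(cat$responses, `[[`, character(1), "id")
    mapped <- vapply(ids, function(id) map_response(cat, id), numeric(1))
    values[, j] <- mapped[ordinals[, j] + 1L]
  }
  list(ordinals = ordinals, values = values,
       item_ids = vapply(items, `[[`, character(1), "id"))
}

#' Exhaustive lookup-table scoring
#'
#' A lookup table maps every possible response pattern (encoded with
#' [pattern_key()]) to a real-valued score.  [build_lookup_table()] fills
#' it by enumerating all patterns and scoring each one with the expected a
#' posteriori trait estimate from the item bank, which is exactly what a
#' proprietary calibration tool would have been queried for pattern by
#' pattern.
#'
#' @param entries named numeric vector: names are pattern keys, values are
#'   scores.
#' @return a `lookup_table` object.
#' @export
lookup_table <- function(entries) {
  stopifnot(is.numeric(entries))
  if (length(entries) > 0L &&
      (is.null(names(entries)) || anyDuplicated(names(entries)))) {
    adaptest_error("duplicate_key", "lookup table keys must be unique")
  }
  structure(list(entries = entries), class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("<lookup_table> %d pattern(s)\n", length(x$entries)))
  invisible(x)
}

#' @rdname lookup_table
#' @param table a `lookup_table`.
#' @param pattern numeric vector of mapped response values, item-number
#'   order (or a ready-made key string).
#' @return `score_lookup()` returns the stored score for the pattern.
#' @export
score_lookup <- function(table, pattern) {
  stopifnot(inherits(table, "lookup_table"))
  key <- if (is.character(pattern)) pattern else pattern_key(pattern)
  if (!key %in% names(table$entries)) {
    adaptest_error("unscorable_pattern",
      sprintf("pattern '%s' has no entry in the lookup table", key))
  }
  unname(table$entries[[key]])
}

#' Score a pattern with a scoring expression
#'
#' The scoring expression is evaluated with `value` bound to the sum of
#' the pattern's mapped values (the conventional raw sum score), so e.g.
#' `"value / 12"` rescales a 12-item dichotomous instrument to \[0, 1\].
#'
#' @param expr a `scoring_expression` or its source text.
#' @param pattern numeric vector of mapped response values.
#' @return the computed score.
#' @export
score_function <- function(expr, pattern) {
  eval_expression(expr, sum(as.numeric(pattern)))
}

#' @rdname lookup_table
#' @param instr a valid [instrument()].
#' @param bank list of [item_parameters()], one per instrument item
#'   (matched by item id).
#' @param grid a [quadrature_grid()].
#' @param cap maximum pattern-space size, as in [enumerate_patterns()].
#' @return `build_lookup_table()` returns a `lookup_table` with one entry
#'   per possible pattern, scored by [eap_estimate()].
#' @export
build_lookup_table <- function(instr, bank, grid = quadrature_grid(),
                               cap = 2^20) {
  pats <- enumerate_patterns(instr, cap = cap)
  bank <- align_bank(bank, pats$item_ids)
  counts <- item_response_counts(instr)
  for (j in seq_along(bank)) {
    if (n_categories(bank[[j]]) != counts[j]) {
      adaptest_error("bank_mismatch",
        sprintf("item '%s' has %d responses but its bank entry has %d categories",
                pats$item_ids[j], counts[j], n_categories(bank[[j]])))
    }
  }
  n <- nrow(pats$ordinals)
  scores <- numeric(n)
  keys <- character(n)
  for (i in seq_len(n)) {
    scores[i] <- eap_estimate(pats$ordinals[i, ], bank, grid)$theta
    keys[i] <- pattern_key(pats$values[i, ])
  }
  if (anyDuplicated(keys)) {
    adaptest_error("duplicate_key",
      paste0("the mapping function collapses distinct response combinations",
             " onto the same pattern key; an exhaustive lookup table needs an",
             " injective mapping per item"))
  }
  lookup_table(stats::setNames(scores, keys))
}

#' Read or write a lookup table file
#'
#' The file is two-column, tab-separated, UTF-8, LF line endings, no
#' header: pattern key, then the score printed with 6 decimal places.
#' Writing the same table twice yields byte-identical files.
#'
#' @param path file path.
#' @return `read_lookup_table()` returns a `lookup_table`;
#'   `write_lookup_table()` returns `path` invisibly.
#' @export
read_lookup_table <- function(path) {
  if (!file.exists(path)) {
    adaptest_error("missing_file", sprintf("lookup table not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  keys <- character(length(lines))
  scores <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      adaptest_error("malformed_row",
        sprintf("%s line %d: expected 2 tab-separated columns, got %d",
                path, i, length(fields)))
    }
    score <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(score)) {
      adaptest_error("malformed_row",
        sprintf("%s line %d: score '%s' is not a number", path, i, fields[2]))
    }
    keys[i] <- fields[1]
    scores[i] <- score
  }
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    adaptest_error("duplicate_key",
      sprintf("%s: pattern key '%s' appears on more than one line", path, dup))
  }
  lookup_table(stats::setNames(scores, keys))
}

#' @rdname read_lookup_table
#' @param table a `lookup_table`.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "lookup_table"))
  lines <- sprintf("%s\t%.6f", names(table$entries), table$entries)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Align a bank (list of item_parameters) to a vector of item ids.
align_bank <- function(bank, item_ids) {
  bank_ids <- vapply(bank, `[[`, character(1), "item_id")
  idx <- match(item_ids, bank_ids)
  if (anyNA(idx)) {
    adaptest_error("bank_mismatch",
      sprintf("item bank is missing parameters for item(s): %s",
              paste(item_ids[is.na(idx)], collapse = ", ")))
  }
  bank[idx]
}
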