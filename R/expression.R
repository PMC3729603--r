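#' The response-mapping expression mini-language
#'
#' Mapping and scoring functions inside an instrument are written in a tiny,
#' deliberately restricted arithmetic language over a single variable named
#' `value`: numeric literals, `value`, the four binary operators `+ - * /`,
#' unary minus, and parentheses.  Nothing else -- no other identifiers, no
#' function calls, no comparisons -- is accepted, so an instrument document
#' can never smuggle executable code into the engine.
#'
#' @param source expression text, e.g. `"(value - 1) / 2"`.
#' @return an object of class `scoring_expression` holding the source text
#'   and its parse tree.
#' @examples
#' e <- parse_expression("(value + 1) / 2")
#' eval_expression(e, 5)  # 3
#' @export
parse_expression <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  tokens <- tokenize_expression(source)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  tree <- parse_additive(state, source)
  tok <- peek_token(state)
  if (!is.null(tok)) {
    adaptest_error("expression_syntax",
      sprintf("unexpected '%s' at position %d in %s",
              tok$text, tok$at, deparse(source)))
  }
  structure(list(source = source, tree = tree), class = "scoring_expression")
}

# Token scanner: numbers (integer or decimal), the identifier `value`,
# operators, parentheses.  Any other identifier is reported as unknown,
# anything else as a syntax error, both with 1-based character positions.
tokenize_expression <- function(source) {
  chars <- strsplit(source, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[ \t\n]$", ch)) {
      i <- i + 1L
      next
    }
    rest <- substr(source, i, n)
    if (grepl("^[0-9]", ch) || (ch == "." && i < n && grepl("^[0-9]$", chars[i + 1L]))) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+", rest))
      tokens[[length(tokens) + 1L]] <-
        list(type = "number", text = m, at = i, value = as.numeric(m))
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      if (!identical(m, "value")) {
        adaptest_error("expression_unknown_identifier",
          sprintf("unknown identifier '%s' at position %d (only 'value' is allowed)",
                  m, i))
      }
      tokens[[length(tokens) + 1L]] <- list(type = "value", text = m, at = i)
      i <- i + nchar(m)
    } else if (ch %in% c("+", "-", "*", "/", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
    } else {
      adaptest_error("expression_syntax",
        sprintf("illegal character '%s' at position %d", ch, i))
    }
  }
  tokens
}

peek_token <- function(state) {
  if (state$pos > length(state$tokens)) NULL else state$tokens[[state$pos]]
}

take_token <- function(state) {
  tok <- peek_token(state)
  state$pos <- state$pos + 1L
  tok
}

parse_additive <- function(state, source) {
  node <- parse_multiplicative(state, source)
  repeat {
    tok <- peek_token(state)
    if (is.null(tok) || !tok$type %in% c("+", "-")) return(node)
    take_token(state)
    rhs <- parse_multiplicative(state, source)
    node <- list(op = tok$type, lhs = node, rhs = rhs)
  }
}

parse_multiplicative <- function(state, source) {
  node <- parse_unary(state, source)
  repeat {
    tok <- peek_token(state)
    if (is.null(tok) || !tok$type %in% c("*", "/")) return(node)
    take_token(state)
    rhs <- parse_unary(state, source)
    node <- list(op = tok$type, lhs = node, rhs = rhs)
  }
}

parse_unary <- function(state, source) {
  tok <- peek_token(state)
  if (is.null(tok)) {
    adaptest_error("expression_syntax",
      sprintf("unexpected end of expression in %s", deparse(source)))
  }
  if (tok$type == "-") {
    take_token(state)
    return(list(op = "neg", arg = parse_unary(state, source)))
  }
  parse_primary(state, source)
}

parse_primary <- function(state, source) {
  tok <- take_token(state)
  if (is.null(tok)) {
    adaptest_error("expression_syntax",
      sprintf("unexpected end of expression in %s", deparse(source)))
  }
  switch(tok$type,
    number = list(op = "const", value = tok$value),
    value = list(op = "value"),
    "(" = {
      node <- parse_additive(state, source)
      closing <- take_token(state)
      if (is.null(closing) || closing$type != ")") {
        adaptest_error("expression_syntax",
          sprintf("missing ')' for '(' at position %d", tok$at))
      }
      node
    },
    adaptest_error("expression_syntax",
      sprintf("unexpected '%s' at position %d", tok$text, tok$at))
  )
}

#' Evaluate a scoring expression
#'
#' Pure arithmetic evaluation with `value` bound to a number.  Division by
#' zero is an evaluation error rather than `Inf`, because a lookup key or a
#' score must always be finite.
#'
#' @param expr a `scoring_expression` from [parse_expression()], or its
#'   source text (parsed on the fly).
#' @param value number bound to the variable `value`.
#' @return a single finite number.
#' @export
eval_expression <- function(expr, value) {
  if (is.character(expr)) expr <- parse_expression(expr)
  stopifnot(inherits(expr, "scoring_expression"), is.numeric(value),
            length(value) == 1L)
  eval_node(expr$tree, value, expr$source)
}

eval_node <- function(node, value, source) {
  switch(node$op,
    const = node$value,
    value = as.numeric(value),
    neg = -eval_node(node$arg, value, source),
    "+" = eval_node(node$lhs, value, source) + eval_node(node$rhs, value, source),
    "-" = eval_node(node$lhs, value, source) - eval_node(node$rhs, value, source),
    "*" = eval_node(node$lhs, value, source) * eval_node(node$rhs, value, source),
    "/" = {
      den <- eval_node(node$rhs, value, source)
      if (den == 0) {
        adaptest_error("expression_evaluation",
          sprintf("division by zero while evaluating %s at value=%s",
                  deparse(source), format(value)))
      }
      eval_node(node$lhs, value, source) / den
    }
  )
}

#' @export
print.scoring_expression <- function(x, ...) {
  cat("<scoring_expression>", x$source, "\n")
  invisible(x)
}
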