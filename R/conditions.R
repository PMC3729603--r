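# Classed conditions shared across the package.  Every user-facing error
# carries a machine-readable class "adaptest_<code>" plus "adaptest_error",
# so callers (and tests) can dispatch on the code rather than the message.

adaptest_error <- function(code, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("adaptest_", code), "adaptest_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' Construct a validation violation record
#'
#' Violations are data, not conditions: validators return a list of these.
#'
#' @param code machine-readable violation code (upper snake case).
#' @param path element path or object id the violation refers to.
#' @param message human-readable description.
#' @return a `violation` object (a named list).
#' @keywords internal
violation <- function(code, path, message) {
  structure(list(code = code, path = path, message = message),
            class = "violation")
}

#' @export
print.violation <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$code, x$path, x$message))
  invisible(x)
}

violation_codes <- function(violations) {
  vapply(violations, `[[`, character(1), "code")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
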