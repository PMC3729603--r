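#' Item parameters for a logistic IRT model
#'
#' One row of an item bank.  Dichotomous items follow the two-parameter
#' logistic (2PL) model with discrimination `a` and difficulty `b`; items
#' with K ordered response categories follow Samejima's graded response
#' model (GRM) with K-1 strictly increasing thresholds.  A dichotomous item
#' is simply the K = 2 case, so `thresholds` of length 1 means 2PL.
#'
#' @param item_id item identifier string.
#' @param a discrimination, strictly positive.
#' @param thresholds numeric vector of difficulty thresholds, strictly
#'   increasing; length K-1 for a K-category item.
#' @return an `item_parameters` object.
#' @export
item_parameters <- function(item_id, a, thresholds) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    adaptest_error("bad_item_parameters",
      sprintf("item '%s': discrimination must be a positive number", item_id))
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds) ||
      any(!is.finite(thresholds)) ||
      (length(thresholds) > 1L && any(diff(thresholds) <= 0))) {
    adaptest_error("bad_item_parameters",
      sprintf("item '%s': thresholds must be finite and strictly increasing",
              item_id))
  }
  structure(list(item_id = item_id, a = a, thresholds = thresholds),
            class = "item_parameters")
}

n_categories <- function(params) length(params$thresholds) + 1L

is_dichotomous <- function(params) length(params$thresholds) == 1L

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item_parameters> %s  a=%.3f  b=(%s)\n", x$item_id, x$a,
              paste(format(x$thresholds, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Read or write an item bank
#'
#' Item banks are tab-separated text with columns `item_id`, `a`, and one or
#' more threshold columns `b1, b2, ...` (a single `b1` for 2PL items; items
#' with fewer categories than the widest item leave trailing cells empty).
#' The reader validates positivity of `a` and monotone thresholds.
#'
#' @param path file path.
#' @return `read_item_bank()` returns a list of [item_parameters()];
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) {
    adaptest_error("missing_file", sprintf("item bank file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("item_id", "a") %in% names(df))) {
    adaptest_error("bad_item_bank",
      sprintf("%s: expected columns item_id, a, b1[, b2, ...]", path))
  }
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  if (length(bcols) == 0L) {
    adaptest_error("bad_item_bank", sprintf("%s: no threshold columns", path))
  }
  if (anyDuplicated(df$item_id)) {
    adaptest_error("bad_item_bank",
      sprintf("%s: duplicate item_id '%s'", path,
              df$item_id[duplicated(df$item_id)][1]))
  }
  lapply(seq_len(nrow(df)), function(i) {
    b <- suppressWarnings(as.numeric(df[i, bcols]))
    b <- b[!is.na(b)]
    item_parameters(df$item_id[i], suppressWarnings(as.numeric(df$a[i])), b)
  })
}

#' @rdname read_item_bank
#' @param bank list of [item_parameters()].
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(is.list(bank), length(bank) > 0L)
  kmax <- max(vapply(bank, function(p) length(p$thresholds), integer(1)))
  rows <- vapply(bank, function(p) {
    b <- c(format(p$thresholds, digits = 15, trim = TRUE),
           rep("", kmax - length(p$thresholds)))
    paste(c(p$item_id, format(p$a, digits = 15, trim = TRUE), b),
          collapse = "\t")
  }, character(1))
  header <- paste(c("item_id", "a", paste0("b", seq_len(kmax))), collapse = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Quadrature grid for latent-trait integration
#'
#' The posterior over the latent trait is integrated numerically on a fixed
#' grid of theta points with prior weights.  The default is 61 equally
#' spaced points on \[-4, 4\] with standard-normal prior weights, normalized
#' to sum to one.
#'
#' @param points strictly increasing theta values.
#' @param weights prior weights, one per point; normalized internally.
#' @return a `quadrature_grid` object.
#' @export
quadrature_grid <- function(points = seq(-4, 4, length.out = 61),
                            weights = stats::dnorm(points)) {
  stopifnot(length(points) >= 1L, length(points) == length(weights))
  if (length(points) > 1L && any(diff(points) <= 0)) {
    adaptest_error("bad_grid", "grid points must be strictly increasing")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    adaptest_error("bad_grid", "grid weights must be nonnegative, not all zero")
  }
  structure(list(points = as.numeric(points),
                 weights = as.numeric(weights) / sum(weights)),
            class = "quadrature_grid")
}

#' Response probabilities under the 2PL model
#'
#' P(affirmative) = 1 / (1 + exp(-a (theta - b))).
#'
#' @param theta latent trait value(s).
#' @param params dichotomous [item_parameters()].
#' @return probability of the affirmative (category 1) response, vectorized
#'   over `theta`.
#' @export
prob_2pl <- function(theta, params) {
  stopifnot(inherits(params, "item_parameters"))
  if (!is_dichotomous(params)) {
    adaptest_error("bad_item_parameters",
      sprintf("item '%s' is not dichotomous", params$item_id))
  }
  stats::plogis(params$a * (theta - params$thresholds[1]))
}

#' Category probabilities under the graded response model
#'
#' With cumulative curves P*(j) = logistic(a (theta - b_j)), P*(0) = 1 and
#' P*(K) = 0, category k has probability P(k) = P*(k) - P*(k+1).  For K = 2
#' this reduces exactly to the 2PL model.
#'
#' @param theta latent trait value(s).
#' @param params [item_parameters()].
#' @param k category index, 0-based (0 .. K-1); `NULL` returns the full
#'   matrix of category probabilities (rows = theta, columns = categories).
#' @return probabilities, vectorized over `theta`.
#' @export
prob_grm <- function(theta, params, k = NULL) {
  stopifnot(inherits(params, "item_parameters"))
  K <- n_categories(params)
  cum <- cbind(1, stats::plogis(outer(theta, params$thresholds,
                                      function(t, b) params$a * (t - b))), 0)
  probs <- cum[, seq_len(K), drop = FALSE] - cum[, seq_len(K) + 1L, drop = FALSE]
  if (is.null(k)) {
    colnames(probs) <- as.character(seq_len(K) - 1L)
    return(probs)
  }
  stopifnot(length(k) == 1L, k >= 0, k <= K - 1L)
  probs[, k + 1L]
}

# Likelihood of one response pattern on the grid points.
# responses: 0-based category indices, NA = unanswered (skipped).
pattern_likelihood <- function(responses, bank, points) {
  L <- rep(1, length(points))
  for (i in seq_along(responses)) {
    k <- responses[i]
    if (is.na(k)) next
    L <- L * prob_grm(points, bank[[i]], k)
  }
  L
}

#' Expected a posteriori trait estimate
#'
#' Posterior mean and posterior standard deviation of theta given a
#' response pattern, computed on a quadrature grid with the grid's prior
#' weights.  Deterministic given the grid; well defined for every pattern,
#' including all-extreme ones and the empty pattern (which recovers the
#' prior moments up to grid resolution).
#'
#' @param responses integer vector of 0-based category indices, one per bank
#'   item, in the same order as `bank`; `NA` entries are treated as
#'   unanswered and contribute nothing.
#' @param bank list of [item_parameters()] aligned with `responses`.
#' @param grid a [quadrature_grid()].
#' @return a list with elements `theta` (posterior mean) and `se` (posterior
#'   standard deviation, always positive).
#' @export
eap_estimate <- function(responses, bank, grid = quadrature_grid()) {
  stopifnot(inherits(grid, "quadrature_grid"))
  if (length(responses) != length(bank)) {
    adaptest_error("bad_pattern",
      sprintf("pattern length %d does not match bank size %d",
              length(responses), length(bank)))
  }
  post <- grid$weights * pattern_likelihood(responses, bank, grid$points)
  total <- sum(post)
  if (total <= 0 || !is.finite(total)) {
    adaptest_error("degenerate_posterior",
      "posterior mass is zero on the grid; widen the grid or check parameters")
  }
  post <- post / total
  theta <- sum(post * grid$points)
  var <- sum(post * (grid$points - theta)^2)
  list(theta = theta, se = sqrt(max(var, .Machine$double.eps)))
}

#' Fisher information of an item at a trait value
#'
#' For a 2PL item this is a^2 P (1 - P).  For a graded item it is the
#' standard category-information sum  I(theta) = sum_k (P_k')^2 / P_k,
#' where P_k' is the derivative of the category probability.
#'
#' @inheritParams prob_grm
#' @return nonnegative information, vectorized over `theta`.
#' @export
item_information <- function(theta, params) {
  stopifnot(inherits(params, "item_parameters"))
  a <- params$a
  cum <- stats::plogis(outer(theta, params$thresholds,
                             function(t, b) a * (t - b)))
  # derivative of each cumulative curve: a * P* (1 - P*)
  dcum <- cbind(0, a * cum * (1 - cum), 0)
  cumfull <- cbind(1, cum, 0)
  K <- n_categories(params)
  info <- rep(0, length(theta))
  for (k in seq_len(K)) {
    pk <- cumfull[, k] - cumfull[, k + 1L]
    dk <- dcum[, k] - dcum[, k + 1L]
    ok <- pk > .Machine$double.eps
    info[ok] <- info[ok] + dk[ok]^2 / pk[ok]
  }
  info
}

#' Simulate a response from an item
#'
#' Draws a 0-based category index from the graded-response (or, for
#' dichotomous items, 2PL) category probabilities at `theta`, using R's
#' current random number generator state.  Callers seed explicitly
#' (e.g. `set.seed()`) for reproducibility.
#'
#' @inheritParams prob_grm
#' @param n number of draws.
#' @return integer vector of 0-based category indices.
#' @export
simulate_response <- function(theta, params, n = 1L) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  p <- drop(prob_grm(theta, params))
  sample.int(length(p), size = n, replace = TRUE, prob = p) - 1L
}
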