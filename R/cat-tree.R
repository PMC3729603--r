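#' Pre-computed binary decision tree for fixed-length adaptive testing
#'
#' Adaptive testing normally re-estimates the latent trait after every
#' response and picks the next most informative item, which is costly on
#' low-powered devices.  Because a fixed-length adaptive test over
#' dichotomous items branches only on negative/affirmative answers, the
#' whole decision process can be pre-computed as a complete binary tree of
#' depth `n` with `2^(n+1) - 1` nodes: each internal node names the item to
#' present, the left child is taken on a negative response and the right
#' child on an affirmative one, and every node except the root stores the
#' trait score and standard error implied by the path so far.  Leaves carry
#' the final score.  Administration then costs a constant-time pointer move
#' per response.
#'
#' Construction uses the canonical adaptive rule: the root presents the
#' item with maximum Fisher information at the prior mean; every deeper
#' node presents the maximum-information unused item at the expected a
#' posteriori estimate given the path's responses, ties broken by
#' lexicographically smallest item id.  Pre-computation cost and storage
#' grow as `O(2^n)`, so depth is capped at 20; in practice accuracy gains
#' plateau after 10--12 items, making depth 12 a sensible default.
#'
#' @param bank list of dichotomous [item_parameters()].
#' @param n test length (tree depth), `1 <= n <= min(length(bank), 20)`.
#' @param grid a [quadrature_grid()] used for every trait estimate.
#' @param bank_ref identifier recorded in the tree for provenance checks.
#' @return a `cat_tree` object: level-order arrays `item_id`, `score`,
#'   `se` of length `2^(n+1) - 1` (1-based heap layout: children of node
#'   `i` at `2i` and `2i + 1`), plus `depth`, `bank_ref` and the builder
#'   grid.
#' @export
build_cat_tree <- function(bank, n, grid = quadrature_grid(),
                           bank_ref = "bank") {
  stopifnot(is.list(bank), length(bank) >= 1L)
  if (!all(vapply(bank, is_dichotomous, logical(1)))) {
    adaptest_error("bad_item_parameters",
      "adaptive-tree construction requires dichotomous (2PL) items")
  }
  if (n > 20L) {
    adaptest_error("intractable",
      sprintf("a depth-%d tree has %s nodes; pre-computation beyond depth 20 is intractable",
              n, format(2^(n + 1) - 1, big.mark = ",")))
  }
  if (n < 1L || n > length(bank)) {
    adaptest_error("bad_tree",
      sprintf("test length %d must be between 1 and the bank size (%d)",
              n, length(bank)))
  }
  bank_ids <- vapply(bank, `[[`, character(1), "item_id")
  N <- 2L^(n + 1L) - 1L
  item_id <- rep(NA_character_, N)
  score <- rep(NA_real_, N)
  se <- rep(NA_real_, N)

  prior_mean <- sum(grid$weights * grid$points)

  select_item <- function(theta, used) {
    free <- setdiff(seq_along(bank), used)
    info <- vapply(free, function(j) item_information(theta, bank[[j]]),
                   numeric(1))
    best <- info == max(info)
    cand <- free[best]
    cand[order(bank_ids[cand])][1]
  }

  # Depth-first construction carrying the path likelihood over the grid, so
  # each node's posterior is the parent's likelihood times one Bernoulli term.
  descend <- function(idx, depth, used, lik) {
    if (idx == 1L) {
      theta <- prior_mean
    } else {
      post <- grid$weights * lik
      post <- post / sum(post)
      theta <- sum(post * grid$points)
      score[idx] <<- theta
      se[idx] <<- sqrt(max(sum(post * (grid$points - theta)^2),
                           .Machine$double.eps))
    }
    if (depth == n) return(invisible(NULL))
    j <- select_item(theta, used)
    item_id[idx] <<- bank_ids[j]
    p <- prob_2pl(grid$points, bank[[j]])
    descend(2L * idx, depth + 1L, c(used, j), lik * (1 - p))
    descend(2L * idx + 1L, depth + 1L, c(used, j), lik * p)
  }
  descend(1L, 0L, integer(), rep(1, length(grid$points)))

  structure(list(depth = as.integer(n), bank_ref = bank_ref, grid = grid,
                 item_id = item_id, score = score, se = se),
            class = "cat_tree")
}

#' @export
print.cat_tree <- function(x, ...) {
  cat(sprintf("<cat_tree> depth %d, %d nodes, bank '%s', first item '%s'\n",
              x$depth, length(x$item_id), x$bank_ref, x$item_id[1]))
  invisible(x)
}

#' Traverse a pre-computed adaptive-testing tree
#'
#' `cat_start()` opens a traversal at the root (which presents the first
#' item but carries no score); `cat_next()` advances one step on a
#' negative or affirmative response, exposing the new node's stored score
#' and standard error.  The state stores the tree position, so each step is
#' constant-time -- no re-traversal from the root.
#'
#' @param tree a `cat_tree` from [build_cat_tree()].
#' @return a `cat_state` with fields `node` (heap index), `depth`, `item`
#'   (item to present next, `NA` when finished), `score`, `se`,
#'   `responses`, `items_asked`, and `done`.
#' @export
cat_start <- function(tree) {
  stopifnot(inherits(tree, "cat_tree"))
  structure(list(node = 1L, depth = 0L, item = tree$item_id[1],
                 score = NA_real_, se = NA_real_,
                 responses = integer(), items_asked = character(),
                 done = FALSE),
            class = "cat_state")
}

#' @rdname cat_start
#' @param state the current `cat_state`.
#' @param response `"negative"`/`"affirmative"`, or 0/1, or `FALSE`/`TRUE`.
#' @return the advanced `cat_state`; after the `n`-th response `done` is
#'   `TRUE` and `score`/`se` hold the final estimate from the leaf.
#' @export
cat_next <- function(tree, state, response) {
  stopifnot(inherits(tree, "cat_tree"), inherits(state, "cat_state"))
  if (state$done) {
    adaptest_error("test_complete",
      "the traversal already reached a leaf; no further items to answer")
  }
  bit <- normalize_response_bit(response)
  child <- 2L * state$node + bit
  state$items_asked <- c(state$items_asked, tree$item_id[state$node])
  state$responses <- c(state$responses, bit)
  state$node <- child
  state$depth <- state$depth + 1L
  state$score <- tree$score[child]
  state$se <- tree$se[child]
  state$item <- tree$item_id[child]
  state$done <- is.na(state$item)
  state
}

normalize_response_bit <- function(response) {
  if (is.character(response)) {
    bit <- match(response, c("negative", "affirmative")) - 1L
    if (is.na(bit)) {
      adaptest_error("bad_response",
        sprintf("response must be 'negative' or 'affirmative', got '%s'",
                response))
    }
    return(bit)
  }
  bit <- as.integer(response)
  if (is.na(bit) || !bit %in% c(0L, 1L)) {
    adaptest_error("bad_response", "response must be 0 (negative) or 1 (affirmative)")
  }
  bit
}

#' Run an online (non-pre-computed) adaptive test
#'
#' The step-by-step counterpart of the pre-computed tree: after every
#' response the trait is re-estimated by [eap_estimate()] and the next item
#' is the maximum-information unused item at the fresh estimate, ties
#' broken by lexicographic item id.  Given the same bank, grid and
#' responses this reproduces a [build_cat_tree()] traversal exactly, and is
#' the route a device would take if per-step estimation were affordable.
#'
#' @param bank list of dichotomous [item_parameters()].
#' @param answers either an integer vector of 0/1 responses consumed in
#'   presentation order, or a function `(params, theta_hat)` returning 0
#'   or 1 for the item about to be answered.
#' @param n test length.
#' @param grid a [quadrature_grid()].
#' @return a list with `item_ids`, `responses`, `scores`, `ses` (per step),
#'   and the final `theta` and `se`.
#' @export
run_adaptive_test <- function(bank, answers, n, grid = quadrature_grid()) {
  stopifnot(n >= 1L, n <= length(bank))
  bank_ids <- vapply(bank, `[[`, character(1), "item_id")
  theta <- sum(grid$weights * grid$points)
  used <- integer()
  responses <- rep(NA_integer_, length(bank))
  item_seq <- character(n)
  resp_seq <- integer(n)
  scores <- numeric(n)
  ses <- numeric(n)
  for (step in seq_len(n)) {
    free <- setdiff(seq_along(bank), used)
    info <- vapply(free, function(j) item_information(theta, bank[[j]]),
                   numeric(1))
    cand <- free[info == max(info)]
    j <- cand[order(bank_ids[cand])][1]
    bit <- if (is.function(answers)) {
      normalize_response_bit(answers(bank[[j]], theta))
    } else {
      normalize_response_bit(answers[step])
    }
    used <- c(used, j)
    responses[j] <- bit
    est <- eap_estimate(responses, bank, grid)
    theta <- est$theta
    item_seq[step] <- bank_ids[j]
    resp_seq[step] <- bit
    scores[step] <- est$theta
    ses[step] <- est$se
  }
  list(item_ids = item_seq, responses = resp_seq, scores = scores, ses = ses,
       theta = scores[n], se = ses[n])
}

#' Validate a pre-computed adaptive-testing tree
#'
#' Guards hand-edited or externally produced tree files: checks the
#' complete-tree node count, that the root carries no score or standard
#' error while every other node does, positive finite standard errors,
#' items on every root-to-leaf path distinct, internal nodes carrying items
#' and leaves not, and (when a bank is supplied) that every referenced item
#' exists in the bank.
#'
#' @param tree a `cat_tree`.
#' @param bank optional list of [item_parameters()] to check item ids
#'   against.
#' @return a list of [violation()] records, empty for a healthy tree.
#' @export
validate_cat_tree <- function(tree, bank = NULL) {
  stopifnot(inherits(tree, "cat_tree"))
  v <- list()
  n <- tree$depth
  N <- 2L^(n + 1L) - 1L
  if (length(tree$item_id) != N || length(tree$score) != N ||
      length(tree$se) != N) {
    v <- c(v, list(violation("NODE_COUNT", "tree",
      sprintf("depth %d requires %d nodes, found %d", n, N,
              length(tree$item_id)))))
    return(v)  # indexing below assumes the complete layout
  }
  if (!is.na(tree$score[1]) || !is.na(tree$se[1])) {
    v <- c(v, list(violation("ROOT_HAS_SCORE", "node 1",
      "the root must not carry a score or standard error")))
  }
  internal <- seq_len(2L^n - 1L)
  leaves <- setdiff(seq_len(N), internal)
  for (i in internal) {
    if (is.na(tree$item_id[i])) {
      v <- c(v, list(violation("MISSING_ITEM", sprintf("node %d", i),
        "internal node presents no item")))
    }
  }
  for (i in leaves) {
    if (!is.na(tree$item_id[i])) {
      v <- c(v, list(violation("LEAF_HAS_ITEM", sprintf("node %d", i),
        "leaf nodes terminate the test and present no item")))
    }
  }
  non_root <- setdiff(seq_len(N), 1L)
  bad_se <- non_root[!is.finite(tree$se[non_root]) | tree$se[non_root] <= 0]
  for (i in bad_se) {
    v <- c(v, list(violation("BAD_SE", sprintf("node %d", i),
      "standard error must be positive and finite")))
  }
  bad_score <- non_root[!is.finite(tree$score[non_root])]
  for (i in bad_score) {
    v <- c(v, list(violation("MISSING_SCORE", sprintf("node %d", i),
      "non-root node lacks a finite score")))
  }
  if (!is.null(bank)) {
    bank_ids <- vapply(bank, `[[`, character(1), "item_id")
    unknown <- setdiff(stats::na.omit(tree$item_id), bank_ids)
    for (id in unknown) {
      v <- c(v, list(violation("UNKNOWN_ITEM", sprintf("item '%s'", id),
        "tree references an item absent from the bank")))
    }
  }
  for (leaf in leaves) {
    path_items <- character()
    i <- leaf %/% 2L
    while (i >= 1L) {
      path_items <- c(path_items, tree$item_id[i])
      i <- i %/% 2L
    }
    path_items <- path_items[!is.na(path_items)]
    if (anyDuplicated(path_items)) {
      dup <- path_items[duplicated(path_items)][1]
      v <- c(v, list(violation("DUPLICATE_ITEM_ON_PATH",
        sprintf("leaf %d", leaf),
        sprintf("item '%s' is presented twice on one path", dup))))
    }
  }
  v
}

#' Read or write a serialized adaptive-testing tree
#'
#' Level-order text encoding: a comment header recording the depth, bank
#' reference and quadrature lattice, a column header, then one
#' tab-separated record per node with the 0-based array index (children of
#' index `i` at `2i + 1` and `2i + 2`), the item id (`.` marks a terminal
#' leaf), and the stored score and standard error (`NA` at the root).  The
#' instrument document references this file through its score computation
#' (`catTree` element), keeping the single-file variation workflow intact.
#'
#' @param tree a `cat_tree`.
#' @param path file path.
#' @return `read_cat_tree()` returns the `cat_tree`; `write_cat_tree()`
#'   returns `path` invisibly.
#' @export
write_cat_tree <- function(tree, path) {
  stopifnot(inherits(tree, "cat_tree"))
  g <- tree$grid$points
  header <- sprintf("# cat-tree depth=%d bank_ref=%s grid=%d:%s:%s",
                    tree$depth, tree$bank_ref, length(g),
                    format(min(g), digits = 15), format(max(g), digits = 15))
  ids <- ifelse(is.na(tree$item_id), ".", tree$item_id)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  records <- sprintf("%d\t%s\t%s\t%s", seq_along(ids) - 1L, ids,
                     num(tree$score), num(tree$se))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, "index\titem_id\tscore\tse", records), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cat_tree
#' @export
read_cat_tree <- function(path) {
  if (!file.exists(path)) {
    adaptest_error("missing_file", sprintf("tree file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L || !startsWith(lines[1], "# cat-tree ")) {
    adaptest_error("bad_tree", sprintf("%s: missing cat-tree header", path))
  }
  get_field <- function(name) {
    m <- regmatches(lines[1], regexpr(paste0(name, "=[^ ]+"), lines[1]))
    if (length(m) == 0L) {
      adaptest_error("bad_tree", sprintf("%s: header lacks %s=", path, name))
    }
    sub(paste0(name, "="), "", m)
  }
  depth <- as.integer(get_field("depth"))
  bank_ref <- get_field("bank_ref")
  gspec <- strsplit(get_field("grid"), ":", fixed = TRUE)[[1]]
  grid <- quadrature_grid(seq(as.numeric(gspec[2]), as.numeric(gspec[3]),
                              length.out = as.integer(gspec[1])))
  records <- lines[-(1:2)]
  records <- records[nzchar(records)]
  N <- 2L^(depth + 1L) - 1L
  if (length(records) != N) {
    adaptest_error("bad_tree",
      sprintf("%s: depth %d requires %d records, found %d", path, depth, N,
              length(records)))
  }
  fields <- strsplit(records, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    adaptest_error("bad_tree",
      sprintf("%s: record %d does not have 4 columns", path, bad[1]))
  }
  mat <- do.call(rbind, fields)
  idx <- as.integer(mat[, 1])
  if (!identical(idx, seq_len(N) - 1L)) {
    adaptest_error("bad_tree", sprintf("%s: indices are not 0..%d in order",
                                       path, N - 1L))
  }
  item_id <- ifelse(mat[, 2] == ".", NA_character_, mat[, 2])
  score <- suppressWarnings(as.numeric(mat[, 3]))
  se <- suppressWarnings(as.numeric(mat[, 4]))
  if (any(!is.finite(score[-1])) || any(!is.finite(se[-1]))) {
    adaptest_error("bad_tree",
      sprintf("%s: non-finite score or se fields outside the root", path))
  }
  structure(list(depth = depth, bank_ref = bank_ref, grid = grid,
                 item_id = item_id, score = score, se = se),
            class = "cat_tree")
}
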