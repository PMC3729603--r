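# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written from scratch (plain arithmetic, no calls
# into the package's estimation paths) so they can arbitrate.

# -- minimal legal instrument document: 1 item, 1 category with 2 responses
minimal_instrument_xml <- function() {
'<instrument>
  <items>
    <item id="i1" number="0">
      <description>Can you walk a block?</description>
      <scoringCategory>c1</scoringCategory>
    </item>
  </items>
  <scoring>
    <categories>
      <category id="c1">
        <responses>
          <response id="no" label="No"/>
          <response id="yes" label="Yes"/>
        </responses>
      </category>
    </categories>
  </scoring>
</instrument>'
}

# a small static 3-item instrument with optional scoring attachment
toy_instrument <- function(computation = NULL, policies = instrument_policies()) {
  cat <- scoring_category("c1", list(response_option("no", "No"),
                                     response_option("yes", "Yes")))
  items <- lapply(1:3, function(i) {
    instrument_item(sprintf("q%d", i), i - 1L,
                    sprintf("Task %d?", i), "c1",
                    media = sprintf("clip%d", i))
  })
  instrument(items, list(cat), policies = policies, computation = computation)
}

# printed 3-item toy bank used by the frozen EAP oracle values
toy_bank <- function() {
  list(item_parameters("q1", 1.0, -1),
       item_parameters("q2", 1.5, 0),
       item_parameters("q3", 2.0, 1))
}

# -- independent dense-grid EAP oracle (10,001 points, std-normal prior);
#    own likelihood arithmetic, no package estimation code
oracle_eap <- function(resp, bank, npoints = 10001L) {
  th <- seq(-4, 4, length.out = npoints)
  w <- stats::dnorm(th)
  w <- w / sum(w)
  L <- rep(1, length(th))
  for (i in seq_along(resp)) {
    if (is.na(resp[i])) next
    a <- bank[[i]]$a
    bs <- bank[[i]]$thresholds
    cum <- cbind(1, 1 / (1 + exp(-a * outer(th, bs, `-`))), 0)
    L <- L * (cum[, resp[i] + 1L] - cum[, resp[i] + 2L])
  }
  post <- w * L
  post <- post / sum(post)
  m <- sum(post * th)
  list(theta = m, se = sqrt(sum(post * (th - m)^2)))
}

# -- independent online-CAT oracle: per-step dense EAP + max-information
#    selection with lexicographic tie-break, written without package calls
#    except the shared parameter container
oracle_online_cat <- function(bank, bits, n, npoints = 61L) {
  th <- seq(-4, 4, length.out = npoints)
  w <- stats::dnorm(th)
  w <- w / sum(w)
  ids <- vapply(bank, `[[`, character(1), "item_id")
  info_at <- function(theta, j) {
    a <- bank[[j]]$a
    p <- 1 / (1 + exp(-a * (theta - bank[[j]]$thresholds[1])))
    a^2 * p * (1 - p)
  }
  theta <- sum(w * th)
  used <- integer()
  L <- rep(1, length(th))
  item_seq <- character(n)
  for (step in seq_len(n)) {
    free <- setdiff(seq_along(bank), used)
    info <- vapply(free, function(j) info_at(theta, j), numeric(1))
    cand <- free[info == max(info)]
    j <- cand[order(ids[cand])][1]
    p <- 1 / (1 + exp(-bank[[j]]$a * (th - bank[[j]]$thresholds[1])))
    L <- L * if (bits[step] == 1) p else 1 - p
    post <- w * L
    post <- post / sum(post)
    theta <- sum(post * th)
    used <- c(used, j)
    item_seq[step] <- ids[j]
  }
  post <- w * L
  post <- post / sum(post)
  list(item_ids = item_seq, theta = theta,
       se = sqrt(sum(post * (th - theta)^2)))
}

# seeded defect variants of the fixture instrument: each mutation plants
# exactly one violation and names the code it must produce
defect_catalogue <- function() {
  list(
    DANGLING_CATEGORY_REF = function(x) {
      sub("<scoringCategory>c1</scoringCategory>",
          "<scoringCategory>ghost</scoringCategory>", x, fixed = TRUE)
    },
    DUPLICATE_ITEM_ID = function(x) {
      item <- '<item id="i1" number="1">
      <description>Again?</description>
      <scoringCategory>c1</scoringCategory>
    </item>'
      sub("</item>", paste0("</item>\n    ", item), x, fixed = TRUE)
    },
    NONCONTIGUOUS_NUMBERS = function(x) {
      item <- '<item id="i9" number="2">
      <description>Skipped one</description>
      <scoringCategory>c1</scoringCategory>
    </item>'
      sub("</item>", paste0("</item>\n    ", item), x, fixed = TRUE)
    },
    DUPLICATE_ITEM_NUMBER = function(x) {
      item <- '<item id="i9" number="0">
      <description>Same slot</description>
      <scoringCategory>c1</scoringCategory>
    </item>'
      sub("</item>", paste0("</item>\n    ", item), x, fixed = TRUE)
    },
    DUPLICATE_RESPONSE_ID = function(x) {
      sub('<response id="yes" label="Yes"/>',
          '<response id="yes" label="Yes"/>\n          <response id="yes" label="Si"/>',
          x, fixed = TRUE)
    },
    EMPTY_RESPONSES = function(x) {
      sub('(?s)<responses>.*</responses>', "<responses></responses>", x,
          perl = TRUE)
    },
    DUPLICATE_CATEGORY_ID = function(x) {
      extra <- '<category id="c1">
        <responses>
          <response id="a" label="A"/>
        </responses>
      </category>'
      sub("</category>", paste0("</category>\n      ", extra), x, fixed = TRUE)
    },
    MULTIPLE_DEFAULT_TEXT = function(x) {
      sub("<description>Can you walk a block?</description>",
          "<description>Can you walk a block?</description>\n      <description>Second default</description>",
          x, fixed = TRUE)
    },
    DUPLICATE_LOCALE = function(x) {
      sub("<description>Can you walk a block?</description>",
          paste0("<description>Can you walk a block?</description>\n",
                 '      <description lang="es">Uno</description>\n',
                 '      <description lang="es">Dos</description>'),
          x, fixed = TRUE)
    },
    UNKNOWN_POLICY = function(x) {
      sub("<items>",
          "<instrumentPolicies><allowRetakes>true</allowRetakes></instrumentPolicies>\n  <items>",
          x, fixed = TRUE)
    },
    BAD_POLICY_VALUE = function(x) {
      sub("<items>",
          "<instrumentPolicies><requireVisitCode>maybe</requireVisitCode></instrumentPolicies>\n  <items>",
          x, fixed = TRUE)
    },
    BAD_SUBMISSION_URL = function(x) {
      sub("<items>",
          "<instrumentPolicies><serverSubmissionURL>not a url</serverSubmissionURL></instrumentPolicies>\n  <items>",
          x, fixed = TRUE)
    },
    PRACTICE_ID_OVERLAP = function(x) {
      block <- '<instructions>
    <instructionText>Practice first.</instructionText>
    <practiceItems>
      <item id="i1" number="0">
        <description>Practice</description>
        <scoringCategory>c1</scoringCategory>
      </item>
    </practiceItems>
  </instructions>'
      sub("<items>", paste0(block, "\n  <items>"), x, fixed = TRUE)
    }
  )
}
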