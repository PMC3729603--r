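---
title: "Methods: instrument definition, IRT scoring, and pre-computed adaptive testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrument definition, IRT scoring, and pre-computed adaptive testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptest)
```

## The problem

Patient-reported outcome instruments -- short questionnaires, often with
accompanying video or image media, asking respondents to judge their own
ability to perform everyday tasks -- are usually baked into the software
that administers them. Every variation of the instrument then means
editing forms, processing scripts and database schemas in lockstep, which
is slow and error-prone. `adaptest` takes the opposite stance: the entire
instrument (presentation policies, localized instructions and practice
items, the ordered items, the shared response scales, and the scoring
mechanism) lives in one XML document, and the engine is instrument-agnostic.
Creating a variation means editing one text file that diffs cleanly under
version control; the same document drives any presentation front end
through a pluggable adapter.

This vignette explains the models and design decisions behind each layer:
the document dialect, the response-mapping mini-language, the item-response
theory (IRT) core, the exhaustive lookup table, the pre-computed adaptive
testing tree, the session engine, and the synthetic-data generators used
throughout the test suite.

## The instrument dialect

An `<instrument>` document has four children:

* `<instrumentPolicies>` -- a flat key-value list of presentation switches:
  `requireRespondentId`, `requireVisitCode`, `requireVideoViewing`,
  `startVideoAutomatically`, `serverSubmissionURL`, `showComputedScore`.
  Boolean policies accept only `true`/`false` (case-insensitive); anything
  else is a validation error, so a configuration is always bit-exact.
  `startVideoAutomatically` is surfaced to the presentation adapter as a
  hint only -- it has no engine-side semantics to enforce.
* `<instructions>` -- optional instruction text plus practice items that
  are presented but never scored or recorded.
* `<items>` -- the test items, each with a unique `id`, a 0-based `number`
  giving presentation order, a localized `description`, an optional
  `media` key, and a `scoringCategory` reference.
* `<scoring>` -- the shared response categories and an optional
  `scoreComputation` naming exactly one scoring mechanism.

Every element holding display text (`instructionText`, `description`,
`label`) may repeat with a `lang` attribute per locale; the single element
*without* `lang` is the default shown when the session locale has no
better match, and more than one default is an error. Locale tags are
BCP-47; resolution tries an exact match, then progressively shorter
prefixes (`en-GB` falls back to `en`), then the default. Only the default
fallback is strictly required by the dialect; prefix fallback is a
practical addition so that regional variants do not silently lose their
base-language text. Resolution is total: it never fails, whatever the tag.

The `media` value is deliberately *not* a filename but a key; a separate
manifest maps `(key, platform, locale)` to actual files, most specific
entry first, so one document can drive platforms with different media
formats. Two points of the dialect were genuinely open and are fixed here
as the decision of record (and encoded in the machine-readable schema at
`inst/extdata/instrument.xsd`): the category identifier is an `id`
*attribute*, matching the attribute form used by items and responses, and
`description` is a repeated element rather than a list container. Element
order within a parent is not significant on input, but
`serialize_instrument()` always emits one canonical order with variants
sorted by locale tag -- so serialization is byte-deterministic and version
control diffs stay minimal.

Validation is two-layered: `parse_instrument()` is strict about structure
(well-formed XML, required attributes, recognized elements) and, by
default, raises on any invariant violation listing machine-readable codes
and element paths; `validate_instrument()` exposes the same checks as data
on already-parsed objects, so hand-built or deliberately broken
instruments can be inspected without exception handling.

## The expression mini-language

Mapping and scoring functions are arithmetic over a single variable
`value`: numeric literals, `+ - * /`, unary minus, parentheses, and
nothing else. The parser is a small hand-written recursive-descent
grammar; any other identifier, function call or comparison is rejected
with its character position. The restriction is a safety property: an
instrument document can never inject executable code into the engine.

Two interpretation decisions the dialect leaves open are fixed as follows:

* **Base value of a response.** The numeric value fed into a category's
  `mappingFunction` is the response's 0-based ordinal position within the
  category's response list. This is deterministic and independent of the
  format of response ids.
* **Rounding of mapped values.** The mapping function's purpose is to
  *bin* response scales, but the grammar's rational functions are
  injective almost everywhere, so the result of the mapping expression is
  rounded to the nearest integer (base R `round()`, half-to-even). A
  5-option scale mapped through `value / 2` therefore bins onto the three
  values 0, 1, 2.
* **`scoringFunction` binding.** When a whole pattern is scored by an
  expression, `value` is bound to the sum of the pattern's mapped values --
  the conventional raw sum score -- so `value / 12` rescales a 12-item
  dichotomous instrument to the unit interval.

## The IRT core

Dichotomous items follow the two-parameter logistic model,
$P(X = 1 \mid \theta) = \operatorname{logit}^{-1}\!\big(a(\theta - b)\big)$,
with discrimination $a > 0$ and difficulty $b$. Polytomous items follow
Samejima's graded response model with strictly increasing thresholds
$b_1 < \dots < b_{K-1}$; the dichotomous model is exactly its $K = 2$
case, and the code treats it so. These are the standard model choices for
short health-outcome instruments with ordered response scales. Parameter
*estimation* is out of scope: item banks are inputs, read from a
tab-separated file with validated positivity and monotonicity.

Trait scoring uses the expected a posteriori (EAP) estimate: the posterior
mean of $\theta$ under a standard-normal prior, with the posterior
standard deviation as the standard error. The posterior is integrated on
a fixed quadrature grid, by default 61 equally spaced points on
$[-4, 4]$ with normalized normal weights. EAP was chosen over maximum
likelihood and maximum a posteriori because it is deterministic, needs no
iteration, is well-defined for all-extreme response patterns (where ML
diverges), and is precisely the quantity a pre-computed lookup table or
decision tree wants to cache. The 61-point default trades accuracy for
speed: against a 10,001-point reference integration the estimate agrees to
about $10^{-3}$ on 3-item banks, with worst-case error on the order of
$2\times10^{-3}$ for extreme patterns of longer instruments; consumers
needing more can pass a denser `quadrature_grid()`. Item selection uses
Fisher information, $a^2 P(1-P)$ for the 2PL and the category-information
sum for the graded model.

## Exhaustive lookup tables

When per-device IRT computation is unwanted, the whole scoring function
can be tabulated: `enumerate_patterns()` walks every combination of
response values (item-number-major lexicographic order) and
`build_lookup_table()` stores the EAP estimate for each. The table file
is two tab-separated columns -- the pattern key (mapped values joined by
commas) and the score to six decimals -- and building the same table twice
yields byte-identical files. The pattern space is $\prod_i r_i$, so
enumeration is refused beyond a cap (default $2^{20}$ entries): exhaustive
pre-computation is only sensible for small instruments, and the error is
explicit rather than a silent multi-hour build. A mapping function that
collapses distinct response combinations onto one key would corrupt the
table, so key collisions abort the build.

## The pre-computed adaptive-testing tree

Adaptive testing re-scores after every response and presents the most
informative remaining item, which is expensive on low-powered tablets.
For fixed-length tests over dichotomous items the entire decision process
is pre-computable as a complete binary tree of depth $n$ with
$2^{n+1} - 1$ nodes: internal nodes name the item to present, the left
child is taken on a negative response and the right child on an
affirmative one, and every node except the root stores the EAP score and
standard error implied by the path so far; leaves carry final scores.
Administration is then a constant-time pointer move per response, because
the traversal state stores its tree position.

The construction rule is the canonical maximum-information CAT: the root
presents the item with the greatest Fisher information at the prior mean,
and each deeper node presents the most informative *unused* item at the
EAP estimate given the path, ties broken by lexicographically smallest
item id. The tree description could also be read as enumerating item
*permutations*, but that reading is inconsistent with a single item per
node, so this package pins the max-information semantics -- and the test
suite asserts, exhaustively for $n \le 8$ and on seeded random sequences
at $n = 12$, that tree traversal reproduces an independently coded online
CAT (fresh estimate plus selection at every step) item-for-item and
score-for-score.

Storage grows as $O(2^n)$, so depth is capped at 20. In the simulations
shipped with the package the mean standard error drops steeply over the
first items and flattens after 10--12: with a seeded 20-item bank and 500
simulated respondents, the drop in mean SE from length 12 to 20 is under
a tenth of the drop from length 1 to 12. Depth 12 is therefore the
sensible default fixture length. Trees serialize to a level-order text
file (index $i$'s children at $2i+1$ and $2i+2$, 0-based) referenced from
the instrument's `scoreComputation`, and `validate_cat_tree()` guards
hand-edited files: node count, bare root, positive finite standard
errors, path-distinct items, known item ids.

Along every root-to-leaf path the stored standard error is non-increasing
-- information accumulates -- which the suite checks for every leaf. This
is an empirical property of well-behaved banks ($a \in [1,2]$,
$b \in [-2,2]$) on the default grid rather than a theorem; a pathological
bank could in principle produce a locally widening posterior.

## The session engine

Sessions are explicit records: identifiers, one timestamped response per
item, start/end/duration, score, status (`in_progress`, `completed`,
`discarded`) and submission state. The engine enforces the policies at
their documented points: identifier collection before start, strict item
order, media viewed to completion before responding (when the policy is
set and the item has media), score display gated by `showComputedScore`.
All timestamps come from an injectable clock, so tests assert exact
durations; durations are whole seconds, timestamps ISO 8601 UTC.

Discarded sessions are retained and flagged rather than deleted -- safer,
and equivalent for export, which only ever emits completed sessions (one
CSV row each, item columns in item-number order). The store is a single
JSON document; every rewrite first copies the previous file to a
timestamped backup, and a corrupt store fails to load with a hint naming
the newest backup. Submission is at-least-once through a pluggable
transport: a session leaves the queue only on an acknowledged delivery,
failures stay queued with their attempts logged. The payload -- the
session record as a self-contained JSON document -- is this package's own
design of record, since the transport contract only requires that the
receiving end acknowledge.

Presentation is a four-function adapter contract. The package ships a
terminal adapter for interactive runs, a scripted adapter for
deterministic tests, and a simulated-respondent adapter used by the
cohort generator.

## Synthetic data: what it emulates and what it does not

`generate_instrument()` builds instruments shaped like a real
media-anchored mobility questionnaire: `m` items in order sharing one
`K`-response category, localized text for any requested locales, an
instructions block with an unscored practice item, a media key per item
with a resolvable manifest. The defaults are `m = 12`, `K = 2` --
matching the fixed-length adaptive setting -- and the test suite also
exercises the 81-item, 5-category long-form geometry.
`generate_item_bank()` draws $a \sim U[1, 2]$ and thresholds spread over
$[-2, 2]$, the ranges of a well-calibrated short instrument.
`simulate_cohort()` draws traits from $N(0, 1)$ by default and pushes
each simulated respondent through the *full* session engine rather than
shortcutting to a probability matrix.

Simulation sizes used by the shipped checks: 200 seeded instruments for
the round-trip sweep, cohorts of 500 for score recovery
(correlation between true and estimated traits around 0.87--0.90,
asserted at $\ge 0.85$) and for the plateau measurement, exhaustive
traversal equivalence at depths 4 and 8 plus 100 random depth-12
sequences. Under these conditions the whole suite runs in about a
minute on one CPU.

What passing these tests does *not* show: the generator draws
unidimensional, locally independent responses from the same model family
the scorer assumes, so the recovery results demonstrate correctness of
the machinery, not robustness to model misspecification,
multidimensionality, careless responding, or differential item
functioning in real populations. Item parameters are taken as known;
calibration uncertainty is outside the package's scope.

## Numerical choices and degenerate inputs

* Quadrature: 61 points on $[-4, 4]$, standard-normal weights normalized
  to sum to one; posterior variance floored at machine epsilon so the
  standard error is always positive.
* A response pattern with zero posterior mass on the grid (possible only
  with pathological parameters) raises an explicit error rather than
  returning `NaN`.
* Expression evaluation treats division by zero as an error: scores and
  lookup keys must be finite.
* Tie-breaks in item selection are lexicographic by item id, making tree
  construction and online selection fully deterministic.
* Lookup-table scores are written with six decimals; tree scores with
  full (17 significant digit) precision, since trees are machine-built
  and machine-read.
* Randomness: fixture generators and the cohort simulator are seeded
  through their configuration and use R's global RNG (the R idiom), so
  `set.seed()` composes with them; `simulate_response()` documents that
  callers seed explicitly.

## Known limitations

* Adaptive trees require dichotomous items; graded items are scored by
  lookup table, scoring expression, or direct EAP.
* Fixed-length adaptive testing only: no variable-length stopping rules,
  content balancing, or exposure control.
* The expression language is deliberately tiny; there is no general
  scripting hook.
* No media rendering: resolution stops at returning a file path.
* The submission server side is out of scope; only the client-side queue
  and payload contract are provided.
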