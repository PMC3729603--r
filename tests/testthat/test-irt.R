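test_that("2PL probabilities follow the logistic closed form", {
  p <- item_parameters("x", 1, 0)
  expect_equal(prob_2pl(0, p), 0.5)
  expect_equal(prob_2pl(log(3), p), 0.75)
  expect_equal(prob_2pl(50, p), 1, tolerance = 1e-12)
  steep <- item_parameters("y", 2, 0.5)
  expect_equal(prob_2pl(0.5, steep), 0.5)
  expect_error(prob_2pl(0, item_parameters("z", 1, c(-1, 1))),
               class = "adaptest_bad_item_parameters")
})

test_that("graded-response categories conserve probability and nest the 2PL", {
  grm <- item_parameters("g", 1.3, c(-1, 0, 1.5))
  thetas <- seq(-3, 3, by = 0.5)
  probs <- prob_grm(thetas, grm)
  expect_equal(rowSums(probs), rep(1, length(thetas)))
  expect_true(all(probs >= 0))
  expect_equal(prob_grm(-20, grm, 0), 1, tolerance = 1e-8)

  set.seed(99)
  for (i in 1:100) {
    a <- runif(1, 0.5, 2.5)
    b <- runif(1, -2, 2)
    dich <- item_parameters("d", a, b)
    th <- runif(5, -3, 3)
    expect_equal(prob_grm(th, dich, 1), prob_2pl(th, dich), tolerance = 1e-12)
    expect_equal(prob_grm(th, dich, 0), 1 - prob_2pl(th, dich),
                 tolerance = 1e-12)
  }
})

test_that("item parameters enforce positive discrimination and ordered thresholds", {
  expect_error(item_parameters("x", 0, 0), class = "adaptest_bad_item_parameters")
  expect_error(item_parameters("x", -1, 0), class = "adaptest_bad_item_parameters")
  expect_error(item_parameters("x", 1, c(1, 1)), class = "adaptest_bad_item_parameters")
  expect_error(item_parameters("x", 1, c(1, 0)), class = "adaptest_bad_item_parameters")
})

test_that("EAP matches the independent dense-grid oracle on the toy bank", {
  bank <- toy_bank()
  grid <- quadrature_grid()
  # frozen values from the 10,001-point oracle (helper oracle_eap)
  est <- eap_estimate(c(1, 1, 0), bank, grid)
  expect_equal(est$theta, 0.312238998942, tolerance = 1e-3)
  expect_equal(est$se, 0.674108082810, tolerance = 1e-3)

  # all 8 dichotomous patterns agree with the oracle within 1e-3
  for (p1 in 0:1) for (p2 in 0:1) for (p3 in 0:1) {
    pat <- c(p1, p2, p3)
    est <- eap_estimate(pat, bank, grid)
    orc <- oracle_eap(pat, bank)
    expect_lt(abs(est$theta - orc$theta), 1e-3)
    expect_lt(abs(est$se - orc$se), 1e-3)
  }
})

test_that("EAP recovers the prior for an empty pattern and responds to data", {
  bank <- toy_bank()
  empty <- eap_estimate(rep(NA_integer_, 3), bank)
  expect_equal(empty$theta, 0, tolerance = 1e-6)
  expect_equal(empty$se, 1, tolerance = 0.01)  # N(0,1) prior, grid-truncated

  single <- eap_estimate(c(NA, NA, 1), list(item_parameters("q", 1, 0))[c(1, 1, 1)])
  expect_gt(single$theta, 0)
  neg <- eap_estimate(c(0, 0, 0), bank)
  aff <- eap_estimate(c(1, 1, 1), bank)
  expect_gt(aff$theta, neg$theta)
  expect_error(eap_estimate(c(0, 1), bank), class = "adaptest_bad_pattern")
})

test_that("Fisher information has its closed-form 2PL values and vanishes in the tails", {
  expect_equal(item_information(0.3, item_parameters("x", 1, 0.3)), 0.25)
  expect_equal(item_information(-1, item_parameters("x", 2, -1)), 1.0)
  grm <- item_parameters("g", 1.4, c(-1, 0.5))
  expect_lt(item_information(9, grm), 1e-3)
  expect_lt(item_information(-9, grm), 1e-3)
  expect_true(all(item_information(seq(-4, 4, 0.25), grm) >= 0))
})

test_that("simulated responses are reproducible and match the model frequencies", {
  p <- item_parameters("x", 1, 0)
  set.seed(7)
  draws1 <- simulate_response(0.5, p, n = 1000)
  set.seed(7)
  draws2 <- simulate_response(0.5, p, n = 1000)
  expect_identical(draws1, draws2)

  set.seed(8)
  expect_true(all(simulate_response(10, p, n = 1e4) == 1L))

  # Monte-Carlo frequencies vs closed form within 3 binomial sigmas
  grm <- item_parameters("g", 1.2, c(-0.5, 0.8))
  set.seed(9)
  n <- 1e5
  draws <- simulate_response(0, grm, n = n)
  expected <- drop(prob_grm(0, grm))
  for (k in 0:2) {
    phat <- mean(draws == k)
    sigma <- sqrt(expected[k + 1] * (1 - expected[k + 1]) / n)
    expect_lt(abs(phat - expected[k + 1]), 3 * sigma + 1e-12)
  }
})

test_that("simulated 2PL respondents are recovered by EAP scoring", {
  cfg <- fixture_config(m = 12, K = 2, N = 500, seed = 11)
  bank <- generate_item_bank(cfg)
  set.seed(cfg$seed)
  thetas <- rnorm(cfg$N)
  grid <- quadrature_grid()
  patterns <- t(vapply(thetas, function(th) {
    vapply(bank, function(p) simulate_response(th, p), integer(1))
  }, integer(cfg$m)))
  est <- vapply(seq_len(cfg$N), function(i) {
    eap_estimate(patterns[i, ], bank, grid)$theta
  }, numeric(1))
  expect_gte(cor(thetas, est), 0.85)

  # mean posterior se strictly decreases as the test lengthens 1..12
  mean_se <- vapply(1:12, function(L) {
    mean(vapply(seq_len(cfg$N), function(i) {
      pat <- rep(NA_integer_, cfg$m)
      pat[1:L] <- patterns[i, 1:L]
      eap_estimate(pat, bank, grid)$se
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_se) < 0))
})

test_that("item banks round-trip through their file format with validation", {
  bank <- list(item_parameters("q1", 1.2, -0.5),
               item_parameters("q2", 1.8, c(-1, 0, 1)),
               item_parameters("q3", 1.0, 0.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_item_bank(bank, path)
  expect_equal(read_item_bank(path), bank)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("item_id\ta\tb1\tb2", "q1\t1.0\t1\t0"), bad)
  expect_error(read_item_bank(bad), class = "adaptest_bad_item_parameters")
  writeLines(c("item_id\ta\tb1", "q1\t1.0\t0", "q1\t1.0\t1"), bad)
  expect_error(read_item_bank(bad), class = "adaptest_bad_item_bank")
})
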