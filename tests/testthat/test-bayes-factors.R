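test_that("complexity estimates match symmetry values", {
  pool <- sample_product(uniform_prior(lay4()), 1e5, seed = 41)
  c1 <- estimate_complexity(h_full4(), pool = pool)
  expect_equal(c1$analytic, 1 / 24)
  expect_lt(abs(c1$value - 1 / 24), 3 * c1$std_error)
  c2 <- estimate_complexity(h_avg4(), pool = pool)
  expect_lt(abs(c2$value - 0.5), 3 * c2$std_error)
  # J = 3 full ordering: each of the 3! orderings equally likely -> 1/6
  lay3 <- condition_layout(c("a", "b", "c"), 7)
  h3 <- parse_hypothesis("a > b > c", lay3)
  c3 <- estimate_complexity(h3, n_draws = 1e5, seed = 42)
  expect_lt(abs(c3$value - 1 / 6), 3 * c3$std_error)
  # complement complexity on the same pool is exactly 1 - c
  cc <- estimate_complexity(complement_of(h_full4()), pool = pool)
  expect_equal(cc$value, 1 - c1$value)
})

test_that("two-condition fits agree with the numerical-integration oracle", {
  lay <- lay2()
  h <- parse_hypothesis("c1 > c2", lay)
  for (x in list(c(5, 2), c(7, 0), c(3, 3), c(0, 6))) {
    post <- posterior_update(uniform_prior(lay), x)
    f <- estimate_fit(h, post, n_draws = 1e5, seed = 40 + x[1])
    exact <- p_beta_greater(x[1] + 1, 8 - x[1], x[2] + 1, 8 - x[2])
    se <- max(f$std_error, sqrt(exact * (1 - exact) / f$n_draws))
    expect_lt(abs(f$value - exact), 3 * se + 1e-6)
  }
})

test_that("Bayes factor arithmetic reproduces the worked ratios", {
  expect_equal(as.numeric(bf_vs_unconstrained(.5483, 1 / 24)), 13.16,
               tolerance = 1e-3)
  expect_equal(as.numeric(bf_vs_unconstrained(.25, .25)), 1)
  expect_equal(as.numeric(bf_vs_unconstrained(.01, 1 / 24)), .24)
  expect_error(bf_vs_unconstrained(.5, 0), "complexity")

  expect_equal(as.numeric(bf_vs_complement(.548, 1 / 24)), 27.9,
               tolerance = .01)
  expect_equal(as.numeric(bf_vs_complement(.89, .5)), 8.09, tolerance = 1e-3)
  expect_equal(as.numeric(bf_vs_complement(.5, .5)), 1)
  expect_equal(as.numeric(bf_vs_complement(0, .5)), 0)
  expect_warning(inf_bf <- bf_vs_complement(1, .5), "Inf")
  expect_identical(as.numeric(inf_bf), Inf)
  expect_error(bf_vs_complement(.5, 1), "strictly between")

  expect_equal(bf_pairwise(13.16, 2.00), 6.58)
  expect_equal(bf_pairwise(3.3, 3.3), 1)
  expect_equal(bf_pairwise(1.98, .26), 7.62, tolerance = .01)
  expect_warning(expect_identical(bf_pairwise(2, 0), Inf), "Inf")
})

test_that("complement BF increases strictly with fit and is 1 iff f = c", {
  cc <- 1 / 24
  f <- seq(.05, .95, by = .05)
  b <- vapply(f, function(fi) as.numeric(bf_vs_complement(fi, cc)),
              numeric(1))
  expect_true(all(diff(b) > 0))
  expect_equal(as.numeric(bf_vs_complement(cc, cc)), 1)
  expect_true(all(b[f > cc] > 1) && all(b[f < cc] < 1))
})

test_that("fit and complement fit sum to one on a shared pool", {
  post <- posterior_update(uniform_prior(lay4()), c(7, 5, 4, 1))
  pool <- sample_product(post, 5e4, seed = 43)
  for (h in list(h_full4(), h_avg4())) {
    f <- estimate_fit(h, post, pool = pool)
    fc <- estimate_fit(complement_of(h), post, pool = pool)
    expect_identical(f$value + fc$value, 1)
  }
})

test_that("complexities of all 24 orderings sum to one on a shared pool", {
  pool <- sample_product(uniform_prior(lay4()), 1e5, seed = 44)
  lay <- lay4()
  cs <- vapply(orderings4(), function(txt) {
    estimate_complexity(parse_hypothesis(txt, lay), pool = pool)$value
  }, numeric(1))
  expect_identical(sum(cs * 1e5), 1e5)  # exact partition of the draws
})

test_that("evaluate_hypotheses fills all families consistently", {
  counts <- nof1_fixture("table1")
  ev <- evaluate_hypotheses(counts, hset4(), n_draws = 2e4, seed = 45)
  expect_s3_class(ev, "nof1_eval")
  expect_equal(nrow(ev), 6)
  # pairwise BFs are exactly the ratio of stored bf_u values (shared pools)
  pw <- attr(ev, "pairwise")
  for (i in seq_len(nrow(pw))) {
    num <- ev$bf_u[ev$person == pw$person[i] &
                     ev$hypothesis == pw$hypothesis[i]]
    den <- ev$bf_u[ev$person == pw$person[i] & ev$hypothesis == pw$vs[i]]
    expect_identical(pw$bf[i], num / den)
  }
  # complexity is data-independent: identical across persons
  expect_equal(length(unique(ev$complexity[ev$hypothesis == "H1"])), 1L)
  # tidy/glance interface
  td <- tidy(ev)
  expect_true(all(c("best", "threshold") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$n_persons, 3L)
  expect_equal(gl$n_hypotheses, 2L)
})

test_that("evaluation is reproducible under a fixed root seed", {
  counts <- nof1_fixture("table1")
  e1 <- evaluate_hypotheses(counts, hset4(), n_draws = 5e3, seed = 46)
  e2 <- evaluate_hypotheses(counts, hset4(), n_draws = 5e3, seed = 46)
  expect_identical(tibble::as_tibble(e1), tibble::as_tibble(e2))
  expect_identical(attr(e1, "pairwise"), attr(e2, "pairwise"))
})

test_that("single-hypothesis evaluation keeps the trivial pairwise entry", {
  counts <- nof1_fixture("table1")[1, ]
  hs <- hypothesis_set(H1 = "c1 > c2 > c3 > c4", layout = lay4())
  ev <- evaluate_hypotheses(counts, hs, n_draws = 5e3, seed = 47)
  pw <- attr(ev, "pairwise")
  expect_equal(nrow(pw), 1L)
  expect_identical(pw$bf, 1)
})

test_that("the best-hypothesis rule uses the max(M-1, 2) threshold", {
  # two hypotheses: an advantage of exactly 2 selects
  d <- select_best(c(H1 = 4, H2 = 2))
  expect_equal(d$best, "H1")
  expect_equal(d$threshold, 2)
  # four hypotheses, top advantage 2.13 < 3: none selected
  d2 <- select_best(c(H1 = 0.59, H2 = 0.93, H3 = 1.98, H4 = 0.26))
  expect_equal(d2$threshold, 3)
  expect_true(is.na(d2$best))
  # ties never select
  d3 <- select_best(c(H1 = 2, H2 = 2, H3 = 2))
  expect_true(is.na(d3$best))
  # override
  expect_equal(select_best(c(H1 = 3, H2 = 2), threshold = 1.2)$best, "H1")
})
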