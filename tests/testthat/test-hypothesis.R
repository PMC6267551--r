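test_that("constraint strings translate to the expected matrices", {
  lay <- lay4()
  m1 <- h_full4()$matrix
  expect_equal(unname(m1), rbind(c(1, -1, 0, 0),
                                 c(0, 1, -1, 0),
                                 c(0, 0, 1, -1)))
  m2 <- h_avg4()$matrix
  expect_equal(unname(m2), matrix(c(.5, .5, -.5, -.5), 1))
  m3 <- parse_hypothesis("c1 > c2; c3 > c4", lay)$matrix
  expect_equal(unname(m3), rbind(c(1, -1, 0, 0), c(0, 0, 1, -1)))
  expect_equal(unname(parse_hypothesis("c1 < c2", lay)$matrix),
               matrix(c(-1, 1, 0, 0), 1))
  # interaction contrast: difference terms on both sides
  m4 <- parse_hypothesis("c1 - c3 > c2 - c4", lay)$matrix
  expect_equal(unname(m4), matrix(c(1, -1, -1, 1), 1))
})

test_that("chains expand to adjacent pairs only, with one +1/-1 per row", {
  h <- h_full8()
  expect_equal(nrow(h$matrix), 7)
  expect_true(all(apply(h$matrix, 1, function(r) {
    sum(r == 1) == 1 && sum(r == -1) == 1 && sum(r != 0) == 2
  })))
})

test_that("parsing is invariant to whitespace and direction rewriting", {
  lay <- lay4()
  a <- parse_hypothesis("c1>c2>c3>c4", lay)
  b <- parse_hypothesis("  c1 >  c2 > c3 >c4 ", lay)
  expect_equal(a$matrix, b$matrix)
  # "a > b" and "b < a" encode the same row
  expect_equal(parse_hypothesis("c1 > c2", lay)$matrix,
               parse_hypothesis("c2 < c1", lay)$matrix)
})

test_that("hyphenated condition names parse without splitting on minus", {
  lay <- condition_layout(c("hr-sup", "hr-sub", "lr-sup", "lr-sub"), 7)
  h <- parse_hypothesis("hr-sup - lr-sup > hr-sub - lr-sub", lay)
  expect_equal(unname(h$matrix), matrix(c(1, -1, -1, 1), 1))
  h2 <- parse_hypothesis("(hr-sup + hr-sub)/2 > (lr-sup + lr-sub)/2", lay)
  expect_equal(unname(h2$matrix), matrix(c(.5, .5, -.5, -.5), 1))
})

test_that("malformed constraint strings fail with informative errors", {
  lay <- lay4()
  expect_error(parse_hypothesis("c1 > c9", lay), "unknown token")
  expect_error(parse_hypothesis("c1 > c2 < c3", lay), "mixed-direction")
  expect_error(parse_hypothesis("c1 > ; c3 > c4", lay), "empty chain")
  expect_error(parse_hypothesis("c1, c2", lay), "no constraints")
  expect_error(parse_hypothesis("c1 > 2", lay), "condition")
  expect_error(parse_hypothesis("(c1 + c2/2 > c3", lay), "parenthes")
  expect_error(parse_hypothesis("c1 > c1", lay), "all zeros")
})

test_that("complement membership is the strict negation of the hypothesis", {
  h <- h_full4()
  comp <- complement_of(h)
  expect_equal(comp$kind, "complement")
  # ascending point violates the descending order
  expect_true(satisfies(comp, c(0.1, 0.2, 0.3, 0.4)))
  expect_false(satisfies(h, c(0.1, 0.2, 0.3, 0.4)))
  # descending point satisfies the hypothesis, not the complement
  expect_true(satisfies(h, c(0.8, 0.6, 0.4, 0.2)))
  expect_false(satisfies(comp, c(0.8, 0.6, 0.4, 0.2)))
  expect_error(complement_of(comp), "informative")
  expect_error(complement_of(unconstrained_hypothesis(lay4())),
               "informative")
})

test_that("membership of H and its complement partition interior draws", {
  h <- h_avg4()
  comp <- complement_of(h)
  draws <- sample_product(uniform_prior(lay4()), 5000, seed = 11)
  in_h <- satisfies(h, draws)
  in_c <- satisfies(comp, draws)
  expect_true(all(xor(in_h, in_c)))  # boundary has probability zero
  # an exact boundary point belongs to neither
  expect_false(satisfies(h, c(.5, .5, .5, .5)))
  expect_false(satisfies(comp, c(.5, .5, .5, .5)))
})

test_that("validate_constraints reports structure without modifying input", {
  d <- validate_constraints(h_full4())
  expect_true(all(d$ok))
  expect_match(d$detail[d$check == "rows"], "K = 3")
  d2 <- validate_constraints(rbind(c(1, -1, 0, 0), c(2, -2, 0, 0)))
  expect_false(d2$ok[d2$check == "no_proportional_rows"])
  d3 <- validate_constraints(rbind(c(1, -1, 0, 0), c(0, 0, 0, 0)))
  expect_false(d3$ok[d3$check == "no_zero_rows"])
})

test_that("layouts and hypothesis sets enforce their invariants", {
  expect_error(condition_layout("only_one", 7), "at least two")
  expect_error(condition_layout(c("a", "a"), 7), "unique")
  expect_error(condition_layout(c("a", "b"), 0), "positive")
  expect_error(hypothesis_set(H1 = "c1 > c2", H1 = "c2 > c1",
                              layout = lay4()), "unique")
  expect_error(hypothesis_set(layout = lay4()), "at least one")
  hs <- hset4()
  expect_equal(names(hs$hypotheses), c("H1", "H2"))
})

test_that("analytic complexity is attached only for complete orderings", {
  expect_equal(analytic_complexity(h_full4()), 1 / 24)
  expect_equal(analytic_complexity(complement_of(h_full4())), 23 / 24)
  expect_equal(analytic_complexity(h_full8()), 1 / factorial(8))
  expect_true(is.na(analytic_complexity(h_avg4())))
  # a reversed chain written with '<' is still a complete ordering
  asc <- parse_hypothesis("c1 < c2 < c3 < c4", lay4())
  expect_equal(analytic_complexity(asc), 1 / 24)
  # partial order is not
  part <- parse_hypothesis("c1 > c2; c3 > c4", lay4())
  expect_true(is.na(analytic_complexity(part)))
})
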