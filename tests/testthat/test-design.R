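test_that("truncated sampling lands in the requested region", {
  h <- h_full4()
  pis <- sample_wp_population(h, n = 500, mode = "under_h", seed = 61)
  expect_true(all(satisfies(h, pis)))
  expect_true(all(pis > 0 & pis < 1))
  pic <- sample_wp_population(h, n = 500, mode = "under_complement",
                              seed = 62)
  expect_true(all(satisfies(complement_of(h), pic)))
  # rejection also works for non-ordering regions
  hp <- parse_hypothesis("c1 > c3; c2 > c3", condition_layout(
    c("c1", "c2", "c3"), 7))
  pp <- sample_wp_population(hp, n = 300, mode = "under_h", seed = 63)
  expect_true(all(satisfies(hp, pp)))
})

test_that("sorted-uniform sampling matches order-statistics theory", {
  h <- h_full4()
  pis <- sample_wp_population(h, n = 2e4, mode = "under_h", seed = 64)
  # the largest coordinate of J sorted uniforms has mean J/(J+1)
  expect_equal(mean(pis[, 1]), 4 / 5, tolerance = 0.01)
  expect_equal(mean(pis[, 4]), 1 / 5, tolerance = 0.01)
  expect_true(all(pis[, 1] > pis[, 2] & pis[, 2] > pis[, 3] &
                    pis[, 3] > pis[, 4]))
})

test_that("sort shortcut and plain rejection sample the same distribution", {
  lay3 <- condition_layout(c("a", "b", "c"), 7)
  h <- parse_hypothesis("a > b > c", lay3)
  short <- sample_wp_population(h, n = 1e5, mode = "under_h", seed = 65)
  # scaling the rows defeats the ordering detection, forcing rejection
  # sampling of the identical region
  h_rej <- h
  h_rej$matrix <- 2 * h$matrix
  expect_true(is.na(analytic_complexity(h_rej)))
  rej <- sample_wp_population(h_rej, n = 1e5, mode = "under_h", seed = 66)
  se <- sqrt(1 / 18) / sqrt(1e5)  # bounded by a uniform's sd
  expect_true(all(abs(colMeans(short) - colMeans(rej)) < 3 * se))
})

test_that("mixture mode draws the configured proportion from each region", {
  h <- h_full4()
  pis <- sample_wp_population(h, n = 1e4, mode = "mixture", theta = .5,
                              seed = 67)
  frac <- mean(satisfies(h, pis))
  expect_lt(abs(frac - .5), 3 * sqrt(.25 / 1e4))
  expect_error(sample_wp_population(h, 10, "mixture", theta = 1.5),
               "theta")
})

test_that("rejection sampling reports exhaustion with an acceptance rate", {
  h <- h_full8()
  h$matrix <- 2 * h$matrix  # force rejection for a 1/8! region
  expect_error(
    sample_wp_population(h, n = 50, mode = "under_h", seed = 68,
                         max_draws = 2e4),
    "acceptance rate"
  )
})

test_that("surrogate Bayes factors point in the population's direction", {
  h <- h_full4()
  s_h <- build_surrogate(h, mode = "under_h", r = 50, size = 60,
                         n_draws = 2e4, seed = 69)
  expect_gt(median(s_h$bf), 1)
  s_c <- build_surrogate(h, mode = "under_complement", r = 50, size = 60,
                         n_draws = 2e4, seed = 70)
  expect_lt(median(s_c$bf), 1)
  # reproducibility is bit-identical
  again <- build_surrogate(h, mode = "under_h", r = 50, size = 60,
                           n_draws = 2e4, seed = 69)
  expect_identical(s_h$bf, again$bf)
})

test_that("bootstrap summaries collapse correctly for degenerate inputs", {
  # P = 1: gP percentiles are the surrogate BF percentiles, median ER is 1
  bf <- exp(stats::rnorm(500))
  bt <- bootstrap_design(bf, p = 1, sets = 400, seed = 71)
  gp_q <- bt$value[bt$statistic == "gp_bf"]
  expect_true(all(gp_q >= min(bf) & gp_q <= max(bf)))
  expect_equal(bt$value[bt$statistic == "er" & bt$percentile == 50], 1)
  # identical surrogate BFs: every gP percentile equals b, SR is 0
  bt2 <- bootstrap_design(rep(2.5, 100), p = 10, sets = 100, seed = 72)
  expect_true(all(bt2$value[bt2$statistic == "gp_bf"] == 2.5))
  expect_true(all(bt2$value[bt2$statistic == "sr"] == 0))
})

test_that("run_design produces a coherent grid of percentile summaries", {
  h <- h_full4()
  cfg <- design_config(h, r_grid = c(7, 21), p_grid = c(5, 15),
                       modes = c("under_h", "under_complement"),
                       surrogate_size = 150, n_boot = 100, n_draws = 5e3,
                       seed = 73)
  res <- run_design(cfg)
  expect_s3_class(res, "nof1_design")
  expect_equal(nrow(res), 2 * 2 * 2 * 3 * 3)  # modes x R x P x stats x pcts
  # percentile triplets are monotone in every cell
  mono <- res |>
    dplyr::arrange(.data$percentile) |>
    dplyr::group_by(.data$population, .data$r, .data$p, .data$statistic) |>
    dplyr::summarise(ok = !is.unsorted(.data$value), .groups = "drop")
  expect_true(all(mono$ok))
  prop <- res[res$statistic %in% c("er", "sr"), ]
  expect_true(all(prop$value >= 0 & prop$value <= 1))
  # opposite populations put the median gP-BF on opposite sides of 1
  med <- res[res$statistic == "gp_bf" & res$percentile == 50 &
               res$r == 21 & res$p == 15, ]
  expect_gt(med$value[med$population == "under_h"], 1)
  expect_lt(med$value[med$population == "under_complement"], 1)
  # identical seed reruns identically
  expect_identical(res$value, run_design(cfg)$value)
})

test_that("median gP-BF grows with the number of replications under H", {
  h <- h_full4()
  meds <- sapply(1:5, function(s) {
    sapply(c(7, 14, 21), function(r) {
      bf <- build_surrogate(h, mode = "under_h", r = r, size = 120,
                            n_draws = 5e3, seed = 80 + s)$bf
      median(bf)
    })
  })
  inversions <- sum(apply(meds, 2, function(m) diff(m) < 0))
  expect_lte(inversions, 1)
})
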