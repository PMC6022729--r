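test_that("fractional distance is a ratio to the comparator", {
  expect_equal(advantage_distance(110, 100), 0.10)
  expect_equal(advantage_distance(24000, 16000), 0.5)
  for (x in c(0.3, 1, 57, 2e6)) expect_equal(advantage_distance(x, x), 0)
  # asymmetric in its arguments
  expect_false(isTRUE(all.equal(advantage_distance(16000, 24000),
                                advantage_distance(24000, 16000))))
  expect_error(advantage_distance(5, 0), "positive")
  expect_error(advantage_distance(-1, 5), "positive")
})

test_that("soft comparison hits the documented anchor points", {
  expect_equal(win_probability(110, 100, "higher_better"), 0.5)
  w20 <- win_probability(120, 100, "higher_better")
  expect_equal(w20, stats::plogis(50 * 0.1))
  expect_gt(w20, 0.99)
  # disadvantages and ties never win
  expect_equal(win_probability(90, 100, "higher_better"), 0)
  expect_equal(win_probability(100, 100, "higher_better"), 0)
  expect_equal(win_probability(24000, 16000, "lower_better"), 0)
  # lower-better advantage: cheap price against an expensive comparator
  expect_equal(win_probability(16000, 24000, "lower_better"),
               stats::plogis(50 * (1 / 3 - 0.1)))
  # strictly increasing in the advantage
  adv <- seq(0.01, 0.5, by = 0.01)
  w <- vapply(adv, function(a)
    win_probability(100 * (1 + a), 100, "higher_better"), 0)
  expect_true(all(diff(w) > 0))
  expect_error(win_probability(0, 100, "higher_better"), "positive")
})

test_that("evaluation distribution follows similarity weighting", {
  pr <- mdbs_problem(
    rbind(dimension("d1", "higher_better"),
          dimension("d2", "higher_better")),
    list(A = c(d1 = 10, d2 = 20), B = c(d1 = 20, d2 = 10)))
  ed <- evaluation_distribution(pr)
  expect_equal(sum(ed), 1, tolerance = 1e-12)
  # mirror symmetry puts half the mass on each alternative
  expect_equal(sum(ed["A", ]), 0.5, tolerance = 1e-12)
  # alpha = 0: every cell weight equals its comparator count
  ed0 <- evaluation_distribution(pr, mdbs_params(alpha = 0))
  expect_equal(unname(as.vector(ed0)), rep(0.25, 4))
})

test_that("missing values are never evaluated", {
  pr <- mdbs_problem(
    rbind(dimension("d1", "higher_better"),
          dimension("d2", "higher_better")),
    list(A = c(d1 = 10), B = c(d1 = 20, d2 = 10),
         C = c(d1 = 15, d2 = 30)))
  ed <- evaluation_distribution(pr)
  expect_equal(ed["A", "d2"], 0)
  expect_equal(sum(ed), 1, tolerance = 1e-12)
  # a dimension with no comparator is equally inert
  pr2 <- mdbs_problem(
    rbind(dimension("d1", "higher_better"),
          dimension("d2", "higher_better")),
    list(A = c(d1 = 10, d2 = 5), B = c(d1 = 20)))
  expect_equal(evaluation_distribution(pr2)["A", "d2"], 0)
})

test_that("degenerate problems raise an explicit error", {
  pr <- mdbs_problem(rbind(dimension("d1", "higher_better")),
                     list(A = c(d1 = 10)))
  expect_error(evaluation_distribution(pr), "degenerate")
  expect_error(accumulation_rates(pr), "degenerate")
})

test_that("partner selection is similarity-weighted over the pool", {
  pr <- mdbs_problem(
    rbind(dimension("price", "lower_better"),
          dimension("mpg", "higher_better")),
    list(A = c(price = 24000, mpg = 32), B = c(price = 16000, mpg = 24),
         D = c(price = 28000, mpg = 29)))
  pd <- partner_distribution("A", "price", pr)
  expect_equal(sum(pd$probability), 1, tolerance = 1e-12)
  # e^(-3 * 0.5) vs e^(-3 * 1/7), normalized
  w <- exp(-3 * c(0.5, 4000 / 28000))
  expect_equal(pd$probability[order(pd$value)], (w / sum(w)),
               tolerance = 1e-6)
  expect_equal(round(sort(pd$probability), 3), c(0.255, 0.745))
  # single comparator gets probability 1
  pd1 <- partner_distribution("A", "price", two_car_problem())
  expect_equal(pd1$probability, 1)
  expect_error(partner_distribution("A", "nope", pr), "no such")
})

test_that("accumulation rates match the hand-built car examples", {
  pp <- mdbs_params()
  r2 <- accumulation_rates(two_car_problem(), pp)
  # the one winning cell of each car carries Eq.-1 weight exp(-1) = 0.3679
  # over a total weight of 1.4313
  expect_equal(unname(r2[["A"]]), unname(r2[["B"]]), tolerance = 1e-12)
  expect_equal(unname(r2[["A"]]), 0.2571, tolerance = 5e-4)
  # identical alternatives hold no strict advantage anywhere
  same <- mdbs_problem(rbind(dimension("d1", "higher_better")),
                       list(A = c(d1 = 5), B = c(d1 = 5)))
  expect_equal(unname(unclass(accumulation_rates(same, pp))), c(0, 0))
  # attraction triad ordering
  p <- load_fixture("synthetic_big_three")
  r3 <- accumulation_rates(subset_problem(p, c("A", "B", "D")), pp)
  expect_true(r3[["A"]] > r3[["B"]] && r3[["B"]] > r3[["D"]])
})

test_that("rates agree with the independent brute-force oracle", {
  pp <- mdbs_params()
  for (seed in 1:8) {
    pr <- random_problem(seed, with_context = TRUE)
    expect_equal(unname(unclass(accumulation_rates(pr, pp))),
                 unname(brute_rates(pr, pp)), tolerance = 1e-12)
  }
})

test_that("relative rank counts strictly beaten pool values", {
  expect_equal(relative_rank(5, c(1, 2, 7), "higher_better"), 2 / 3)
  skewed <- load_fixture("money_skewed")
  expect_equal(relative_rank(200, skewed, "higher_better"), 5 / 7)
  unif <- load_fixture("money_uniform")
  expect_equal(relative_rank(200, unif, "higher_better"), 2 / 6)
  expect_equal(relative_rank(0.5, c(1, 2, 7), "higher_better"), 0)
  # ties count as not beaten; lower-better flips the direction
  expect_equal(relative_rank(2, c(1, 2, 3), "higher_better"), 1 / 3)
  expect_equal(relative_rank(2, c(1, 2, 3), "lower_better"), 1 / 3)
  expect_error(relative_rank(5, numeric(0), "higher_better"), "empty")
})

test_that("subjective value behaves as a single-cell rate", {
  pp <- mdbs_params()
  pool <- c(10, 20, 30)
  expect_equal(subjective_value(5, pool, "higher_better", pp), 0)
  # with uniform partner weights (alpha 0) the curve is nondecreasing;
  # under similarity weighting it dips locally at pool values, where the
  # tied partner is maximally similar but never beaten
  grid <- seq(5, 60, by = 2.5)
  sv0 <- vapply(grid, subjective_value, 0, pool = pool,
                polarity = "higher_better",
                params = mdbs_params(alpha = 0))
  expect_true(all(diff(sv0) >= -1e-12))
  expect_lt(subjective_value(30, pool, "higher_better", pp),
            subjective_value(27.5, pool, "higher_better", pp))
  # a denser sub-value region lifts the skewed-pool value of 200
  expect_gt(
    subjective_value(200, load_fixture("money_skewed"), "higher_better"),
    subjective_value(200, load_fixture("money_uniform"), "higher_better"))
  expect_error(subjective_value(5, numeric(0), "higher_better"), "empty")
})

test_that("comparison enumeration crosses pairs with shared dimensions", {
  p3 <- subset_problem(load_fixture("synthetic_big_three"),
                       c("A", "B", "D"))
  expect_equal(nrow(enumerate_comparisons(p3)), 12)
  expect_equal(nrow(enumerate_comparisons(two_car_problem())), 4)
  # each intransitive pair shares exactly one dimension
  expect_equal(nrow(enumerate_comparisons(load_fixture("intransitive"))),
               6)
})

test_that("problem validation names the offending field", {
  dims <- rbind(dimension("d1", "higher_better"))
  expect_error(mdbs_problem(dims, list(A = c(d2 = 1))), "undeclared")
  expect_error(mdbs_problem(dims, list(A = c(d1 = -2))), "nonpositive")
  expect_error(mdbs_problem(dims, list(A = c(d1 = 1)),
                            context = list(d1 = c(0))), "context")
  expect_error(dimension("d1", "bigger_better"))
})
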