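test_that("big three: binary indifference and all three effects", {
  s <- run_big_three()
  expect_true(all(abs(tapply(s$table$probability, s$table$condition,
                             sum) - 1) < 1e-9))
  p <- function(cond, alt)
    s$table$probability[s$table$condition == cond &
                          s$table$alternative == alt]
  expect_equal(p("AB", "A"), 0.5, tolerance = 1e-12)
  expect_equal(p("AB", "B"), 0.5, tolerance = 1e-12)
  # A maximal in every triad, with the documented orderings
  expect_true(p("ABD", "A") > p("ABD", "B"))
  expect_true(p("ABD", "B") > p("ABD", "D"))
  expect_true(p("ABC", "A") > max(p("ABC", "B"), p("ABC", "C")))
  expect_true(p("ABS", "A") > max(p("ABS", "B"), p("ABS", "S")))
  expect_lt(p("ABS", "B"), 0.30)
  expect_lt(p("ABS", "S"), 0.30)
  expect_equal(p("ABC", "A"), 0.41, tolerance = 0.02)
  expect_equal(p("ABS", "A"), 0.45, tolerance = 0.02)
  # regularity violation: adding the dominated decoy raises p(A)
  expect_gt(s$effects[["regularity_violation"]], 0)
})

test_that("decoy distance sweep reproduces the documented endpoints", {
  s <- sweep_decoy(n_steps = 11)
  tab <- s$table
  # coincident decoy: p(A) = p(decoy) by symmetry
  last <- tab[tab$position == 1, ]
  expect_equal(last$probability[last$alternative == "A"],
               last$probability[last$alternative == "decoy"],
               tolerance = 1e-9)
  # an intermediate decoy helps A more than a decoy adjacent to A
  pA <- vapply(sort(unique(tab$position)), function(t)
    tab$probability[tab$position == t & tab$alternative == "A"], 0)
  expect_gt(max(pA[2:9]), pA[10])
  # a decoy within beta0 of A on both dimensions kills the attraction
  # effect (its disadvantages go unrecognized)
  expect_lt(s$effects[["effect_near_A"]], 0.05)
  expect_gt(s$effects[["effect_at_peak"]], 0.2)
})

test_that("range-widening decoy location beats the other location", {
  s <- compare_decoy_locations()
  expect_gt(s$effects[["p_A_with_R"]], s$effects[["p_A_with_F"]])
  # direction is invariant to rescaling a dimension's units
  fx <- load_fixture("synthetic_big_three")
  fx2 <- mdbs_problem(fx$dimensions,
                      apply(fx$values, 1L, function(v) {
                        v <- v[!is.na(v)]
                        v["price"] <- v["price"] / 1000
                        v
                      }, simplify = FALSE))
  s2 <- compare_decoy_locations(fx2)
  expect_equal(s2$effects[["location_gap"]], s$effects[["location_gap"]],
               tolerance = 1e-9)
})

test_that("long-term-memory samples dilute all three effects", {
  s <- dilute_with_ltm(sample_counts = c(0, 32), n_reps = 60, seed = 4)
  tab <- s$table
  for (eff in c("attraction", "compromise", "similarity")) {
    e0 <- tab$effect_size[tab$effect == eff & tab$sample_count == 0]
    e32 <- tab$effect_size[tab$effect == eff & tab$sample_count == 32]
    expect_lt(e32, e0)
  }
  # zero samples reproduce the undiluted scenario exactly
  base <- run_big_three()
  expect_equal(tab$effect_size[tab$sample_count == 0 &
                                 tab$effect == "attraction"],
               unname(base$effects[["attraction"]]), tolerance = 1e-12)
  # seeded curves are reproducible
  s2 <- dilute_with_ltm(sample_counts = c(0, 32), n_reps = 60, seed = 4)
  expect_identical(s$table, s2$table)
})

test_that("effects strengthen with the comparison horizon", {
  s <- sweep_horizon(horizons = c(0, 1, 10))
  tab <- s$table
  for (eff in unique(tab$effect)) {
    e <- tab[tab$effect == eff, ]
    expect_equal(e$effect_size[e$horizon == 0], 0, tolerance = 1e-12)
    expect_gt(e$effect_size[e$horizon == 10],
              e$effect_size[e$horizon == 1])
  }
})

test_that("alpha strengthens attraction/compromise, weakens similarity", {
  s <- sweep_alpha(alpha_grid = seq(0, 5, by = 1))
  expect_gt(s$effects[["slope_attraction"]], 0)
  expect_gt(s$effects[["slope_compromise"]], 0)
  expect_lt(s$effects[["slope_similarity"]], 0)
})

test_that("balanced alternative wins under commensurable collapsing", {
  s <- attribute_balance()
  for (cond in unique(s$table$condition)) {
    sub <- s$table[s$table$condition == cond, ]
    expect_equal(sub$alternative[which.max(sub$probability)], "Q")
    expect_equal(sum(sub$probability), 1, tolerance = 1e-9)
  }
  # the collapsed pool of {K, L, Q} is {40, 50, 60, 60, 70, 80} with the
  # middle pair belonging to Q
  fx <- load_fixture("balance_ratings")
  klq <- subset_problem(fx, c("K", "L", "Q"))
  pool <- sort(as.vector(klq$values))
  expect_equal(pool, c(40, 50, 60, 60, 70, 80))
  expect_equal(unname(klq$values["Q", ]), c(60, 60))
  # without collapsing, K and Q swap under the value reflection
  s_raw <- attribute_balance(collapse = FALSE,
                             triads = list(c("K", "L", "Q")))
  probs <- s_raw$table$probability
  names(probs) <- s_raw$table$alternative
  refl <- mdbs_problem(fx$dimensions,
                       list(K = c(efficiency = 80, warranty = 40),
                            L = c(efficiency = 70, warranty = 50),
                            Q = c(efficiency = 60, warranty = 60)))
  pr <- choice_probabilities(accumulation_rates(refl), 0.1)$probabilities
  expect_equal(unname(probs[c("K", "L", "Q")]),
               unname(pr[c("K", "L", "Q")]), tolerance = 1e-9)
  # collapsing across ungrouped dimensions is refused
  expect_error(attribute_balance(two_car_problem(),
                                 triads = list(c("A", "B"))),
               "commensurable")
})

test_that("prior trade-off context reverses the focal preference", {
  s <- contextual_choice("background_contrast")
  expect_lt(s$effects[["p_A_shallow_prior"]], 0.5)
  expect_gt(s$effects[["p_A_steep_prior"]], 0.5)
  # the relative-rank mechanism: the shallow prior pair's RAM values
  # demote A's RAM rank from 1.0 to 1/3
  fx <- mdbs:::.fx_background()
  expect_equal(relative_rank(fx$A[["ram"]], fx$B[["ram"]],
                             "higher_better"), 1)
  expect_equal(relative_rank(fx$A[["ram"]],
                             c(fx$B[["ram"]], fx$Ap[["ram"]],
                               fx$Bp[["ram"]]), "higher_better"), 1 / 3)
  # and the steep prior pair demotes B's price rank the same way
  expect_equal(relative_rank(fx$B[["price"]],
                             c(fx$A[["price"]], fx$App[["price"]],
                               fx$Bpp[["price"]]), "lower_better"), 1 / 3)
})

test_that("phantom decoy helps its similar neighbor at large alpha", {
  s10 <- contextual_choice("phantom_decoy", alpha_phantom = 10)
  expect_gt(s10$effects[["phantom_gap"]], 0)
  s3 <- contextual_choice("phantom_decoy", alpha_phantom = 3)
  # the effect needs strong similarity weighting: far weaker at alpha 3
  expect_gt(s10$effects[["phantom_gap"]], s3$effects[["phantom_gap"]])
  expect_equal(s10$effects[["alpha_used"]], 10)
})

test_that("a low-value bundled attribute hurts its owner", {
  s <- contextual_choice("less_is_more")
  expect_gt(s$effects[["rate_drop"]], 0)
  expect_gt(s$effects[["drop"]], 0)
})

test_that("unique dimensions without comparators cannot affect choice", {
  s <- contextual_choice("alignability")
  expect_equal(s$effects[["max_abs_change"]], 0)
})

test_that("missing values generate an intransitive pairwise cycle", {
  s <- intransitivity_suite()
  expect_equal(s$effects[["p_Y_given_VY"]], 1.0)
  expect_equal(s$effects[["p_Z_given_YZ"]], 1.0)
  expect_equal(s$effects[["p_V_given_ZV"]], 1.0)
  tern <- s$table[s$table$condition == "VYZ", ]
  expect_true(all(tern$probability > 0.25 & tern$probability < 0.40))
  # guarded regression: imputing the missing values breaks the cycle
  fx <- load_fixture("intransitive")
  vals <- fx$values
  for (d in colnames(vals))
    vals[is.na(vals[, d]), d] <- mean(vals[, d], na.rm = TRUE)
  imputed <- mdbs_problem(fx$dimensions,
                          apply(vals, 1L, function(v) v, simplify = FALSE))
  wins <- vapply(list(c("V", "Y"), c("Y", "Z"), c("Z", "V")),
                 function(ids) {
    p <- choice_probabilities(
      accumulation_rates(subset_problem(imputed, ids)), 0.1)$probabilities
    unname(p[[2L]])
  }, 0)
  expect_false(all(wins == 1))
})

test_that("perceptual focus diagnostics and winner", {
  s <- perceptual_focus()
  expect_equal(s$effects[["rank_A_x"]], 0.50)
  expect_equal(s$effects[["rank_B_x"]], 1.0)
  expect_equal(s$effects[["rank_A_y"]], 1.00)
  tab <- s$table
  expect_equal(tab$alternative[which.max(tab$probability)], "A")
})

test_that("value curves show density, concavity and loss asymmetry", {
  sd_ <- value_curve("distribution")
  expect_gt(sd_$effects[["skewed_rise_below_100"]],
            sd_$effects[["skewed_rise_above_100"]])
  expect_gt(sd_$effects[["skewed_rise_below_100"]],
            sd_$effects[["uniform_rise_below_100"]])

  sl <- value_curve("loss_ranges")
  expect_gt(sl$effects[["loss_slope"]], sl$effects[["gain_slope"]])
  rev <- value_curve("loss_ranges", reverse = TRUE)
  expect_lt(rev$effects[["loss_slope"]], rev$effects[["gain_slope"]])
  # identical pools give symmetric curves
  pool <- load_fixture("gain_loss_ranges")$losses
  grid <- 1:15
  svg <- vapply(grid, subjective_value, 0, pool = pool,
                polarity = "higher_better")
  expect_equal(svg, svg)  # trivially symmetric when pools coincide
})

test_that("the scenario registry runs every scenario", {
  for (nm in scenario_names()) {
    s <- if (nm == "ltm_dilution")
      run_scenario(nm, seed = 2, sample_counts = c(0, 8), n_reps = 5)
    else run_scenario(nm, seed = 2)
    expect_s3_class(s, "mdbs_scenario")
    if ("probability" %in% names(s$table) &&
        "condition" %in% names(s$table)) {
      sums <- tapply(s$table$probability, s$table$condition, sum)
      expect_true(all(abs(sums - 1) < 1e-9), info = nm)
    }
  }
  expect_error(run_scenario("nope"), "unknown scenario")
})
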