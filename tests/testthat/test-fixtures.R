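test_that("packaged fixtures match their plain-text snapshots", {
  # intransitive trio
  snap <- read.csv(system.file("extdata", "table5_intransitive.csv",
                               package = "mdbs"))
  fx <- load_fixture("intransitive")
  for (i in seq_len(nrow(snap))) {
    d <- snap$measure[i]
    expect_equal(fx$dimensions$polarity[fx$dimensions$name == d],
                 snap$polarity[i])
    for (id in c("V", "Y", "Z")) {
      v <- snap[[id]][i]
      if (is.na(v)) expect_true(is.na(fx$values[id, d]))
      else expect_equal(unname(fx$values[id, d]), v)
    }
  }
  # qualitative-comparison cars
  snap <- read.csv(system.file("extdata", "table_j1_cars.csv",
                               package = "mdbs"))
  j1 <- load_fixture("j1_cars")
  expect_equal(unname(j1$values[snap$alternative, "x"]), snap$x)
  expect_equal(unname(j1$values[snap$alternative, "y"]), snap$y)
  expect_equal(unname(j1$values["A", ]), c(2.00, 3.00))
  # consumer products
  snap <- read.csv(system.file("extdata", "table_f1_products.csv",
                               package = "mdbs"))
  prods <- load_fixture("products")
  for (i in seq_len(nrow(snap))) {
    pr <- prods[[snap$product[i]]]
    d <- snap$dimension[i]
    expect_equal(unname(pr$values["A", d]), snap$A[i])
    expect_equal(unname(pr$values["B", d]), snap$B[i])
    expect_equal(pr$dimensions$polarity[pr$dimensions$name == d],
                 snap$polarity[i])
  }
  expect_equal(unname(prods$mouthwash$values["A", ]), c(4.5, 77))
  expect_equal(unname(prods$mouthwash$values["B", ]), c(7.2, 56))
})

test_that("money pools replace zero by the epsilon placeholder", {
  sk <- load_fixture("money_skewed")
  expect_equal(length(sk), 7)
  expect_equal(min(sk), 0.01)
  expect_equal(load_fixture("money_skewed", epsilon = 0.5)[1], 0.5)
  expect_error(load_fixture("nope"), "available")
})

test_that("attraction decoy worsens the favored alternative everywhere", {
  prods <- load_fixture("products")
  d <- make_attraction_decoy(prods$mouthwash, "A", "B")
  expect_equal(unname(d["breath"]), 4.5 - 0.25 * 2.7)
  expect_equal(unname(d["germs"]), 77 - 0.25 * 21)
  # a lower-better dimension worsens upward
  cars <- two_car_problem()
  dc <- make_attraction_decoy(cars, "A", "B")
  expect_gt(dc[["price"]], 24000)
  expect_lt(dc[["mpg"]], 32)
  # dominance under the polarities
  pol <- c(price = "lower_better", mpg = "higher_better")
  worse <- mapply(function(dv, av, p)
    if (p == "higher_better") dv < av else dv > av,
    dc, cars$values["A", names(dc)], pol[names(dc)])
  expect_true(all(worse))
  # the zero-fraction limit approaches a copy of the favored alternative
  near <- make_attraction_decoy(cars, "A", "B", fraction = 1e-9)
  expect_equal(unname(near), unname(cars$values["A", ]),
               tolerance = 1e-6)
  expect_error(make_attraction_decoy(cars, "A", "B", fraction = 0))
})

test_that("similarity decoy is a barely-perturbed clone of the rival", {
  prods <- load_fixture("products")
  s <- make_similarity_decoy(prods$mouthwash, "A", "B")
  expect_equal(unname(s["breath"]), 7.2 - 0.02 * 2.7)
  expect_equal(unname(s["germs"]), 56 + 0.02 * 21)
  # all pairwise fractional distances from the rival stay under beta0
  b <- prods$mouthwash$values["B", ]
  expect_true(all(abs(s - b) / b < 0.1))
  clone <- make_similarity_decoy(prods$mouthwash, "A", "B", fraction = 0)
  expect_equal(unname(clone), unname(b))
  # the subtraction side is overridable
  s2 <- make_similarity_decoy(prods$mouthwash, "A", "B",
                              subtract_dim = "germs")
  expect_gt(s2[["breath"]], 7.2)
  expect_lt(s2[["germs"]], 56)
  one_dim <- mdbs_problem(rbind(dimension("d", "higher_better")),
                          list(A = c(d = 1), B = c(d = 2)))
  expect_error(make_similarity_decoy(one_dim, "A", "B"), "two dimensions")
})

test_that("compromise decoy extends the rival-through-favored line", {
  cars <- two_car_problem()
  cd <- make_compromise_decoy(cars, "A", "B")
  expect_equal(unname(cd), c(32000, 40))
  # the favored alternative is intermediate on every dimension
  a <- cars$values["A", ]; b <- cars$values["B", ]
  expect_true(all((a > pmin(b, cd)) & (a < pmax(b, cd))))
  expect_error(make_compromise_decoy(cars, "A", "B", extrapolation = 0))
})

test_that("decoy constructors commute with dimension rescaling", {
  cars <- two_car_problem()
  scaled <- mdbs_problem(cars$dimensions,
                         list(A = c(price = 24, mpg = 32),
                              B = c(price = 16, mpg = 24)))
  for (f in list(make_attraction_decoy, make_compromise_decoy,
                 make_similarity_decoy)) {
    d1 <- f(cars, "A", "B")
    d2 <- f(scaled, "A", "B")
    expect_equal(unname(d1["price"] / 1000), unname(d2["price"]),
                 tolerance = 1e-12)
    expect_equal(unname(d1["mpg"]), unname(d2["mpg"]), tolerance = 1e-12)
  }
})

test_that("long-term-memory sampling is seeded and well-calibrated", {
  spec <- ltm_spec(mean = c(price = 24000, mpg = 32),
                   sd = c(price = 8000, mpg = 8),
                   correlation = -0.2, n = 50, seed = 9)
  p1 <- sample_ltm(spec)
  p2 <- sample_ltm(spec)
  expect_identical(p1, p2)
  expect_equal(lengths(p1), c(price = 50L, mpg = 50L))
  expect_true(all(unlist(p1) > 0))
  # moment check at large n
  big <- sample_ltm(ltm_spec(mean = c(price = 24000, mpg = 32),
                             sd = c(price = 8000, mpg = 8),
                             correlation = -0.2, n = 1e5, seed = 2))
  expect_equal(mean(big$price) / 24000, 1, tolerance = 0.02)
  expect_equal(stats::cor(big$price, big$mpg), -0.2, tolerance = 0.02)
  # empty sample leaves scenarios unchanged
  none <- sample_ltm(ltm_spec(mean = c(a = 1), sd = c(a = 1),
                              n = 0, seed = 1))
  expect_equal(none, list(a = numeric(0)))
  expect_error(
    sample_ltm(ltm_spec(mean = c(a = -50), sd = c(a = 1), n = 5,
                        seed = 1)),
    "infeasible")
})

test_that("synthetic choice data follow the closed-form probabilities", {
  pp <- mdbs_params()
  pr <- subset_problem(load_fixture("synthetic_big_three"),
                       c("A", "B", "D"))
  cnt <- generate_choice_data(pr, pp, 5000, seed = 21)
  expect_equal(sum(cnt), 5000)
  expect_identical(cnt, generate_choice_data(pr, pp, 5000, seed = 21))
  p <- choice_probabilities(accumulation_rates(pr, pp),
                            pp$theta)$probabilities
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(cnt / 5000 - p) < 3 * se + 1e-9))
})
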