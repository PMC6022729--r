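# Packaged attribute-value tables and synthetic stimulus construction.
#
# Plain-text snapshots of the same tables ship under inst/extdata/ and are
# checked against these definitions in the test suite.

.fx_big_three <- function() {
  # Synthetic car market: prices in USD (lower better), fuel efficiency in
  # mpg (higher better). Calibrated so that the binary {A, B} choice is
  # exactly indifferent under default parameters, with an attraction decoy
  # D (dominated by A), a compromise-maker C (A becomes intermediate), a
  # near-clone S of B, and a far point E on the D-to-A line used for decoy
  # distance sweeps.
  mdbs_problem(
    dimensions = rbind(dimension("price", "lower_better"),
                       dimension("mpg", "higher_better")),
    alternatives = list(A = c(price = 24000, mpg = 32),
                        B = c(price = 16000, mpg = 24),
                        C = c(price = 32000, mpg = 40),
                        D = c(price = 28000, mpg = 29),
                        S = c(price = 16500, mpg = 23),
                        E = c(price = 32000, mpg = 26)))
}

.fx_j1 <- function() {
  # Two abstract rating dimensions on a common scale, both higher-better.
  mdbs_problem(
    dimensions = rbind(dimension("x", "higher_better"),
                       dimension("y", "higher_better")),
    alternatives = list(A  = c(x = 2.00, y = 3.00),
                        B  = c(x = 3.00, y = 2.00),
                        D  = c(x = 1.75, y = 2.75),
                        Dp = c(x = 1.90, y = 2.90),
                        F  = c(x = 1.75, y = 3.00),
                        R  = c(x = 2.00, y = 2.75),
                        C  = c(x = 1.00, y = 4.00),
                        S  = c(x = 2.90, y = 2.10),
                        J  = c(x = 2.90, y = 2.00),
                        H  = c(x = 1.90, y = 2.00),
                        G  = c(x = 1.80, y = 2.00),
                        K  = c(x = 0.50, y = 4.50),
                        L  = c(x = 1.50, y = 3.50),
                        Q  = c(x = 2.50, y = 2.50),
                        U  = c(x = 3.50, y = 1.50)))
}

.fx_intransitive <- function() {
  # Three alternatives with systematically missing values: each pairwise
  # choice shares exactly one dimension, and the shared-dimension loser
  # has zero accumulation rate, producing a deterministic preference
  # cycle V -> Z -> Y -> V in pairwise choice.
  mdbs_problem(
    dimensions = rbind(dimension("price", "lower_better"),
                       dimension("efficiency", "higher_better"),
                       dimension("warranty", "higher_better")),
    alternatives = list(V = c(price = 24, warranty = 70),
                        Y = c(price = 16, efficiency = 24),
                        Z = c(efficiency = 32, warranty = 50)))
}

.fx_balance <- function() {
  # Ratings on a 0-100 scale for both warranty and efficiency: the two
  # dimensions are commensurable and may be collapsed into one pooled
  # comparison space. Q is the balanced alternative.
  mdbs_problem(
    dimensions = rbind(dimension("efficiency", "higher_better",
                                 group = "rating"),
                       dimension("warranty", "higher_better",
                                 group = "rating")),
    alternatives = list(K = c(efficiency = 40, warranty = 80),
                        L = c(efficiency = 50, warranty = 70),
                        Q = c(efficiency = 60, warranty = 60),
                        U = c(efficiency = 70, warranty = 50),
                        W = c(efficiency = 80, warranty = 40)))
}

.fx_products <- function() {
  # Consumer-product pairs, two dimensions each. Polarity metadata: price,
  # fee, noise and (GPS) accuracy are lower-better; everything else is
  # higher-better. Whether GPS update rate (Hz) and positional accuracy
  # (m) are best read this way is debatable; the accuracy-in-meters
  # reading (smaller error better) is used here.
  specs <- list(
    mouthwash = list(dims = c(breath = "higher_better",
                              germs = "higher_better"),
                     A = c(breath = 4.5, germs = 77),
                     B = c(breath = 7.2, germs = 56)),
    exercise_class = list(dims = c(fee = "lower_better",
                                   calories = "higher_better"),
                          A = c(fee = 9.49, calories = 356),
                          B = c(fee = 6.49, calories = 259)),
    chocolate = list(dims = c(amount = "higher_better",
                              variety = "higher_better"),
                     A = c(amount = 26, variety = 9),
                     B = c(amount = 33, variety = 5)),
    gps = list(dims = c(update = "higher_better",
                        accuracy = "lower_better"),
               A = c(update = 3.04, accuracy = 4.97),
               B = c(update = 5.62, accuracy = 7.83)),
    battery = list(dims = c(price = "lower_better",
                            talk_time = "higher_better"),
                   A = c(price = 19.93, talk_time = 14.55),
                   B = c(price = 13.49, talk_time = 9.25)),
    light_bulb = list(dims = c(life = "higher_better",
                               price = "lower_better"),
                      A = c(life = 1309, price = 1.35),
                      B = c(life = 1923, price = 2.50)),
    air_purifier = list(dims = c(noise = "lower_better",
                                 efficiency = "higher_better"),
                        A = c(noise = 64.7, efficiency = 325),
                        B = c(noise = 39.3, efficiency = 203)),
    strawberry = list(dims = c(quantity = "higher_better",
                               price = "lower_better"),
                      A = c(quantity = 407, price = 2.58),
                      B = c(quantity = 452, price = 2.85)))
  lapply(specs, function(s) {
    dims <- do.call(rbind, lapply(names(s$dims), function(nm)
      dimension(nm, s$dims[[nm]])))
    mdbs_problem(dims, list(A = s$A, B = s$B))
  })
}

#' Replace zero magnitudes by a small positive placeholder
#'
#' Attribute magnitudes must be strictly positive because fractional
#' distances blow up at zero. Fixture value sets quoted with a 0 member
#' (the money sets, the gain/loss ranges) replace it by `epsilon` so that
#' 0 still counts as beaten by every positive value.
#'
#' @param x Numeric vector.
#' @param epsilon Positive replacement for zeros (default 0.01).
#' @return `x` with zeros replaced.
#' @export
zero_to_epsilon <- function(x, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  x[x == 0] <- epsilon
  x
}

#' Load a packaged fixture
#'
#' @param name One of:
#'   \describe{
#'     \item{`synthetic_big_three`}{Synthetic car market (price, mpg) with
#'       target A, rival B, compromise-maker C, attraction decoy D,
#'       near-clone S and sweep endpoint E.}
#'     \item{`j1_cars`}{Fifteen alternatives on two abstract rating
#'       dimensions (the qualitative-comparison set, including the
#'       perceptual-focus cars A, B, G, H, J).}
#'     \item{`intransitive`}{Three alternatives with missing values
#'       generating an intransitive pairwise cycle.}
#'     \item{`balance_ratings`}{Five cars rated 0-100 on two commensurable
#'       dimensions; Q is balanced.}
#'     \item{`products`}{List of eight two-alternative consumer-product
#'       problems with polarity metadata.}
#'     \item{`money_skewed`}{Positively skewed monetary value pool
#'       (0, 10, 20, 50, 100, 200, 500; zero as epsilon).}
#'     \item{`money_uniform`}{Uniform monetary pool (0, 100, ..., 500;
#'       zero as epsilon).}
#'     \item{`gain_loss_ranges`}{List with `gains` (uniform 0-40, one-unit
#'       grid) and `losses` (uniform 0-20) pools.}
#'   }
#' @param epsilon Placeholder for zero values in money pools.
#' @return An [mdbs_problem()], a list of problems, or a numeric pool,
#'   depending on the fixture.
#' @export
load_fixture <- function(name, epsilon = 0.01) {
  catalog <- c("synthetic_big_three", "j1_cars", "intransitive",
               "balance_ratings", "products", "money_skewed",
               "money_uniform", "gain_loss_ranges")
  if (!name %in% catalog)
    stop("unknown fixture '", name, "'; available: ",
         paste(catalog, collapse = ", "))
  switch(name,
    synthetic_big_three = .fx_big_three(),
    j1_cars = .fx_j1(),
    intransitive = .fx_intransitive(),
    balance_ratings = .fx_balance(),
    products = .fx_products(),
    money_skewed = zero_to_epsilon(c(0, 10, 20, 50, 100, 200, 500), epsilon),
    money_uniform = zero_to_epsilon(c(0, 100, 200, 300, 400, 500), epsilon),
    gain_loss_ranges = list(gains = zero_to_epsilon(0:40, epsilon),
                            losses = zero_to_epsilon(0:20, epsilon)))
}

.decoy_prep <- function(problem, favored, rival) {
  stopifnot(inherits(problem, "mdbs_problem"))
  va <- problem$values[favored, ]
  vb <- problem$values[rival, ]
  if (any(is.na(va)) || any(is.na(vb)))
    stop("decoy construction requires both alternatives on all dimensions")
  list(va = va, vb = vb, pol = .polarities(problem))
}

#' Construct an attraction (dominated) decoy
#'
#' Worsens the favored alternative, in the utility direction, by
#' `fraction` of the absolute attribute difference between the two
#' alternatives on every dimension, so the decoy is strictly dominated by
#' the favored alternative.
#'
#' @param problem An [mdbs_problem()] containing both alternatives.
#' @param favored,rival Alternative ids.
#' @param fraction Positive worsening fraction (default 0.25).
#' @return Named numeric vector of decoy attribute values.
#' @export
make_attraction_decoy <- function(problem, favored, rival,
                                  fraction = 0.25) {
  if (fraction <= 0) stop("'fraction' must be > 0")
  d <- .decoy_prep(problem, favored, rival)
  diff <- abs(d$va - d$vb) * fraction
  worse <- ifelse(d$pol[names(d$va)] == "higher_better",
                  d$va - diff, d$va + diff)
  if (any(worse <= 0)) stop("decoy would have nonpositive values")
  worse
}

#' Construct a similarity (near-clone) decoy
#'
#' A near-clone of the rival of the favored alternative: `fraction` of the
#' absolute attribute difference is subtracted from the rival's value on
#' one dimension and added on the other, so all resulting pairwise
#' fractional distances stay below the comparison threshold and the
#' clone's differences are mostly unrecognized.
#'
#' @inheritParams make_attraction_decoy
#' @param fraction Perturbation fraction (default 0.02).
#' @param subtract_dim Dimension receiving the subtraction; defaults to
#'   the first declared dimension.
#' @return Named numeric vector of decoy attribute values.
#' @export
make_similarity_decoy <- function(problem, favored, rival,
                                  fraction = 0.02, subtract_dim = NULL) {
  d <- .decoy_prep(problem, favored, rival)
  if (length(d$va) != 2L)
    stop("similarity decoy construction requires exactly two dimensions")
  subtract_dim <- subtract_dim %||% names(d$va)[1L]
  if (!subtract_dim %in% names(d$va)) stop("unknown 'subtract_dim'")
  diff <- abs(d$va - d$vb) * fraction
  out <- d$vb
  out[subtract_dim] <- out[subtract_dim] - diff[subtract_dim]
  other <- setdiff(names(d$va), subtract_dim)
  out[other] <- out[other] + diff[other]
  if (any(out <= 0)) stop("decoy would have nonpositive values")
  out
}

#' Construct a compromise-maker
#'
#' Extends the line from the rival through the favored alternative by
#' `extrapolation` times the attribute difference, so the favored
#' alternative becomes intermediate between the rival and the new
#' extreme.
#'
#' @inheritParams make_attraction_decoy
#' @param extrapolation Positive extension factor (default 1: symmetric
#'   spacing).
#' @return Named numeric vector of decoy attribute values.
#' @export
make_compromise_decoy <- function(problem, favored, rival,
                                  extrapolation = 1.0) {
  if (extrapolation <= 0) stop("'extrapolation' must be > 0")
  d <- .decoy_prep(problem, favored, rival)
  out <- d$va + extrapolation * (d$va - d$vb)
  if (any(out <= 0)) stop("decoy would have nonpositive values")
  out
}

#' Long-term-memory sampling specification
#'
#' @param mean Named numeric vector of per-dimension means (typically the
#'   target alternative's attribute values).
#' @param sd Named numeric vector of per-dimension standard deviations
#'   (typically the absolute attribute difference between two focal
#'   alternatives).
#' @param correlation Common pairwise correlation between dimensions, in
#'   (-1, 1). Attribute dimensions usually trade off, so the default is
#'   -0.2.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return An object of class `mdbs_ltm_spec`.
#' @export
ltm_spec <- function(mean, sd, correlation = -0.2, n, seed) {
  stopifnot(length(mean) == length(sd), all(sd > 0),
            correlation > -1, correlation < 1, n >= 0)
  if (is.null(names(mean))) stop("'mean' must be named by dimension")
  structure(list(mean = mean, sd = sd[names(mean)],
                 correlation = correlation, n = n, seed = seed),
            class = "mdbs_ltm_spec")
}

#' Sample long-term-memory values into a context pool
#'
#' Seeded multivariate-normal draws with the spec's means, standard
#' deviations and common correlation, truncated to strictly positive
#' values by rejection resampling (draws with any nonpositive coordinate
#' are redrawn).
#'
#' @param spec An [ltm_spec()].
#' @return Named list of numeric vectors (one per dimension), usable as
#'   the `context` argument of [mdbs_problem()].
#' @export
sample_ltm <- function(spec) {
  stopifnot(inherits(spec, "mdbs_ltm_spec"))
  d <- length(spec$mean)
  if (spec$n == 0)
    return(stats::setNames(rep(list(numeric(0)), d), names(spec$mean)))
  if (any(stats::pnorm(0, spec$mean, spec$sd) > 0.99))
    stop("infeasible truncation: >99% of the mass is nonpositive on ",
         "dimension ",
         names(spec$mean)[which(stats::pnorm(0, spec$mean, spec$sd) > 0.99)][1L])
  Sigma <- diag(1 - spec$correlation, d) + spec$correlation
  Sigma <- Sigma * tcrossprod(spec$sd)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  out <- matrix(NA_real_, nrow = 0, ncol = d)
  guard <- 0L
  while (nrow(out) < spec$n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed to converge")
    draw <- MASS::mvrnorm(max(spec$n * 2L, 10L), mu = spec$mean,
                          Sigma = Sigma)
    draw <- matrix(draw, ncol = d)
    out <- rbind(out, draw[apply(draw > 0, 1L, all), , drop = FALSE])
  }
  out <- out[seq_len(spec$n), , drop = FALSE]
  stats::setNames(lapply(seq_len(d), function(j) out[, j]),
                  names(spec$mean))
}

#' Generate synthetic choice data
#'
#' Multinomial draws from the closed-form choice probabilities of a
#' problem: the data-generating companion of the inference module.
#'
#' @param problem An [mdbs_problem()].
#' @param params An [mdbs_params()] object.
#' @param n_trials Number of simulated choices.
#' @param seed Integer seed.
#' @return Named integer vector of choice counts summing to `n_trials`.
#' @export
generate_choice_data <- function(problem, params = mdbs_params(),
                                 n_trials, seed) {
  stopifnot(n_trials >= 1)
  p <- choice_probabilities(accumulation_rates(problem, params),
                            params$theta)$probabilities
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(as.integer(stats::rmultinom(1L, n_trials, p)), names(p))
}
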