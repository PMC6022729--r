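# Named context-effect scenarios: each returns an mdbs_scenario with a tidy
# choice table and named effect sizes.

.scenario_result <- function(name, table, effects, params, seed = NULL) {
  structure(list(name = name, table = table,
                 effects = unlist(effects), params = params, seed = seed),
            class = "mdbs_scenario")
}

#' @export
print.mdbs_scenario <- function(x, ...) {
  cat("MDbS scenario:", x$name, "\n")
  print(x$table, row.names = FALSE)
  if (length(x$effects)) {
    cat("effects:\n")
    print(round(x$effects, 4))
  }
  invisible(x)
}

.choice_row <- function(condition, dist, extra = NULL) {
  p <- dist$probabilities
  out <- data.frame(condition = condition, alternative = names(p),
                    probability = unname(p), stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

.closed <- function(problem, params) {
  choice_probabilities(accumulation_rates(problem, params), params$theta)
}

# the three canonical triads of a big-three fixture, plus the binary set
.big_three_sets <- function(fixture) {
  list(AB  = c("A", "B"), ABD = c("A", "B", "D"),
       ABC = c("A", "B", "C"), ABS = c("A", "B", "S"))
}

#' The big three context effects on one fixture
#'
#' Closed-form choice distributions for the binary set \{A, B\} and the
#' three triads with the attraction decoy D, the compromise-maker C, and
#' the near-clone S. Effect sizes are the A-minus-B probability difference
#' in each triad plus the regularity violation
#' `p(A | \{A,B,D\}) - p(A | \{A,B\})`.
#'
#' @param fixture A problem containing alternatives A, B, C, D, S
#'   (default: the packaged synthetic car market).
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario`.
#' @export
run_big_three <- function(fixture = load_fixture("synthetic_big_three"),
                          params = mdbs_params()) {
  need <- c("A", "B", "C", "D", "S")
  if (!all(need %in% rownames(fixture$values)))
    stop("fixture must contain alternatives ", paste(need, collapse = ", "))
  sets <- .big_three_sets(fixture)
  dists <- lapply(sets, function(ids)
    .closed(subset_problem(fixture, ids), params))
  tab <- do.call(rbind, Map(.choice_row, names(dists), dists))
  pA <- function(cond) dists[[cond]]$probabilities[["A"]]
  pB <- function(cond) dists[[cond]]$probabilities[["B"]]
  .scenario_result("big_three", tab,
    list(attraction = pA("ABD") - pB("ABD"),
         compromise = pA("ABC") - pB("ABC"),
         similarity = pA("ABS") - pB("ABS"),
         regularity_violation = pA("ABD") - pA("AB")),
    params)
}

#' Sweep the attraction decoy along the line from E to A
#'
#' Moves the decoy from the far point E toward coincidence with A and
#' reports the choice distribution at each position. The attraction effect
#' first strengthens as the decoy leaves E, then weakens as the decoy
#' approaches A: once the decoy sits within the comparison threshold
#' `beta0` of A, A's advantages over it are mostly unrecognized.
#'
#' @param fixture A problem with alternatives A, B and endpoint E.
#' @param n_steps Number of positions along the path (endpoints included).
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario`; effects include the peak position and a
#'   flag for the non-monotone profile.
#' @export
sweep_decoy <- function(fixture = load_fixture("synthetic_big_three"),
                        n_steps = 11, params = mdbs_params()) {
  stopifnot(n_steps >= 3)
  vA <- fixture$values["A", ]
  vE <- fixture$values["E", ]
  if (any(is.na(vA)) || any(is.na(vE)))
    stop("fixture must provide fully specified alternatives A and E")
  base <- subset_problem(fixture, c("A", "B"))
  ts <- seq(0, 1, length.out = n_steps)
  rows <- list(); effect <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    dec <- vE + ts[k] * (vA - vE)
    prob <- mdbs_problem(base$dimensions,
                         list(A = vA[!is.na(vA)],
                              B = base$values["B", ][!is.na(base$values["B", ])],
                              decoy = dec[!is.na(dec)]))
    d <- .closed(prob, params)
    rows[[k]] <- .choice_row(sprintf("t=%.2f", ts[k]), d,
                             data.frame(position = ts[k]))
    effect[k] <- d$probabilities[["A"]] - d$probabilities[["B"]]
  }
  peak <- which.max(effect)
  .scenario_result("decoy_distance", do.call(rbind, rows),
    list(peak_position = ts[peak],
         effect_at_peak = effect[peak],
         effect_at_far = effect[1L],
         effect_near_A = effect[n_steps - 1L],
         nonmonotone = as.numeric(peak > 1L && peak < n_steps)),
    params)
}

#' Range-widening versus frequency-widening decoy locations
#'
#' Compares two dominated decoys built from A: `R` worsens A on the
#' dimension where A is already at a disadvantage against B (widening that
#' dimension's range, so A's disadvantage is fractionally smaller and A
#' also gains wins against the decoy there), while `F` worsens A on A's
#' strong dimension. A attracts a higher decision probability with R in
#' the choice set than with F.
#'
#' @param fixture A problem containing fully specified A and B.
#' @param fraction Worsening fraction of the A-B attribute difference.
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario` with effect `location_gap =
#'   p(A|\{A,B,R\}) - p(A|\{A,B,F\})`.
#' @export
compare_decoy_locations <- function(fixture =
                                      load_fixture("synthetic_big_three"),
                                    fraction = 0.5,
                                    params = mdbs_params()) {
  stopifnot(fraction > 0)
  vA <- fixture$values["A", ]
  vB <- fixture$values["B", ]
  pol <- .polarities(fixture)
  dims <- names(vA)
  adv <- mapply(function(a, b, p) .beats(a, b, p), vA, vB, pol[dims])
  if (!any(adv) || all(adv))
    stop("A and B must trade off: each better on at least one dimension")
  worsen <- function(v, dim) {
    delta <- abs(vA[dim] - vB[dim]) * fraction
    v[dim] <- if (pol[[dim]] == "higher_better") v[dim] - delta
              else v[dim] + delta
    if (v[dim] <= 0) stop("decoy would have nonpositive value")
    v
  }
  weak_dim <- dims[!adv][1L]    # A disadvantaged here: R widens this range
  strong_dim <- dims[adv][1L]   # F worsens A's strong dimension
  dec_R <- worsen(vA, weak_dim)
  dec_F <- worsen(vA, strong_dim)
  mk <- function(dec, id) {
    alts <- list(A = vA[!is.na(vA)], B = vB[!is.na(vB)])
    alts[[id]] <- dec[!is.na(dec)]
    mdbs_problem(fixture$dimensions, alts)
  }
  dR <- .closed(mk(dec_R, "R"), params)
  dF <- .closed(mk(dec_F, "F"), params)
  tab <- rbind(.choice_row("ABR", dR), .choice_row("ABF", dF))
  .scenario_result("decoy_location", tab,
    list(p_A_with_R = dR$probabilities[["A"]],
         p_A_with_F = dF$probabilities[["A"]],
         location_gap = dR$probabilities[["A"]] - dF$probabilities[["A"]]),
    params)
}

#' Dilution of the big three effects by long-term-memory samples
#'
#' Familiarity with a choice domain is modeled as sampling attribute
#' values from long-term memory: a bivariate normal centered on A's values
#' with standard deviation equal to the absolute A-B attribute difference
#' and a common between-dimension correlation of -0.2. The sampled values
#' join working memory as context, diluting the within-choice-set
#' comparisons that drive the attraction, compromise, and similarity
#' effects; all three weaken as the sample count grows.
#'
#' @param fixture A big-three fixture.
#' @param sample_counts Integer vector of long-term-memory sample counts.
#' @param n_reps Seeded replications averaged per count.
#' @param seed Integer seed.
#' @param params An [mdbs_params()] object.
#' @param correlation Between-dimension correlation of the sampler.
#' @return An `mdbs_scenario`; the table holds the mean effect size per
#'   effect and sample count.
#' @export
dilute_with_ltm <- function(fixture = load_fixture("synthetic_big_three"),
                            sample_counts = c(0, 4, 16, 64),
                            n_reps = 500, seed = 1,
                            params = mdbs_params(),
                            correlation = -0.2) {
  vA <- fixture$values["A", ]
  vB <- fixture$values["B", ]
  sdv <- abs(vA - vB)
  sets <- list(attraction = c("A", "B", "D"),
               compromise = c("A", "B", "C"),
               similarity = c("A", "B", "S"))
  probs <- lapply(sets, function(ids) subset_problem(fixture, ids))
  rows <- list()
  for (s in sample_counts) {
    acc <- stats::setNames(numeric(length(sets)), names(sets))
    reps <- if (s == 0) 1L else n_reps
    for (rep in seq_len(reps)) {
      ctx <- if (s == 0) list() else
        sample_ltm(ltm_spec(vA, sdv, correlation, n = s,
                            seed = seed + 7919L * rep + s))
      for (eff in names(sets)) {
        pr <- probs[[eff]]
        pr2 <- mdbs_problem(pr$dimensions,
                            apply(pr$values, 1L, function(v) v[!is.na(v)],
                                  simplify = FALSE),
                            ctx)
        d <- .closed(pr2, params)
        acc[eff] <- acc[eff] +
          d$probabilities[["A"]] - d$probabilities[["B"]]
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(sample_count = s, effect = names(sets),
                 effect_size = unname(acc / reps),
                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  first <- tab[tab$sample_count == min(sample_counts), ]
  last <- tab[tab$sample_count == max(sample_counts), ]
  eff <- stats::setNames(last$effect_size - first$effect_size,
                         paste0("delta_", last$effect))
  .scenario_result("ltm_dilution", tab, as.list(eff), params, seed)
}

#' Big three effects under a fixed comparison horizon
#'
#' Effect sizes `p(A) - p(B)` for the three triads after a forced number
#' of comparison steps; with no comparisons every alternative is tied and
#' choice is uniform, and the effects strengthen as the horizon grows.
#'
#' @param fixture A big-three fixture.
#' @param horizons Integer vector of comparison horizons.
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario`.
#' @export
sweep_horizon <- function(fixture = load_fixture("synthetic_big_three"),
                          horizons = c(0, 1, 2, 5, 10),
                          params = mdbs_params()) {
  sets <- list(attraction = c("A", "B", "D"),
               compromise = c("A", "B", "C"),
               similarity = c("A", "B", "S"))
  rows <- list()
  for (eff in names(sets)) {
    pr <- subset_problem(fixture, sets[[eff]])
    for (h in horizons) {
      d <- fixed_horizon_choice(pr, params, h)
      rows[[length(rows) + 1L]] <-
        data.frame(effect = eff, horizon = h,
                   effect_size = d$probabilities[["A"]] -
                     d$probabilities[["B"]],
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  .scenario_result("horizon", tab, list(), params)
}

#' Big three effects across the similarity parameter
#'
#' Relative choice share of A over B, `p(A) / (p(A) + p(B))`, for each
#' triad over a grid of `alpha` values. Stronger similarity weighting
#' strengthens the attraction and compromise effects but weakens the
#' similarity effect.
#'
#' @param fixture A big-three fixture.
#' @param alpha_grid Grid of similarity decay values within `[0, 5]`.
#' @param params An [mdbs_params()] object supplying the other parameters.
#' @return An `mdbs_scenario` with per-effect share trends.
#' @export
sweep_alpha <- function(fixture = load_fixture("synthetic_big_three"),
                        alpha_grid = seq(0, 5, by = 0.5),
                        params = mdbs_params()) {
  stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 5))
  sets <- list(attraction = c("A", "B", "D"),
               compromise = c("A", "B", "C"),
               similarity = c("A", "B", "S"))
  rows <- list()
  for (eff in names(sets)) {
    pr <- subset_problem(fixture, sets[[eff]])
    for (a in alpha_grid) {
      pa <- mdbs_params(alpha = a, beta0 = params$beta0,
                        beta1 = params$beta1, theta = params$theta)
      d <- .closed(pr, pa)
      p <- d$probabilities
      rows[[length(rows) + 1L]] <-
        data.frame(effect = eff, alpha = a,
                   share_A = unname(p[["A"]] / (p[["A"]] + p[["B"]])),
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  slope <- vapply(names(sets), function(eff) {
    s <- tab[tab$effect == eff, ]
    unname(stats::coef(stats::lm(share_A ~ alpha, s))[2L])
  }, 0)
  .scenario_result("alpha_sweep", tab,
                   as.list(stats::setNames(slope,
                                           paste0("slope_", names(sets)))),
                   params)
}

#' Attribute balance with commensurable-dimension collapsing
#'
#' When two dimensions share a scale and unit (a commensurable group),
#' attribute values may be compared across dimensions: collapsing makes
#' every attribute value of every alternative an evaluation target whose
#' comparison partners are the other alternatives' values on the other
#' dimension(s) of the group, and evidence credits the owner of the
#' target value. The balanced alternative's identical ratings sit in the
#' middle of the collapsed value set, so it is evaluated most often and
#' wins enough comparisons to dominate -- the compromise mechanism in
#' disguise.
#'
#' @param fixture The rating-car fixture (alternatives K, L, Q, U, W on
#'   two commensurable 0-100 rating dimensions).
#' @param triads List of id triples to evaluate.
#' @param params An [mdbs_params()] object.
#' @param collapse If `FALSE`, returns the ordinary per-dimension
#'   distributions instead.
#' @return An `mdbs_scenario`; effects report the balanced alternative's
#'   probability per triad.
#' @export
attribute_balance <- function(fixture = load_fixture("balance_ratings"),
                              triads = list(c("K", "L", "Q"),
                                            c("L", "Q", "U"),
                                            c("Q", "U", "W")),
                              params = mdbs_params(),
                              collapse = TRUE) {
  grp <- fixture$dimensions$group
  if (collapse && (anyNA(grp) || length(unique(grp)) != 1L))
    stop("collapsing requires all dimensions to share a commensurable group")
  pol <- unique(fixture$dimensions$polarity)
  if (collapse && length(pol) != 1L)
    stop("commensurable dimensions must share a polarity")
  rows <- list(); eff <- list()
  for (ids in triads) {
    pr <- subset_problem(fixture, ids)
    if (collapse) {
      cells <- .cells(pr)
      # partner pool of a value on dimension d: the collapsed values on
      # the group's other dimensions (owner exclusion handles the rest)
      dims <- unique(cells$dim)
      pools <- stats::setNames(lapply(dims, function(d) {
        other <- cells[cells$dim != d, ]
        list(values = other$value, owner = other$owner)
      }), dims)
      eng <- .engine(cells, pools,
                     stats::setNames(rep(pol, length(dims)), dims), params)
      r <- stats::setNames(numeric(length(ids)), ids)
      contrib <- eng$eval_prob * eng$winsum
      for (k in seq_len(nrow(cells)))
        r[cells$owner[k]] <- r[cells$owner[k]] + contrib[k]
      d <- choice_probabilities(r, params$theta)
    } else {
      d <- .closed(pr, params)
    }
    cond <- paste(ids, collapse = "")
    rows[[cond]] <- .choice_row(cond, d)
    if ("Q" %in% ids) eff[[paste0("p_Q_", cond)]] <- d$probabilities[["Q"]]
  }
  .scenario_result("attribute_balance", do.call(rbind, rows), eff, params)
}

# background-contrast computers: price (USD, lower better) and RAM (KB,
# higher better). The focal pair trades off at $2.50/KB; the shallow prior
# pair at $0.22/KB sits above A's RAM and below A's price, the steep prior
# pair at $17.50/KB sits below A's RAM and below B's price.
.fx_background <- function() {
  dims <- rbind(dimension("price", "lower_better"),
                dimension("ram", "higher_better"))
  list(dims = dims,
       A = c(price = 1100, ram = 600), B = c(price = 600, ram = 400),
       Ap = c(price = 744, ram = 850), Bp = c(price = 700, ram = 650),
       App = c(price = 580, ram = 520), Bpp = c(price = 230, ram = 500))
}

#' Contextual-choice presets
#'
#' Four phenomena driven by context values in working memory:
#' \describe{
#'   \item{`background_contrast`}{A prior decision's attribute values stay
#'     in working memory. After a prior pair trading price for RAM at a
#'     shallow $0.22/KB rate (RAM-rich alternatives), the focal
#'     high-RAM computer A loses relative rank on RAM and B is favored;
#'     after a steep $17.50/KB prior pair (cheap alternatives), B loses
#'     relative rank on price and A is favored.}
#'   \item{`phantom_decoy`}{The values of an announced-unavailable
#'     alternative that slightly dominates A remain in working memory.
#'     Because they are most similar to A's values, A is evaluated most
#'     often; with a sufficiently large similarity decay `alpha` (default
#'     10 for this preset) A is chosen over B.}
#'   \item{`less_is_more`}{Adding a bundled attribute on which the target
#'     ranks poorly (its value loses to the context comparators on that
#'     dimension) strictly lowers the target's choice probability.}
#'   \item{`alignability`}{Attributes unique to one alternative have no
#'     comparators when their context pools are empty, so their values
#'     cannot be evaluated and cannot affect choice.}
#' }
#'
#' @param preset Scenario name (see above).
#' @param params An [mdbs_params()] object. The phantom preset replaces
#'   `alpha` by `alpha_phantom`.
#' @param alpha_phantom Similarity decay used for the phantom preset.
#' @return An `mdbs_scenario`.
#' @export
contextual_choice <- function(preset = c("background_contrast",
                                         "phantom_decoy", "less_is_more",
                                         "alignability"),
                              params = mdbs_params(),
                              alpha_phantom = 10) {
  preset <- match.arg(preset)
  switch(preset,
    background_contrast = {
      fx <- .fx_background()
      mk <- function(prior) {
        ctx <- list(price = unname(c(fx[[prior[1L]]]["price"],
                                     fx[[prior[2L]]]["price"])),
                    ram = unname(c(fx[[prior[1L]]]["ram"],
                                   fx[[prior[2L]]]["ram"])))
        mdbs_problem(fx$dims, list(A = fx$A, B = fx$B), ctx)
      }
      d_shallow <- .closed(mk(c("Ap", "Bp")), params)
      d_steep <- .closed(mk(c("App", "Bpp")), params)
      tab <- rbind(.choice_row("prior_0.22_per_KB", d_shallow),
                   .choice_row("prior_17.50_per_KB", d_steep))
      .scenario_result("background_contrast", tab,
        list(p_A_shallow_prior = d_shallow$probabilities[["A"]],
             p_A_steep_prior = d_steep$probabilities[["A"]],
             reversal = d_steep$probabilities[["A"]] -
               d_shallow$probabilities[["A"]]),
        params)
    },
    phantom_decoy = {
      # The phantom mechanism runs through evaluation frequency: the
      # unavailable alternative's values are most similar to A's, so A
      # is evaluated most often. Under similarity-weighted partner
      # selection that boost cancels exactly out of the rates, so this
      # preset uses the uniform partner rule, where evaluation frequency
      # is a separate factor.
      j1 <- load_fixture("j1_cars")
      pa <- mdbs_params(alpha = alpha_phantom, beta0 = params$beta0,
                        beta1 = params$beta1, theta = params$theta)
      vA <- j1$values["A", ]
      phantom <- vA * 1.05   # slightly dominates its similar neighbor A
      mk <- function(ctx) mdbs_problem(
        j1$dimensions[j1$dimensions$name %in% c("x", "y"), ],
        list(A = vA[c("x", "y")], B = j1$values["B", c("x", "y")]), ctx)
      rate_p <- accumulation_rates(mk(list(x = unname(phantom["x"]),
                                           y = unname(phantom["y"]))),
                                   pa, partner = "uniform")
      rate_0 <- accumulation_rates(mk(list()), pa, partner = "uniform")
      d <- choice_probabilities(rate_p, pa$theta)
      base <- choice_probabilities(rate_0, pa$theta)
      tab <- rbind(.choice_row("AB", base),
                   .choice_row("AB_plus_phantom", d))
      .scenario_result("phantom_decoy", tab,
        list(p_A_with_phantom = d$probabilities[["A"]],
             phantom_gap = d$probabilities[["A"]] - d$probabilities[["B"]],
             alpha_used = pa$alpha),
        pa)
    },
    less_is_more = {
      # Bundling a low-value attribute with the leading car diverts
      # evaluation to a cell that never wins, lowering A's accumulation
      # rate. Under the relative stopping rule the rate loss is shared
      # through normalization, so the untimed probabilities are
      # unchanged; the effect expresses itself whenever comparisons are
      # limited, so the choice probabilities are reported under a
      # moderate comparison horizon.
      cars <- load_fixture("synthetic_big_three")
      base <- subset_problem(cars, c("A", "B", "D"))
      dims <- rbind(base$dimensions, dimension("bundle", "higher_better"))
      vals <- apply(base$values, 1L, function(v) v[!is.na(v)],
                    simplify = FALSE)
      before <- mdbs_problem(dims, vals)
      vals$A <- c(vals$A, bundle = 1.0)
      # the bundled attribute ranks at the bottom of its context pool
      after <- mdbs_problem(dims, vals, list(bundle = c(2.0, 3.0)))
      horizon <- 5
      r0 <- accumulation_rates(before, params)
      r1 <- accumulation_rates(after, params)
      d0 <- fixed_horizon_choice(before, params, horizon)
      d1 <- fixed_horizon_choice(after, params, horizon)
      tab <- rbind(.choice_row("without_bundle", d0),
                   .choice_row("with_low_rank_bundle", d1))
      .scenario_result("less_is_more", tab,
        list(rate_A_before = r0[["A"]], rate_A_after = r1[["A"]],
             rate_drop = r0[["A"]] - r1[["A"]],
             p_A_before = d0$probabilities[["A"]],
             p_A_after = d1$probabilities[["A"]],
             drop = d0$probabilities[["A"]] - d1$probabilities[["A"]]),
        params)
    },
    alignability = {
      dims <- rbind(dimension("calories", "lower_better"),
                    dimension("kernel_size", "higher_better"),
                    dimension("sweetness", "higher_better"))
      mk <- function(kernel) mdbs_problem(dims,
        list(A = c(calories = 110, kernel_size = kernel),
             B = c(calories = 130, sweetness = 7)))
      d1 <- .closed(mk(3), params)
      d2 <- .closed(mk(9), params)
      tab <- rbind(.choice_row("unique_value_3", d1),
                   .choice_row("unique_value_9", d2))
      .scenario_result("alignability", tab,
        list(max_abs_change = max(abs(d1$probabilities -
                                        d2$probabilities))),
        params)
    })
}

#' Intransitive preference cycle from systematically missing values
#'
#' With the packaged three-alternative fixture, each pairwise choice set
#' shares exactly one present dimension and the shared-dimension loser has
#' accumulation rate exactly 0 (a missing value is never evaluated), so
#' each pairwise winner is chosen with probability 1 -- a deterministic
#' cycle -- while the ternary choice is near-indifferent.
#'
#' @param fixture The missing-value fixture.
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario` with three pairwise and one ternary
#'   distribution.
#' @export
intransitivity_suite <- function(fixture = load_fixture("intransitive"),
                                 params = mdbs_params()) {
  pairs <- list(VY = c("V", "Y"), YZ = c("Y", "Z"), ZV = c("Z", "V"))
  rows <- list()
  for (nm in names(pairs))
    rows[[nm]] <- .choice_row(nm,
      .closed(subset_problem(fixture, pairs[[nm]]), params))
  tern <- .closed(fixture, params)
  rows$VYZ <- .choice_row("VYZ", tern)
  tab <- do.call(rbind, rows)
  win <- function(nm, id)
    tab$probability[tab$condition == nm & tab$alternative == id]
  .scenario_result("intransitivity", tab,
    list(p_Y_given_VY = win("VY", "Y"),
         p_Z_given_YZ = win("YZ", "Z"),
         p_V_given_ZV = win("ZV", "V"),
         ternary_spread = max(tern$probabilities) -
           min(tern$probabilities)),
    params)
}

#' Perceptual focus: biased attention from clustered attribute values
#'
#' In the five-car set \{A, B, G, H, J\}, three cars cluster near A on the
#' first dimension, so A is compared there often and wins about half of
#' those comparisons, while on the second dimension A's value beats every
#' rival. The combination of comparison frequency and relative rank gives
#' A the highest decision probability.
#'
#' @param fixture The qualitative-comparison car set (contains A, B, G,
#'   H, J on dimensions x and y).
#' @param params An [mdbs_params()] object.
#' @return An `mdbs_scenario` whose effects include the three diagnostic
#'   relative ranks.
#' @export
perceptual_focus <- function(fixture = load_fixture("j1_cars"),
                             params = mdbs_params()) {
  ids <- c("A", "B", "G", "H", "J")
  pr <- subset_problem(fixture, ids)
  d <- .closed(pr, params)
  rivals <- function(id, dim) pr$values[setdiff(ids, id), dim]
  .scenario_result("perceptual_focus", .choice_row("ABGHJ", d),
    list(rank_A_x = relative_rank(pr$values["A", "x"], rivals("A", "x"),
                                  "higher_better"),
         rank_B_x = relative_rank(pr$values["B", "x"], rivals("B", "x"),
                                  "higher_better"),
         rank_A_y = relative_rank(pr$values["A", "y"], rivals("A", "y"),
                                  "higher_better"),
         p_A = d$probabilities[["A"]]),
    params)
}

#' Relative-rank and subjective-value curves over a value pool
#'
#' \describe{
#'   \item{`incidental`}{Curves against a small incidental pool
#'     (1, 2, 7): the rank of a target value tracks how many pool
#'     values it beats.}
#'   \item{`distribution`}{Curves against the positively skewed versus
#'     uniform monetary pools: value rises fastest in the dense region of
#'     the distribution, so the skewed pool yields the more concave
#'     curve.}
#'   \item{`loss_ranges`}{Subjective-value curves for gains drawn uniform
#'     0-40 and losses uniform 0-20 (one-unit grids). The narrower loss
#'     range makes a matched amount cover more of the loss distribution,
#'     so the loss curve is steeper -- loss aversion; reversing the
#'     ranges reverses the asymmetry.}
#' }
#'
#' @param preset One of `incidental`, `distribution`, `loss_ranges`.
#' @param grid Optional numeric grid of target values.
#' @param params An [mdbs_params()] object.
#' @param reverse For `loss_ranges`: swap the gain and loss ranges.
#' @return An `mdbs_scenario`; the table has columns `pool`, `value`,
#'   `relative_rank`, `subjective_value`.
#' @export
value_curve <- function(preset = c("incidental", "distribution",
                                   "loss_ranges"),
                        grid = NULL, params = mdbs_params(),
                        reverse = FALSE) {
  preset <- match.arg(preset)
  curve <- function(pool_name, pool, grid) {
    data.frame(pool = pool_name, value = grid,
               relative_rank = vapply(grid, relative_rank, 0, pool = pool,
                                      polarity = "higher_better"),
               subjective_value = vapply(grid, subjective_value, 0,
                                         pool = pool,
                                         polarity = "higher_better",
                                         params = params),
               stringsAsFactors = FALSE)
  }
  switch(preset,
    incidental = {
      grid <- grid %||% seq(0.5, 8, by = 0.5)
      tab <- curve("incidental", c(1, 2, 7), grid)
      .scenario_result("value_incidental", tab, list(), params)
    },
    distribution = {
      grid <- grid %||% seq(10, 500, by = 10)
      tab <- rbind(curve("skewed", load_fixture("money_skewed"), grid),
                   curve("uniform", load_fixture("money_uniform"), grid))
      rise <- function(pool, lo, hi) {
        s <- tab[tab$pool == pool, ]
        stats::approx(s$value, s$relative_rank, hi)$y -
          stats::approx(s$value, s$relative_rank, lo)$y
      }
      .scenario_result("value_distribution", tab,
        list(skewed_rise_below_100 = rise("skewed", 10, 100),
             skewed_rise_above_100 = rise("skewed", 100, 500),
             uniform_rise_below_100 = rise("uniform", 10, 100)),
        params)
    },
    loss_ranges = {
      gl <- load_fixture("gain_loss_ranges")
      if (reverse) gl <- list(gains = gl$losses, losses = gl$gains)
      grid <- grid %||% seq(1, 20, by = 1)
      tab <- rbind(curve("gains", gl$gains, grid),
                   curve("losses", gl$losses, grid))
      slope <- function(pool) {
        s <- tab[tab$pool == pool & tab$value <= 15 & tab$value >= 5, ]
        unname(stats::coef(stats::lm(subjective_value ~ value, s))[2L])
      }
      .scenario_result("value_loss", tab,
        list(gain_slope = slope("gains"), loss_slope = slope("losses"),
             loss_aversion = slope("losses") - slope("gains")),
        params)
    })
}

#' Names of the packaged scenarios
#' @return Character vector accepted by [run_scenario()].
#' @export
scenario_names <- function() {
  c("big_three", "decoy_distance", "decoy_location", "ltm_dilution",
    "horizon", "alpha_sweep", "attribute_balance", "background_contrast",
    "phantom_decoy", "less_is_more", "alignability", "intransitivity",
    "perceptual_focus", "value_incidental", "value_distribution",
    "value_loss")
}

#' Run a scenario by name
#'
#' @param name One of [scenario_names()].
#' @param params An [mdbs_params()] object.
#' @param seed Seed for stochastic scenarios.
#' @param ... Further arguments passed to the scenario function (e.g.
#'   `n_reps` for `ltm_dilution`, `horizons` for `horizon`).
#' @return An `mdbs_scenario`.
#' @export
run_scenario <- function(name, params = mdbs_params(), seed = 1, ...) {
  switch(name,
    big_three = run_big_three(params = params, ...),
    decoy_distance = sweep_decoy(params = params, ...),
    decoy_location = compare_decoy_locations(params = params, ...),
    ltm_dilution = dilute_with_ltm(params = params, seed = seed, ...),
    horizon = sweep_horizon(params = params, ...),
    alpha_sweep = sweep_alpha(params = params, ...),
    attribute_balance = attribute_balance(params = params),
    background_contrast = contextual_choice("background_contrast", params),
    phantom_decoy = contextual_choice("phantom_decoy", params),
    less_is_more = contextual_choice("less_is_more", params),
    alignability = contextual_choice("alignability", params),
    intransitivity = intransitivity_suite(params = params),
    perceptual_focus = perceptual_focus(params = params),
    value_incidental = value_curve("incidental", params = params),
    value_distribution = value_curve("distribution", params = params),
    value_loss = value_curve("loss_ranges", params = params),
    stop("unknown scenario '", name, "'; see scenario_names()"))
}
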