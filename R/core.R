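#' Fractional advantage distance between two attribute values
#'
#' The perceived distance between a target and a comparator value is the
#' absolute difference expressed as a fraction of the comparator:
#' `|target - comparator| / |comparator|`. It is asymmetric in its
#' arguments and behaves pathologically as the comparator approaches zero,
#' which is why all attribute magnitudes are required to be strictly
#' positive.
#'
#' @param target_value,comparator_value Strictly positive magnitudes.
#'   `comparator_value` may be a vector.
#' @return Nonnegative fractional distance(s).
#' @examples
#' advantage_distance(110, 100)  # 0.10
#' @export
advantage_distance <- function(target_value, comparator_value) {
  stopifnot(is.numeric(target_value), is.numeric(comparator_value))
  if (any(!is.finite(target_value)) || any(!is.finite(comparator_value)))
    stop("values must be finite")
  if (any(target_value <= 0) || any(comparator_value <= 0))
    stop("attribute values must be strictly positive")
  abs(target_value - comparator_value) / abs(comparator_value)
}

# strict preference under a dimension's polarity; ties are not preferred
.beats <- function(a, b, polarity) {
  if (polarity == "higher_better") a > b else a < b
}

#' Soft ordinal comparison: probability the target wins
#'
#' A comparison favors the target only if it is strictly preferable under
#' the dimension's polarity; the probability is then a logistic function of
#' the fractional advantage, `plogis(beta1 * (D - beta0))`. Any
#' disadvantage or exact tie wins with probability 0. At the default
#' parameters a 10% advantage is favored with probability .50 and a 20%
#' advantage with probability > .99.
#'
#' @param target_value Strictly positive target magnitude (scalar).
#' @param comparator_value Strictly positive comparator magnitude(s).
#' @param polarity `"higher_better"` or `"lower_better"`.
#' @param params An [mdbs_params()] object.
#' @return Win probability, vectorized over `comparator_value`.
#' @examples
#' win_probability(110, 100, "higher_better")  # 0.5
#' win_probability(120, 100, "higher_better")  # > .99
#' win_probability(90, 100, "higher_better")   # 0: disadvantage
#' @export
win_probability <- function(target_value, comparator_value,
                            polarity = c("higher_better", "lower_better"),
                            params = mdbs_params()) {
  polarity <- match.arg(polarity)
  params <- as_mdbs_params(params)
  d <- advantage_distance(target_value, comparator_value)
  p <- stats::plogis(params$beta1 * (d - params$beta0))
  ifelse(.beats(target_value, comparator_value, polarity), p, 0)
}

# ---- generalized cell engine -------------------------------------------
#
# The engine operates on "cells": one row per (owner, dimension, value)
# that can be a target of evaluation. Pools map each dimension to its
# working-memory values and their owners (NA owner = context value).
# Comparators for a cell are all pool entries not owned by the cell's
# owner; context values are always comparators. This generalization lets
# commensurable dimensions share a single pooled comparison space.

.engine <- function(cells, pools, polarities, params) {
  params <- as_mdbs_params(params)
  n <- nrow(cells)
  w <- numeric(n)           # unnormalized evaluation weight per cell
  winsum <- numeric(n)      # partner-weighted win probability per cell
  partners <- vector("list", n)
  for (k in seq_len(n)) {
    pool <- pools[[cells$dim[k]]]
    keep <- is.na(pool$owner) | pool$owner != cells$owner[k]
    cvals <- pool$values[keep]
    if (!length(cvals)) {
      partners[[k]] <- data.frame(value = numeric(0), owner = character(0),
                                  probability = numeric(0))
      next
    }
    d <- advantage_distance(cells$value[k], cvals)
    sim <- exp(-params$alpha * d)
    w[k] <- sum(sim)
    pw <- sim / sum(sim)
    wp <- win_probability(cells$value[k], cvals, polarities[[cells$dim[k]]],
                          params)
    winsum[k] <- sum(pw * wp)
    partners[[k]] <- data.frame(value = cvals, owner = pool$owner[keep],
                                probability = pw, win = wp,
                                stringsAsFactors = FALSE)
  }
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate problem: no evaluation target has any comparator")
  list(cells = cells, eval_prob = w / tot, winsum = winsum,
       partners = partners)
}

.problem_engine <- function(problem, params) {
  stopifnot(inherits(problem, "mdbs_problem"))
  dims <- problem$dimensions$name
  pools <- stats::setNames(lapply(dims, .pool, problem = problem), dims)
  .engine(.cells(problem), pools, .polarities(problem), params)
}

#' Evaluation distribution over (alternative, dimension) cells
#'
#' The probability that a given alternative's value on a given dimension is
#' the next target of evaluation is proportional to its summed similarity
#' `exp(-alpha * D)` to the other attribute values in working memory on
#' that dimension. Context values contribute similarity but are never
#' themselves targets; a missing value, or a dimension with no comparators,
#' has evaluation probability 0.
#'
#' @param problem An [mdbs_problem()].
#' @param params An [mdbs_params()] object.
#' @return A matrix (alternatives x dimensions) of probabilities summing
#'   to 1.
#' @export
evaluation_distribution <- function(problem, params = mdbs_params()) {
  eng <- .problem_engine(problem, params)
  out <- matrix(0, nrow = nrow(problem$values), ncol = ncol(problem$values),
                dimnames = dimnames(problem$values))
  for (k in seq_len(nrow(eng$cells)))
    out[eng$cells$owner[k], eng$cells$dim[k]] <- eng$eval_prob[k]
  out
}

#' Partner-selection distribution for one target cell
#'
#' Given that an alternative is being evaluated on a dimension, the
#' comparison partner is drawn from the other working-memory values on that
#' dimension with probability proportional to `exp(-alpha * D)`: more
#' similar values are more likely partners, mirroring the
#' similarity-weighted selection of evaluation targets.
#'
#' @param alternative Id of the alternative under evaluation.
#' @param dim Dimension name.
#' @inheritParams evaluation_distribution
#' @return A data frame with columns `value`, `owner` (`NA` for context
#'   values), `probability` (summing to 1) and `win` (the soft win
#'   probability of the target against that partner).
#' @export
partner_distribution <- function(alternative, dim, problem,
                                 params = mdbs_params()) {
  eng <- .problem_engine(problem, params)
  k <- which(eng$cells$owner == alternative & eng$cells$dim == dim)
  if (!length(k))
    stop("no such target cell: alternative '", alternative,
         "' has no value on dimension '", dim, "'")
  pd <- eng$partners[[k]]
  if (!nrow(pd))
    stop("empty comparator pool for alternative '", alternative,
         "' on dimension '", dim, "'")
  pd
}

#' Evidence accumulation rates
#'
#' The per-comparison-step probability that each choosable alternative
#' gains one evidence unit: the evaluation probability of each of its cells
#' times the partner-weighted probability that the cell's value wins the
#' comparison. Winning against a context value counts as evidence; context
#' values never accrue evidence themselves.
#'
#' @inheritParams evaluation_distribution
#' @param partner Partner-selection rule inside a comparison:
#'   `"similarity"` (the default; probability proportional to
#'   `exp(-alpha * D)`, mirroring the target-selection weighting) or
#'   `"uniform"` (each comparator equally likely). Under the similarity
#'   rule the evaluation weight of a cell cancels exactly against the
#'   partner normalization, so the rate reduces to a sum of pairwise
#'   similarity-weighted wins; the uniform rule keeps evaluation
#'   frequency and win probability as separate factors. The uniform
#'   variant exists for mechanisms that run through evaluation frequency
#'   alone (see [contextual_choice()] preset `phantom_decoy`).
#' @return A named numeric vector (class `mdbs_rates`) with one entry per
#'   alternative, each in `[0, 1]`, summing to at most 1.
#' @examples
#' p <- load_fixture("synthetic_big_three")
#' accumulation_rates(subset_problem(p, c("A", "B")), mdbs_params())
#' @export
accumulation_rates <- function(problem, params = mdbs_params(),
                               partner = c("similarity", "uniform")) {
  partner <- match.arg(partner)
  eng <- .problem_engine(problem, params)
  ids <- rownames(problem$values)
  r <- stats::setNames(numeric(length(ids)), ids)
  winsum <- if (partner == "similarity") eng$winsum else
    vapply(eng$partners, function(pd) {
      if (nrow(pd)) mean(pd$win) else 0
    }, 0)
  contrib <- eng$eval_prob * winsum
  for (k in seq_len(nrow(eng$cells)))
    r[eng$cells$owner[k]] <- r[eng$cells$owner[k]] + contrib[k]
  structure(r, class = "mdbs_rates")
}

#' @export
print.mdbs_rates <- function(x, ...) {
  cat("MDbS accumulation rates (per comparison step):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Relative rank of a value within a pool
#'
#' The proportion of pool values that the target strictly beats under the
#' dimension's preference polarity. Ties count as not beaten. The pool is
#' taken as given: if the target itself is a member of the pool being
#' ranked against, include it (it counts in the denominator and, being a
#' tie, is never beaten).
#'
#' @param target_value Target magnitude.
#' @param pool Numeric vector of pool values (nonempty).
#' @param polarity `"higher_better"` or `"lower_better"`.
#' @return Proportion in `[0, 1]`.
#' @examples
#' relative_rank(5, c(1, 2, 7), "higher_better")  # 2/3
#' @export
relative_rank <- function(target_value,
                          pool,
                          polarity = c("higher_better", "lower_better")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(target_value), length(target_value) == 1L)
  if (!length(pool)) stop("comparison pool is empty")
  mean(.beats(target_value, pool, polarity))
}

#' Subjective value of an attribute value within a pool
#'
#' The single-cell accumulation rate of the target: the similarity-weighted
#' (partner-probability-weighted) mean of the soft win probability over the
#' comparison pool. With `alpha = 0` and all pairwise fractional distances
#' well above `beta0`, this reduces to the relative rank.
#'
#' @inheritParams relative_rank
#' @param params An [mdbs_params()] object.
#' @return Nonnegative real in `[0, 1]`.
#' @export
subjective_value <- function(target_value, pool,
                             polarity = c("higher_better", "lower_better"),
                             params = mdbs_params()) {
  polarity <- match.arg(polarity)
  params <- as_mdbs_params(params)
  if (!length(pool)) stop("comparison pool is empty")
  d <- advantage_distance(target_value, pool)
  w <- exp(-params$alpha * d)
  sum(w / sum(w) * win_probability(target_value, pool, polarity, params))
}

#' Enumerate within-choice-set pairwise comparisons
#'
#' All ordered pairs of distinct choosable alternatives crossed with the
#' dimensions on which both have a present value: the rows of the
#' comparison table for a choice set (e.g. 3 alternatives x 2 shared
#' dimensions gives 12 comparisons).
#'
#' @param problem An [mdbs_problem()].
#' @return A data frame with columns `target`, `comparator`, `dim`.
#' @export
enumerate_comparisons <- function(problem) {
  stopifnot(inherits(problem, "mdbs_problem"))
  ids <- rownames(problem$values)
  dims <- colnames(problem$values)
  out <- expand.grid(target = ids, comparator = ids, dim = dims,
                     stringsAsFactors = FALSE)
  out <- out[out$target != out$comparator, ]
  keep <- mapply(function(t, c, d) {
    !is.na(problem$values[t, d]) && !is.na(problem$values[c, d])
  }, out$target, out$comparator, out$dim)
  out <- out[keep, c("target", "comparator", "dim")]
  out <- out[order(out$target, out$comparator, out$dim), ]
  rownames(out) <- NULL
  out
}
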