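#' Relative stopping rule
#'
#' A decision is made when the difference between the maximum and the mean
#' of the evidence counts reaches the threshold `theta`. With `theta`
#' at most `1 - 1/n` (n alternatives), the very first evidence unit stops
#' the race, because a single unit lifts the leader `1 - 1/n` above the
#' mean.
#'
#' @param counts Nonnegative integer evidence counts, one per alternative.
#' @param theta Stopping threshold (> 0).
#' @return Logical scalar.
#' @examples
#' is_stopped(c(1, 0, 0), 0.1)   # TRUE: difference 2/3
#' is_stopped(c(1, 0), 0.52)     # FALSE: difference 0.5
#' @export
is_stopped <- function(counts, theta) {
  stopifnot(is.numeric(counts), length(counts) >= 1L, theta > 0)
  max(counts) - mean(counts) >= theta - 1e-12
}

.check_rates <- function(rates) {
  r <- unclass(rates)
  stopifnot(is.numeric(r), length(r) >= 2L)
  if (any(r < -1e-12) || any(r > 1 + 1e-12))
    stop("rates must lie in [0, 1]")
  r <- pmin(pmax(r, 0), 1)
  if (sum(r) > 1 + 1e-9) stop("rates must sum to at most 1")
  if (is.null(names(r))) names(r) <- paste0("alt", seq_along(r))
  r
}

#' Choice probabilities under the relative stopping rule
#'
#' Absorption probabilities of the unit-increment random walk over evidence
#' counts: at each comparison step alternative `i` gains one unit with
#' probability `rates[i]` (with probability `1 - sum(rates)` nothing
#' happens), and the walk stops per [is_stopped()]. Null steps rescale time
#' but not absorption, so the walk is solved on evidence units only. When
#' `theta <= 1 - 1/n` the first unit absorbs and the probabilities reduce
#' exactly to `rates / sum(rates)`; for larger `theta` the general
#' absorbing walk is solved by forward propagation over count states,
#' truncated at `t_max` total units (residual mass must fall below
#' `tol`).
#'
#' @param rates A rate vector, e.g. from [accumulation_rates()].
#' @param theta Stopping threshold.
#' @param t_max Truncation level for the general solver (total evidence
#'   units).
#' @param tol Maximum residual (unabsorbed) probability mass tolerated at
#'   `t_max`.
#' @return An object of class `mdbs_choice`: list with `probabilities`
#'   (named, summing to 1), `expected_comparisons`, and `method =
#'   "closed_form"`.
#' @examples
#' choice_probabilities(c(A = 0.3, B = 0.1, C = 0.1), theta = 0.1)
#' @export
choice_probabilities <- function(rates, theta = 0.1, t_max = 200,
                                 tol = 1e-12) {
  r <- .check_rates(rates)
  n <- length(r)
  total <- sum(r)
  if (total <= 0)
    stop("no decision possible: all accumulation rates are zero ",
         "(no alternative holds a recognizable advantage)")
  if (theta <= (1 - 1 / n) + 1e-12) {
    p <- r / total
    ec <- 1 / total
  } else {
    sol <- .absorbing_walk(r / total, theta, n, t_max, tol)
    p <- stats::setNames(sol$absorb, names(r))
    ec <- sol$expected_units / total
  }
  structure(list(probabilities = p, expected_comparisons = ec,
                 method = "closed_form"),
            class = "mdbs_choice")
}

# forward propagation of the conditioned walk (one unit per step, step
# probabilities q); returns absorption mass per alternative and the
# expected number of evidence units until absorption
.absorbing_walk <- function(q, theta, n, t_max, tol) {
  absorb <- numeric(n)
  expected_units <- 0
  states <- matrix(0L, nrow = 1L, ncol = n)
  mass <- 1
  for (t in seq_len(t_max)) {
    expected_units <- expected_units + sum(mass)
    key <- new.env(hash = TRUE, parent = emptyenv())
    new_states <- list(); new_mass <- numeric(0)
    for (s in seq_along(mass)) {
      cnt <- states[s, ]
      for (i in seq_len(n)) {
        if (q[i] <= 0) next
        m <- mass[s] * q[i]
        nxt <- cnt
        nxt[i] <- nxt[i] + 1L
        if (max(nxt) - mean(nxt) >= theta - 1e-12) {
          # absorbing increments always create a unique strict maximum
          absorb[i] <- absorb[i] + m
        } else {
          k <- paste(nxt, collapse = ",")
          j <- key[[k]]
          if (is.null(j)) {
            new_states[[length(new_states) + 1L]] <- nxt
            new_mass <- c(new_mass, m)
            key[[k]] <- length(new_mass)
          } else {
            new_mass[j] <- new_mass[j] + m
          }
        }
      }
    }
    if (!length(new_mass)) {
      return(list(absorb = absorb, expected_units = expected_units))
    }
    states <- do.call(rbind, new_states)
    mass <- new_mass
  }
  if (sum(mass) > tol)
    stop("absorbing-walk truncation at ", t_max, " units leaves residual ",
         "mass ", signif(sum(mass), 3), " > tol; increase t_max")
  list(absorb = absorb / sum(absorb), expected_units = expected_units)
}

#' Expected number of comparison steps before a decision
#'
#' Counts all comparison steps, including those on which no evidence
#' accrues. For `theta <= 1 - 1/n` this is the geometric waiting time
#' `1 / sum(rates)` for the first evidence unit (e.g. 2.5 comparisons at a
#' total rate of 0.4).
#'
#' @inheritParams choice_probabilities
#' @return Positive real.
#' @export
expected_comparisons <- function(rates, theta = 0.1, t_max = 200,
                                 tol = 1e-12) {
  choice_probabilities(rates, theta, t_max, tol)$expected_comparisons
}

#' @export
print.mdbs_choice <- function(x, ...) {
  cat("MDbS choice distribution (", x$method, "):\n", sep = "")
  print(round(x$probabilities, 4))
  cat("expected comparisons:", round(x$expected_comparisons, 3), "\n")
  invisible(x)
}

#' Simulate the comparison-and-accumulation process
#'
#' Seeded Monte Carlo trials of the full process: at each comparison step a
#' target cell is drawn from the evaluation distribution, a partner from
#' the partner distribution, and the target wins (one evidence unit for its
#' alternative) with the soft comparison probability; the trial stops per
#' [is_stopped()]. Because the three draws compound to an increment of
#' alternative `i` with probability `rates[i]`, trials are advanced
#' vectorized on the rate vector.
#'
#' @param problem An [mdbs_problem()].
#' @param params An [mdbs_params()] object.
#' @param n_trials Number of independent trials (>= 1).
#' @param seed Integer seed; required for reproducibility.
#' @param max_steps Guard against non-decision (default 1e5 steps/trial).
#' @return An object of class `mdbs_simulation`: list with `n_trials`,
#'   `wins` (named counts summing to `n_trials`), `comparisons` (per-trial
#'   step counts), `seed`.
#' @export
simulate_choices <- function(problem, params = mdbs_params(), n_trials,
                             seed, max_steps = 1e5) {
  stopifnot(n_trials >= 1)
  if (missing(seed)) stop("'seed' is required")
  params <- as_mdbs_params(params)
  r <- unclass(accumulation_rates(problem, params))
  if (sum(r) <= 0)
    stop("non-decision: all accumulation rates are zero for alternatives ",
         paste(names(r), collapse = ", "),
         " (no alternative ever wins a comparison)")
  n <- length(r)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  counts <- matrix(0L, nrow = n_trials, ncol = n)
  steps <- integer(n_trials)
  winner <- integer(n_trials)
  active <- seq_len(n_trials)
  probs <- c(1 - sum(r), r)  # outcome 1 = null step
  step <- 0L
  while (length(active)) {
    step <- step + 1L
    if (step > max_steps)
      stop("non-decision: ", length(active), " trial(s) undecided after ",
           max_steps, " steps (rates: ",
           paste(signif(r, 4), collapse = ", "), ")")
    out <- sample.int(n + 1L, length(active), replace = TRUE, prob = probs)
    steps[active] <- steps[active] + 1L
    hit <- out > 1L
    if (any(hit)) {
      ai <- active[hit]
      alt <- out[hit] - 1L
      counts[cbind(ai, alt)] <- counts[cbind(ai, alt)] + 1L
      cm <- counts[ai, , drop = FALSE]
      stopped <- (apply(cm, 1L, max) - rowMeans(cm)) >= params$theta - 1e-12
      if (any(stopped)) {
        done <- ai[stopped]
        winner[done] <- alt[stopped]  # absorbing unit is the strict max
        active <- setdiff(active, done)
      }
    }
  }
  wins <- tabulate(winner, nbins = n)
  structure(list(n_trials = n_trials,
                 wins = stats::setNames(wins, names(r)),
                 comparisons = steps, seed = seed),
            class = "mdbs_simulation")
}

#' @export
print.mdbs_simulation <- function(x, ...) {
  cat("MDbS simulation:", x$n_trials, "trials (seed", x$seed, ")\n")
  print(round(x$wins / x$n_trials, 4))
  cat("mean comparisons:", round(mean(x$comparisons), 3), "\n")
  invisible(x)
}

#' Choice under a fixed comparison horizon (time pressure)
#'
#' Exact distribution of the chosen alternative when the process is forced
#' to stop after a fixed number of comparison steps (null steps included):
#' dynamic programming over evidence-count vectors, with uniform
#' tie-breaking among the evidence maxima. Horizons above `dp_cap` fall
#' back to seeded simulation with a message.
#'
#' @param problem An [mdbs_problem()].
#' @param params An [mdbs_params()] object.
#' @param n_comparisons Nonnegative horizon.
#' @param dp_cap Largest horizon solved exactly (default 25).
#' @param n_sim Trials used beyond `dp_cap`.
#' @param seed Seed used beyond `dp_cap`.
#' @return An `mdbs_choice` object with method `"fixed_horizon"` (or
#'   `"fixed_horizon_sim"`).
#' @export
fixed_horizon_choice <- function(problem, params = mdbs_params(),
                                 n_comparisons, dp_cap = 25,
                                 n_sim = 1e5, seed = 1) {
  stopifnot(n_comparisons >= 0)
  params <- as_mdbs_params(params)
  r <- unclass(accumulation_rates(problem, params))
  n <- length(r)
  if (n_comparisons > dp_cap) {
    message("horizon ", n_comparisons, " above exact-DP cap ", dp_cap,
            "; falling back to simulation")
    return(.horizon_sim(r, n_comparisons, n_sim, seed))
  }
  step_p <- c(1 - sum(r), r)
  states <- matrix(0L, nrow = 1L, ncol = n)
  mass <- 1
  for (s in seq_len(n_comparisons)) {
    key <- new.env(hash = TRUE, parent = emptyenv())
    new_states <- list(); new_mass <- numeric(0)
    add <- function(cnt, m) {
      k <- paste(cnt, collapse = ",")
      j <- key[[k]]
      if (is.null(j)) {
        new_states[[length(new_states) + 1L]] <<- cnt
        new_mass <<- c(new_mass, m)
        key[[k]] <<- length(new_mass)
      } else new_mass[j] <<- new_mass[j] + m
    }
    for (st in seq_along(mass)) {
      cnt <- states[st, ]
      if (step_p[1L] > 0) add(cnt, mass[st] * step_p[1L])
      for (i in seq_len(n)) {
        if (step_p[i + 1L] <= 0) next
        nxt <- cnt
        nxt[i] <- nxt[i] + 1L
        add(nxt, mass[st] * step_p[i + 1L])
      }
    }
    states <- do.call(rbind, new_states)
    mass <- new_mass
  }
  p <- numeric(n)
  for (st in seq_along(mass)) {
    cnt <- states[st, ]
    top <- which(cnt == max(cnt))
    p[top] <- p[top] + mass[st] / length(top)
  }
  structure(list(probabilities = stats::setNames(p, names(r)),
                 expected_comparisons = n_comparisons,
                 method = "fixed_horizon"),
            class = "mdbs_choice")
}

.horizon_sim <- function(r, horizon, n_sim, seed) {
  n <- length(r)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- matrix(0L, nrow = n_sim, ncol = n)
  probs <- c(1 - sum(r), r)
  for (s in seq_len(horizon)) {
    out <- sample.int(n + 1L, n_sim, replace = TRUE, prob = probs)
    hit <- out > 1L
    if (any(hit))
      counts[cbind(which(hit), out[hit] - 1L)] <-
        counts[cbind(which(hit), out[hit] - 1L)] + 1L
  }
  p <- numeric(n)
  mx <- apply(counts, 1L, max)
  for (i in seq_len(n_sim)) {
    top <- which(counts[i, ] == mx[i])
    p[top] <- p[top] + 1 / length(top)
  }
  structure(list(probabilities = stats::setNames(p / n_sim, names(r)),
                 expected_comparisons = horizon,
                 method = "fixed_horizon_sim"),
            class = "mdbs_choice")
}

#' Predicted comparison frequency per alternative pair
#'
#' Expected number of comparisons between each unordered pair of
#' alternatives before a decision: the per-step probability of selecting
#' the pair (evaluation probability of one member times the partner
#' probability of the other, summed over dimensions and averaged over the
#' direction of comparison) times the expected number of comparison steps.
#' Comparisons against context values are reported in a `(context)` row,
#' so the counts sum to the expected number of comparisons.
#'
#' @param problem An [mdbs_problem()].
#' @param params An [mdbs_params()] object.
#' @param theta Stopping threshold used for the expected step count;
#'   defaults to the value in `params`.
#' @return A data frame with columns `a`, `b`, `expected_count`.
#' @export
comparison_frequency_prediction <- function(problem,
                                            params = mdbs_params(),
                                            theta = params$theta) {
  params <- as_mdbs_params(params)
  eng <- .problem_engine(problem, params)
  rates <- accumulation_rates(problem, params)
  ec <- expected_comparisons(rates, theta)
  ids <- rownames(problem$values)
  pairs <- list()
  addp <- function(a, b, p) {
    nm <- if (is.na(b)) paste(a, "(context)", sep = "|")
          else paste(sort(c(a, b)), collapse = "|")
    pairs[[nm]] <<- (pairs[[nm]] %||% 0) + p
  }
  for (k in seq_len(nrow(eng$cells))) {
    pd <- eng$partners[[k]]
    if (!nrow(pd)) next
    for (j in seq_len(nrow(pd)))
      addp(eng$cells$owner[k], pd$owner[j],
           eng$eval_prob[k] * pd$probability[j])
  }
  nm <- names(pairs)
  ab <- strsplit(nm, "|", fixed = TRUE)
  data.frame(a = vapply(ab, `[`, "", 1L),
             b = vapply(ab, `[`, "", 2L),
             expected_count = unlist(pairs, use.names = FALSE) * ec,
             row.names = NULL, stringsAsFactors = FALSE)
}
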