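# Shared fixtures and independent oracles for the test suite.

two_car_problem <- function() {
  mdbs_problem(
    dimensions = rbind(dimension("price", "lower_better"),
                       dimension("mpg", "higher_better")),
    alternatives = list(A = c(price = 24000, mpg = 32),
                        B = c(price = 16000, mpg = 24)))
}

rescale_dim <- function(problem, dim, c) {
  alts <- apply(problem$values, 1L, function(v) {
    v[dim] <- v[dim] * c
    v[!is.na(v)]
  }, simplify = FALSE)
  ctx <- problem$context
  if (!is.null(ctx[[dim]])) ctx[[dim]] <- ctx[[dim]] * c
  mdbs_problem(problem$dimensions, alts, ctx)
}

# random, non-degenerate decision problem for property tests
random_problem <- function(seed, with_context = FALSE) {
  set.seed(seed)
  repeat {
    n_alt <- sample(2:4, 1)
    n_dim <- sample(2:3, 1)
    dims <- do.call(rbind, lapply(seq_len(n_dim), function(j)
      dimension(paste0("d", j),
                sample(c("higher_better", "lower_better"), 1))))
    alts <- lapply(seq_len(n_alt), function(i)
      stats::setNames(round(stats::runif(n_dim, 1, 100), 2), dims$name))
    names(alts) <- paste0("alt", seq_len(n_alt))
    ctx <- list()
    if (with_context && stats::runif(1) < 0.7) {
      d <- sample(dims$name, 1)
      ctx[[d]] <- round(stats::runif(sample(1:3, 1), 1, 100), 2)
    }
    pr <- mdbs_problem(dims, alts, ctx)
    ok <- tryCatch(sum(accumulation_rates(pr)) > 1e-6,
                   error = function(e) FALSE)
    if (ok) return(pr)
  }
}

# Independent accumulation-rate oracle: a direct, loop-level transcription
# of the evaluation, partner and win definitions, sharing no code with the
# package engine.
brute_rates <- function(problem, params) {
  ids <- rownames(problem$values)
  dims <- problem$dimensions$name
  pol <- stats::setNames(problem$dimensions$polarity, dims)
  # working-memory pool per dimension with owners
  pool <- lapply(dims, function(d) {
    v <- problem$values[, d]
    owners <- ids[!is.na(v)]
    vals <- unname(v[!is.na(v)])
    cv <- problem$context[[d]]
    if (!is.null(cv)) {
      vals <- c(vals, cv)
      owners <- c(owners, rep(NA, length(cv)))
    }
    list(v = vals, o = owners)
  })
  names(pool) <- dims
  win <- function(t, c, p) {
    if ((p == "higher_better" && t > c) || (p == "lower_better" && t < c))
      stats::plogis(params$beta1 * (abs(t - c) / abs(c) - params$beta0))
    else 0
  }
  weight <- matrix(0, length(ids), length(dims),
                   dimnames = list(ids, dims))
  winsum <- weight
  for (a in ids) for (d in dims) {
    ta <- problem$values[a, d]
    if (is.na(ta)) next
    keep <- is.na(pool[[d]]$o) | pool[[d]]$o != a
    comp <- pool[[d]]$v[keep]
    if (!length(comp)) next
    sim <- exp(-params$alpha * abs(ta - comp) / abs(comp))
    weight[a, d] <- sum(sim)
    wp <- vapply(comp, function(x) win(ta, x, pol[[d]]), 0)
    winsum[a, d] <- sum(sim / sum(sim) * wp)
  }
  tot <- sum(weight)
  rowSums(weight / tot * winsum)
}
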