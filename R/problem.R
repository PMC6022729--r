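#' Describe an attribute dimension
#'
#' @param name Dimension label, unique within a problem.
#' @param polarity `"higher_better"` (e.g. fuel efficiency) or
#'   `"lower_better"` (e.g. price): the preference direction on this
#'   dimension.
#' @param group Optional commensurable-group label. Dimensions sharing a
#'   group are on the same scale and unit and may be collapsed into one
#'   pooled comparison space (see [attribute_balance()]).
#' @return A one-row data frame with columns `name`, `polarity`, `group`.
#' @examples
#' dimension("price", "lower_better")
#' @export
dimension <- function(name, polarity = c("higher_better", "lower_better"),
                      group = NA_character_) {
  polarity <- match.arg(polarity)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, polarity = polarity, group = as.character(group),
             stringsAsFactors = FALSE)
}

#' Construct a decision problem
#'
#' A decision problem is a set of choosable alternatives described on named
#' attribute dimensions, together with the other attribute values the
#' decision maker holds in working memory (context values: prior-trial
#' alternatives, announced-unavailable "phantom" alternatives, samples from
#' long-term memory). Working memory on a dimension is the union of the
#' choosable alternatives' values and the context values on that dimension.
#' Context values act only as comparison partners and similarity
#' contributors; they are never themselves evaluated and never accrue
#' evidence.
#'
#' @param dimensions A data frame of dimension specs, typically built by
#'   `rbind`-ing calls to [dimension()].
#' @param alternatives Named list; each element is a named numeric vector
#'   of strictly positive attribute values keyed by dimension name.
#'   A dimension may be absent (or `NA`) for an alternative: the value is
#'   then missing and the alternative is never evaluated on that dimension.
#' @param context Optional named list of numeric vectors: extra working
#'   memory values per dimension. All values must be strictly positive.
#' @return An object of class `mdbs_problem` with components `dimensions`
#'   (data frame), `values` (alternatives x dimensions matrix, `NA` for
#'   missing), and `context` (named list).
#' @examples
#' p <- mdbs_problem(
#'   dimensions = rbind(dimension("price", "lower_better"),
#'                      dimension("mpg", "higher_better")),
#'   alternatives = list(A = c(price = 24000, mpg = 32),
#'                       B = c(price = 16000, mpg = 24)))
#' accumulation_rates(p, mdbs_params())
#' @export
mdbs_problem <- function(dimensions, alternatives, context = list()) {
  stopifnot(is.data.frame(dimensions),
            all(c("name", "polarity") %in% names(dimensions)))
  if (is.null(dimensions$group)) dimensions$group <- NA_character_
  dn <- dimensions$name
  if (anyDuplicated(dn)) stop("dimension names must be unique")
  if (!all(dimensions$polarity %in% c("higher_better", "lower_better")))
    stop("polarity must be 'higher_better' or 'lower_better'")
  if (!is.list(alternatives) || length(alternatives) < 1L)
    stop("need at least one alternative")
  ids <- names(alternatives)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("alternatives must have unique, nonempty names")

  values <- matrix(NA_real_, nrow = length(ids), ncol = length(dn),
                   dimnames = list(ids, dn))
  for (id in ids) {
    v <- alternatives[[id]]
    if (length(v) == 0L) stop("alternative '", id, "' has no values")
    vn <- names(v)
    if (is.null(vn) || !all(vn %in% dn))
      stop("alternative '", id, "' has values on undeclared dimensions: ",
           paste(setdiff(vn, dn), collapse = ", "))
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("alternative '", id, "' has nonpositive value on dimension '",
           vn[bad][1L], "'; attribute magnitudes must be > 0")
    values[id, vn] <- as.numeric(v)
  }
  if (any(rowSums(!is.na(values)) == 0L))
    stop("every alternative needs at least one present value")

  context <- context %||% list()
  if (length(context)) {
    cn <- names(context)
    if (is.null(cn) || !all(cn %in% dn))
      stop("context values on undeclared dimensions: ",
           paste(setdiff(cn, dn), collapse = ", "))
    for (nm in cn) {
      cv <- as.numeric(context[[nm]])
      if (any(!is.finite(cv)) || any(cv <= 0))
        stop("context values on dimension '", nm, "' must be finite and > 0")
      context[[nm]] <- cv
    }
    context <- context[vapply(context, length, 1L) > 0L]
  }

  structure(list(dimensions = dimensions[, c("name", "polarity", "group")],
                 values = values, context = context),
            class = "mdbs_problem")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mdbs_problem <- function(x, ...) {
  cat("MDbS decision problem:", nrow(x$values), "alternative(s) on",
      ncol(x$values), "dimension(s)\n")
  tab <- as.data.frame(x$values)
  pol <- ifelse(x$dimensions$polarity == "lower_better", " (-)", " (+)")
  names(tab) <- paste0(x$dimensions$name, pol)
  print(tab)
  if (length(x$context)) {
    cat("context values:\n")
    for (nm in names(x$context))
      cat("  ", nm, ": ", paste(signif(x$context[[nm]], 6), collapse = ", "),
          "\n", sep = "")
  }
  invisible(x)
}

#' Restrict a problem to a subset of alternatives
#'
#' Context values are kept; removed alternatives' values are dropped from
#' working memory entirely (they are choosable-alternative values, not
#' context). To keep a removed alternative's values in working memory --
#' e.g. for a phantom decoy -- add them explicitly via `as_context`.
#'
#' @param problem An [mdbs_problem()].
#' @param ids Character vector of alternative ids to keep.
#' @param as_context Optional character vector of alternative ids whose
#'   values move into the context pool instead of being dropped.
#' @return A new `mdbs_problem`.
#' @export
subset_problem <- function(problem, ids, as_context = character()) {
  stopifnot(inherits(problem, "mdbs_problem"))
  all_ids <- rownames(problem$values)
  if (!all(ids %in% all_ids))
    stop("unknown alternative id(s): ",
         paste(setdiff(ids, all_ids), collapse = ", "))
  if (!all(as_context %in% all_ids))
    stop("unknown as_context id(s): ",
         paste(setdiff(as_context, all_ids), collapse = ", "))
  ctx <- problem$context
  for (id in as_context) {
    v <- problem$values[id, ]
    for (nm in names(v)[!is.na(v)])
      ctx[[nm]] <- c(ctx[[nm]], unname(v[nm]))
  }
  alts <- lapply(ids, function(id) {
    v <- problem$values[id, ]
    v[!is.na(v)]
  })
  names(alts) <- ids
  mdbs_problem(problem$dimensions, alts, ctx)
}

# polarity lookup, named by dimension
.polarities <- function(problem) {
  stats::setNames(problem$dimensions$polarity, problem$dimensions$name)
}

# working-memory pool on one dimension: values plus owner ids (NA = context)
.pool <- function(problem, dim) {
  v <- problem$values[, dim]
  own <- rownames(problem$values)[!is.na(v)]
  vals <- v[!is.na(v)]
  ctx <- problem$context[[dim]]
  if (!is.null(ctx) && length(ctx)) {
    vals <- c(vals, ctx)
    own <- c(own, rep(NA_character_, length(ctx)))
  }
  list(values = unname(vals), owner = own)
}

# target cells: one row per (alternative, dimension) with a present value
.cells <- function(problem) {
  idx <- which(!is.na(problem$values), arr.ind = TRUE)
  data.frame(owner = rownames(problem$values)[idx[, 1L]],
             dim = colnames(problem$values)[idx[, 2L]],
             value = problem$values[idx],
             stringsAsFactors = FALSE)
}
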