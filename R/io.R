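# Reading and writing choice-set descriptions and result tables.

#' Parse a decision problem from JSON or CSV
#'
#' JSON schema (versioned, see `write_problem()` for the emitter):
#' \preformatted{
#' {
#'   "dimensions":   [{"name": "price", "polarity": "lower_better"},
#'                    {"name": "mpg",   "polarity": "higher_better"}],
#'   "alternatives": {"A": {"price": 24000, "mpg": 32},
#'                    "B": {"price": 16000, "mpg": 24}},
#'   "context":      {"price": [28000]}
#' }
#' }
#' CSV dialect: one row per dimension with columns `dimension`,
#' `polarity`, optional `group` and `context` (semicolon-separated
#' values), then one column per alternative. Blank cells are missing
#' values.
#'
#' @param path Path to a `.json` or `.csv` file, or a JSON string.
#' @return An [mdbs_problem()].
#' @export
parse_problem <- function(path) {
  is_file <- file.exists(path) && !dir.exists(path)
  if (!is_file && !grepl("^\\s*\\{", path))
    stop("no such file: ", path)
  if (is_file && grepl("\\.csv$", path, ignore.case = TRUE))
    return(.parse_problem_csv(path))
  txt <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n")
         else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (is.null(obj$dimensions) || is.null(obj$alternatives))
    stop("problem JSON needs 'dimensions' and 'alternatives' fields")
  dims <- as.data.frame(obj$dimensions, stringsAsFactors = FALSE)
  if (is.null(dims$group)) dims$group <- NA_character_
  bad <- setdiff(dims$polarity, c("higher_better", "lower_better"))
  if (length(bad))
    stop("unknown polarity token '", bad[1L],
         "'; use higher_better or lower_better")
  alts <- lapply(obj$alternatives, function(a) unlist(a))
  ctx <- if (!is.null(obj$context)) lapply(obj$context, as.numeric)
         else list()
  mdbs_problem(dims, alts, ctx)
}

.parse_problem_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("dimension", "polarity")
  if (!all(need %in% names(tab)))
    stop("problem CSV needs 'dimension' and 'polarity' columns")
  bad <- setdiff(tab$polarity, c("higher_better", "lower_better"))
  if (length(bad))
    stop("unknown polarity token '", bad[1L],
         "'; use higher_better or lower_better")
  meta <- intersect(c("dimension", "polarity", "group", "context"),
                    names(tab))
  alt_cols <- setdiff(names(tab), meta)
  if (!length(alt_cols)) stop("problem CSV has no alternative columns")
  dims <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    dimension(tab$dimension[i], tab$polarity[i],
              if ("group" %in% meta) tab$group[i] else NA_character_)))
  alts <- lapply(alt_cols, function(id) {
    v <- suppressWarnings(as.numeric(tab[[id]]))
    stats::setNames(v, tab$dimension)[!is.na(v)]
  })
  names(alts) <- alt_cols
  ctx <- list()
  if ("context" %in% meta) {
    for (i in seq_len(nrow(tab))) {
      cv <- tab$context[i]
      if (!is.na(cv) && nzchar(cv))
        ctx[[tab$dimension[i]]] <-
          as.numeric(strsplit(cv, ";", fixed = TRUE)[[1L]])
    }
  }
  mdbs_problem(dims, alts, ctx)
}

#' Write a decision problem to JSON or CSV
#'
#' @param problem An [mdbs_problem()].
#' @param path Output path; format follows the extension (`.json` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_problem <- function(problem, path) {
  stopifnot(inherits(problem, "mdbs_problem"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- data.frame(dimension = problem$dimensions$name,
                      polarity = problem$dimensions$polarity,
                      group = problem$dimensions$group,
                      stringsAsFactors = FALSE)
    tab$context <- vapply(problem$dimensions$name, function(nm) {
      cv <- problem$context[[nm]]
      if (is.null(cv) || !length(cv)) "" else paste(cv, collapse = ";")
    }, "")
    for (id in rownames(problem$values))
      tab[[id]] <- problem$values[id, ]
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  } else {
    alts <- lapply(rownames(problem$values), function(id) {
      v <- problem$values[id, ]
      as.list(v[!is.na(v)])
    })
    names(alts) <- rownames(problem$values)
    obj <- list(schema = "mdbs-problem-v1",
                dimensions = problem$dimensions,
                alternatives = alts,
                context = problem$context)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Tidy a result object into a data frame
#'
#' @param x An `mdbs_choice`, `mdbs_scenario` or `mdbs_simulation`.
#' @return A data frame with stable columns: scenarios give
#'   `(scenario, condition, alternative, probability, ...)`, choice
#'   distributions `(alternative, probability)`, simulations
#'   `(alternative, wins, frequency)`.
#' @export
tidy_result <- function(x) {
  if (inherits(x, "mdbs_scenario")) {
    tab <- x$table
    tab <- cbind(scenario = x$name, tab)
    return(tab)
  }
  if (inherits(x, "mdbs_choice"))
    return(data.frame(alternative = names(x$probabilities),
                      probability = unname(x$probabilities),
                      expected_comparisons = x$expected_comparisons,
                      method = x$method, stringsAsFactors = FALSE))
  if (inherits(x, "mdbs_simulation"))
    return(data.frame(alternative = names(x$wins),
                      wins = unname(x$wins),
                      frequency = unname(x$wins) / x$n_trials,
                      stringsAsFactors = FALSE))
  stop("cannot tidy object of class ", paste(class(x), collapse = "/"))
}

#' Write a result object to CSV or JSON
#'
#' CSV output is the tidy table with floating point at six significant
#' digits; JSON output carries the table plus parameter values and seed
#' for provenance.
#'
#' @param x A result object (see [tidy_result()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default follows the extension.
#' @param params,seed Optional provenance overrides; scenarios carry
#'   their own.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL, params = NULL,
                          seed = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (!format %in% c("csv", "json")) stop("format must be csv or json")
  tab <- tidy_result(x)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = 6)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  } else {
    params <- params %||% x$params
    seed <- seed %||% x$seed
    obj <- list(result = tab,
                effects = if (inherits(x, "mdbs_scenario"))
                  as.list(signif(x$effects, 6)),
                params = if (!is.null(params)) unclass(params),
                seed = seed)
    obj <- obj[!vapply(obj, is.null, TRUE)]
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
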