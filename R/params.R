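#' Model parameters
#'
#' Bundles the four tunable parameters of the multialternative
#' decision-by-sampling model with their default values.
#'
#' @param alpha Similarity decay rate (>= 0) governing how strongly
#'   attention concentrates on similar attribute values: the weight of a
#'   comparison between values at fractional distance `D` is
#'   `exp(-alpha * D)`. `alpha = 0` makes target and partner selection
#'   similarity-blind.
#' @param beta0 Fractional-advantage threshold of the soft ordinal
#'   comparison: an advantage of exactly `beta0` (10% by default) is
#'   favored with probability one half.
#' @param beta1 Sensitivity (> 0) of the logistic soft comparison; very
#'   large values recover a hard step comparison.
#' @param theta Relative stopping threshold (> 0): a decision is made when
#'   the leading evidence count exceeds the mean count by at least `theta`.
#'
#' @return An object of class `mdbs_params`: a named list with components
#'   `alpha`, `beta0`, `beta1`, `theta`.
#' @examples
#' mdbs_params()
#' mdbs_params(alpha = 10)  # stronger similarity focus
#' @export
mdbs_params <- function(alpha = 3.0, beta0 = 0.1, beta1 = 50, theta = 0.1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (beta1 <= 0) stop("'beta1' must be > 0")
  if (theta <= 0) stop("'theta' must be > 0")
  structure(list(alpha = alpha, beta0 = beta0, beta1 = beta1, theta = theta),
            class = "mdbs_params")
}

#' @export
print.mdbs_params <- function(x, ...) {
  cat("MDbS parameters: alpha =", x$alpha, ", beta0 =", x$beta0,
      ", beta1 =", x$beta1, ", theta =", x$theta, "\n")
  invisible(x)
}

as_mdbs_params <- function(x) {
  if (inherits(x, "mdbs_params")) return(x)
  if (is.list(x) || is.numeric(x)) return(do.call(mdbs_params, as.list(x)))
  stop("cannot interpret 'params'; use mdbs_params()")
}
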