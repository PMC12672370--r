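#' @useDynLib cyclebrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor pf pt quantile coef lm anova
#'   p.adjust complete.cases fitted
#' @importFrom utils read.delim write.table head combn
NULL

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
# All stochastic generators in the package route through this so that a seed
# argument makes a call bit-reproducible without disturbing the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("'seed' must be a single finite number")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Square-root transform of hormone concentrations
#'
#' Variance-stabilizing transform applied to hormone levels before they enter
#' temporal-score regressions or mass-univariate designs.
#'
#' @param values Numeric vector of concentrations, all non-negative.
#' @return Element-wise square root of `values`.
#' @export
sqrt_transform <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric")
  bad <- which(values < 0)
  if (length(bad)) {
    stop(sprintf("negative concentration at index %d (value %g)",
                 bad[1L], values[bad[1L]]))
  }
  sqrt(values)
}

#' Z-score a numeric vector
#'
#' Centers to mean zero and scales to unit sample (n - 1) standard deviation.
#' Constant input is an error: a degenerate standardization has no meaning
#' for the downstream correlation and regression analyses.
#'
#' @param values Numeric vector, length at least 2.
#' @return Standardized vector.
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("'values' must be a numeric vector of length >= 2")
  }
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (values - mean(values)) / s
}
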