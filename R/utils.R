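#' @useDynLib coexdecay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Run `expr` with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Percentile bootstrap CI of the median of `x`. Uses the fast C++ resampler.
#' Bootstrap confidence interval of the median
#'
#' Percentile bootstrap (2.5/97.5 by default) of the median of a numeric
#' vector. Draws from the RNG stream in effect, so wrap in `set.seed()` (or
#' pass through functions that take a `seed`) for reproducibility.
#'
#' @param x numeric vector.
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @return list with `median`, `ci_low`, `ci_high`, `n_boot`.
#' @export
boot_median_ci <- function(x, n_boot = 1000L, conf = 0.95) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2L, n_boot >= 1L)
  meds <- boot_median_cpp(as.numeric(x), as.integer(n_boot))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
  list(median = stats::median(x), ci_low = ci[1], ci_high = ci[2],
       n_boot = as.integer(n_boot))
}
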