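#' Fit the exponential distance-decay model
#'
#' Least-squares fit of rho(d) = rho0 * exp(-lambda * d) + c to a smoothed
#' correlation (or overlap) curve, with box constraints rho0 in [0, 2],
#' lambda > 0, c in [-1, 1] (widened automatically for statistics on other
#' scales, e.g. percent overlap). The characteristic correlation distance is
#' dexp = 1/lambda: the distance over which the above-baseline correlation
#' falls by a factor e.
#'
#' Starting values are derivative-free: c from the median of the last
#' distance decile, rho0 from the first decile minus c, and lambda from the
#' distance where the curve first drops below c + rho0/e. The fit is flagged
#' `converged = FALSE` when the optimizer errors, stops early, or runs into
#' the lambda lower bound (flat curve: dexp is then meaningless).
#'
#' @param curve data.frame with `distance_bp` and `median_value` (as from
#'   [sliding_median()]); alternatively pass `distance` and `value` vectors.
#' @param distance,value raw vectors, used when `curve` is NULL.
#' @param lam_min lower bound on lambda; default 1e-6 / (distance span), so
#'   flat curves hit the bound instead of chasing lambda to 0.
#' @return object of class `decay_fit`: list with `rho0`, `lam`, `c`,
#'   `dexp`, `rss`, `converged`, `n_points`, `message`.
#' @export
fit_exponential_decay <- function(curve = NULL, distance = NULL, value = NULL,
                                  lam_min = NULL) {
  if (!is.null(curve)) {
    distance <- curve$distance_bp
    value <- curve$median_value
  }
  ok <- !is.na(distance) & !is.na(value)
  d <- as.numeric(distance[ok])
  y <- as.numeric(value[ok])
  if (length(d) < 10L) stop("need at least 10 points to fit the decay model")
  dspan <- max(d) - min(d)
  if (dspan <= 0) stop("all points at a single distance; cannot fit")
  dpos <- d[d > 0]
  if (length(dpos) && max(dpos) / min(dpos) < 10) {
    warning("distances span less than one decade; the decay fit may be poorly constrained")
  }
  if (is.null(lam_min)) lam_min <- 1e-6 / dspan

  if (stats::sd(y) < 1e-14 * max(1, abs(mean(y)))) {
    out <- list(rho0 = 0, lam = lam_min, c = y[1], dexp = 1 / lam_min,
                rss = 0, converged = FALSE, n_points = length(d),
                message = "curve is exactly flat: dexp unreliable")
    class(out) <- "decay_fit"
    return(out)
  }

  # value scale: correlations live in [-1,1]; other statistics (e.g. percent
  # overlap) get bounds inflated to their own range
  vscale <- max(1, max(abs(y)))
  rho0_max <- 2 * vscale
  c_box <- vscale

  # derivative-free initialization from the curve's deciles
  qd <- stats::quantile(d, c(0.1, 0.9), names = FALSE)
  c0 <- stats::median(y[d >= qd[2]])
  rho00 <- stats::median(y[d <= qd[1]]) - c0
  rho00 <- min(max(rho00, 1e-3 * vscale), rho0_max)
  thr <- c0 + rho00 / exp(1)
  o <- order(d)
  below <- which(y[o] < thr & d[o] > 0)
  d_e <- if (length(below)) d[o][below[1]] else stats::median(d)
  lam0 <- min(max(1 / max(d_e, dspan * 1e-6), lam_min * 10), 1 / (dspan * 1e-4))
  c0 <- min(max(c0, -c_box), c_box)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ rho0 * exp(-lam * d) + c,
      data = data.frame(d = d, y = y),
      start = list(rho0 = rho00, lam = lam0, c = c0),
      lower = c(0, lam_min, -c_box),
      upper = c(rho0_max, Inf, c_box),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = 1000, maxfev = 10000)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(rho0 = NA_real_, lam = NA_real_, c = NA_real_,
                dexp = NA_real_, rss = NA_real_, converged = FALSE,
                n_points = length(d),
                message = paste("optimizer failed:", conditionMessage(fit)))
    class(out) <- "decay_fit"
    return(out)
  }
  par <- stats::coef(fit)
  at_bound <- par[["lam"]] <= lam_min * (1 + 1e-8)
  out <- list(
    rho0 = unname(par[["rho0"]]),
    lam = unname(par[["lam"]]),
    c = unname(par[["c"]]),
    dexp = 1 / unname(par[["lam"]]),
    rss = sum(stats::residuals(fit)^2),
    converged = !at_bound,
    n_points = length(d),
    message = if (at_bound) "lambda at lower bound: curve is flat, dexp unreliable" else "ok"
  )
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit: rho(d) = rho0 * exp(-lambda d) + c\n")
  cat(sprintf("  rho0   = %.4g\n  lambda = %.4g per bp\n  c      = %.4g\n",
              x$rho0, x$lam, x$c))
  cat(sprintf("  dexp   = %.4g bp\n  rss    = %.4g over %d points\n",
              x$dexp, x$rss, x$n_points))
  if (!isTRUE(x$converged)) cat("  NOT CONVERGED:", x$message, "\n")
  invisible(x)
}

#' Write a decay fit as JSON
#' @param fit `decay_fit` object.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(rho0 = fit$rho0, lambda_per_bp = fit$lam, c = fit$c,
         dexp_bp = fit$dexp, rss = fit$rss, converged = fit$converged,
         n_points = fit$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
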