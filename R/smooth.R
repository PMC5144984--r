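#' Sliding-median smoothing of a value-versus-distance cloud
#'
#' Sorts the records by distance and, for every contiguous window of
#' `window` records (step 1), emits the window's median distance, median
#' value, and first/third quartiles (type-7 quantiles, for interquartile
#' bands). The heavy lifting is an order-statistic sliding window in C++;
#' its contract is defined by naive per-window recomputation.
#'
#' @param distance,value numeric vectors of equal length (NA pairs dropped).
#' @param window window size in records, default 1000.
#' @param statistic_name label stored on the curve (e.g. "rho", "overlap").
#' @return data.frame with `distance_bp`, `median_value`, `q25`, `q75`;
#'   attributes `window` and `statistic_name`.
#' @export
sliding_median <- function(distance, value, window = 1000L,
                           statistic_name = "rho") {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be an integer >= 1")
  ok <- !is.na(distance) & !is.na(value)
  distance <- as.numeric(distance[ok])
  value <- as.numeric(value[ok])
  n <- length(value)
  if (n < window) {
    stop(sprintf("only %d records for window size %d; use a smaller window",
                 n, window))
  }
  o <- order(distance)
  d <- distance[o]
  v <- value[o]
  q <- roll_quantiles_cpp(v, window)
  # distances are already sorted, so each window's median is read off by index
  h <- (window - 1) * 0.5
  lo <- floor(h); g <- h - lo
  starts <- seq_len(n - window + 1L)
  dmed <- d[starts + lo]
  if (g > 0) dmed <- (1 - g) * dmed + g * d[starts + lo + 1]
  out <- data.frame(distance_bp = dmed, median_value = q$median,
                    q25 = q$q25, q75 = q$q75)
  attr(out, "window") <- window
  attr(out, "statistic_name") <- statistic_name
  out
}

#' Write a smoothed curve to TSV
#' @param curve curve from [sliding_median()].
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
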