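#' Read an expression matrix from TSV
#'
#' First column must be the gene id; remaining columns are experiments.
#' `NA` marks missing (unassayed) entries, distinct from zero.
#'
#' @param path TSV path.
#' @return numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Convert read counts to transcripts per million (TPM)
#'
#' TPM_g = 1e6 * (counts_g / length_g) / sum_j (counts_j / length_j),
#' computed per experiment, so every column sums to one million.
#'
#' @param counts genes x experiments count matrix (rownames = gene ids).
#' @param lengths effective gene lengths in bp, one per row of `counts`.
#' @return TPM matrix of the same shape.
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene row")
  }
  if (any(lengths <= 0, na.rm = TRUE)) stop("gene lengths must be positive")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  rate <- counts / lengths
  denom <- colSums(rate, na.rm = TRUE)
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop("experiment(s) with zero total signal: ",
         paste(colnames(counts)[bad] %||% bad, collapse = ", "))
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Drop genes detected in too few experiments
#'
#' A gene counts as detected in an experiment when its value is non-missing
#' and strictly positive. Genes detected in fewer than `min_frac` of the
#' experiments are discarded (boundary inclusive: exactly `min_frac` keeps).
#'
#' @param m expression matrix (genes x experiments), NA = missing.
#' @param min_frac minimum detected fraction, default 0.8.
#' @return filtered matrix.
#' @export
detection_filter <- function(m, min_frac = 0.8) {
  stopifnot(min_frac > 0, min_frac <= 1)
  detected <- rowSums(!is.na(m) & m > 0)
  keep <- detected >= min_frac * ncol(m)
  if (!any(keep)) stop("detection filter removed every gene")
  message(sprintf("detection filter: kept %d / %d genes (min_frac = %g)",
                  sum(keep), nrow(m), min_frac))
  m[keep, , drop = FALSE]
}

#' Rank expression within each experiment
#'
#' Replaces each column by within-experiment ranks over the non-missing
#' genes (average ranks for ties); missing entries stay missing. Ranking
#' within experiment makes every downstream pair correlation a Spearman
#' coefficient, invariant to any monotone transform of the expression scale.
#'
#' @param m expression matrix (genes x experiments).
#' @return matrix of ranks, same shape and dimnames.
#' @export
rank_by_experiment <- function(m) {
  if (nrow(m) < 2L) stop("ranking needs at least 2 genes")
  n_ok <- colSums(!is.na(m))
  drop <- which(n_ok < 2L)
  if (length(drop)) {
    warning("excluding ", length(drop),
            " experiment(s) with < 2 non-missing genes")
    m <- m[, -drop, drop = FALSE]
  }
  apply(m, 2, function(x) rank(x, na.last = "keep", ties.method = "average"))
}

#' Spearman correlation via Pearson on ranks
#'
#' Ranks each vector (average ranks for ties, pairwise-complete
#' observations) and evaluates the covariance form
#' rho = cov(r_x, r_y) / (sd(r_x) sd(r_y)).
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman rho, or NA if either rank vector is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  .pearson(rx, ry)
}

.pearson <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  cx <- x - mean(x)
  cy <- y - mean(y)
  sx <- sqrt(sum(cx^2))
  sy <- sqrt(sum(cy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(cx * cy) / (sx * sy)
}

#' Per-pair correlations of ranked expression
#'
#' For each gene pair, the Pearson correlation of the two genes' rank
#' vectors across experiments (the Spearman coefficient of the underlying
#' expression), using experiments where both genes are non-missing. Pairs
#' with fewer than `min_obs` joint observations, with a gene absent from
#' the ranked matrix, or with a constant rank vector are omitted.
#'
#' @param ranks ranked matrix from [rank_by_experiment()] (rownames = gene ids).
#' @param pairs pair table from [neighbor_pairs()].
#' @param min_obs minimum joint observations, default 10.
#' @return pair table restricted to scored pairs, with `rho` and `n_obs`
#'   columns appended.
#' @export
pair_correlations <- function(ranks, pairs, min_obs = 10L) {
  min_obs <- max(3L, as.integer(min_obs))
  ia <- match(pairs$gene_a, rownames(ranks))
  ib <- match(pairs$gene_b, rownames(ranks))
  present <- !is.na(ia) & !is.na(ib)
  n_absent <- sum(!present)
  if (n_absent) {
    message(sprintf("pair_correlations: %d pairs skipped (gene not in expression matrix)",
                    n_absent))
  }
  pr <- pairs[present, , drop = FALSE]
  ia <- ia[present]; ib <- ib[present]
  m <- ncol(ranks)
  has_na <- anyNA(ranks)
  if (!has_na) {
    # fast path: standardize each gene's rank vector once, rho by row products
    ctr <- ranks - rowMeans(ranks)
    ss <- sqrt(rowSums(ctr^2))
    rho <- rep(NA_real_, nrow(pr))
    chunk <- 100000L
    for (s in seq(1L, nrow(pr), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(pr))
      num <- rowSums(ctr[ia[s:e], , drop = FALSE] * ctr[ib[s:e], , drop = FALSE])
      den <- ss[ia[s:e]] * ss[ib[s:e]]
      rho[s:e] <- ifelse(den > 0, num / den, NA_real_)
    }
    n_obs <- rep(m, nrow(pr))
  } else {
    rho <- numeric(nrow(pr))
    n_obs <- integer(nrow(pr))
    for (p in seq_len(nrow(pr))) {
      x <- ranks[ia[p], ]; y <- ranks[ib[p], ]
      ok <- !is.na(x) & !is.na(y)
      n_obs[p] <- sum(ok)
      rho[p] <- if (n_obs[p] >= 2L) .pearson(x[ok], y[ok]) else NA_real_
    }
  }
  keep <- !is.na(rho) & n_obs >= min_obs
  n_skip <- sum(!keep)
  if (n_skip) {
    message(sprintf("pair_correlations: %d pairs omitted (constant gene or < %d joint observations)",
                    n_skip, min_obs))
  }
  out <- pr[keep, , drop = FALSE]
  out$rho <- rho[keep]
  out$n_obs <- as.integer(n_obs[keep])
  rownames(out) <- NULL
  attr(out, "k") <- attr(pairs, "k")
  out
}

#' Write pair correlations to TSV
#' @param cors correlation table from [pair_correlations()].
#' @param path output path.
#' @export
write_correlations <- function(cors, path) {
  cols <- intersect(c("gene_a", "gene_b", "distance_bp", "orientation",
                      "rho", "n_obs"), names(cors))
  utils::write.table(cors[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
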