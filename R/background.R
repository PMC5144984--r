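#' Cross-chromosome background correlation
#'
#' Estimates the null level of the neighbor-correlation curve: each gene is
#' paired with `n_per_gene` genes sampled (without replacement, per gene)
#' from other chromosomes, the Spearman correlation of each random pair is
#' computed on the ranked matrix, and the median is reported with a
#' percentile bootstrap 95% confidence interval from `n_boot` resamples.
#'
#' @param ranks ranked matrix from [rank_by_experiment()].
#' @param genes gene table covering the rows of `ranks` (used for
#'   chromosome assignment; genes absent from `ranks` are ignored).
#' @param n_per_gene partners per gene, default 20.
#' @param n_boot bootstrap resamples, default 10000.
#' @param seed RNG seed (required for reproducibility).
#' @param conf confidence level of the bootstrap interval.
#' @return list with `median_rho`, `ci_low`, `ci_high`, `n_pairs`, `n_boot`,
#'   `seed`.
#' @export
background_correlation <- function(ranks, genes, n_per_gene = 20L,
                                   n_boot = 10000L, seed, conf = 0.95) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  genes <- genes[genes$gene_id %in% rownames(ranks), , drop = FALSE]
  chrom <- genes$chromosome
  if (length(unique(chrom)) < 2L) {
    stop("background sampling needs genes on at least 2 chromosomes")
  }
  idx <- match(genes$gene_id, rownames(ranks))
  n <- nrow(genes)
  with_seed(seed, {
    partners <- vector("list", n)
    warned <- FALSE
    chrom_split <- split(seq_len(n), chrom)
    for (g in seq_len(n)) {
      pool <- which(chrom != chrom[g])
      take <- min(n_per_gene, length(pool))
      if (take < n_per_gene && !warned) {
        warning("fewer eligible cross-chromosome partners than n_per_gene; sampling all")
        warned <- TRUE
      }
      partners[[g]] <- pool[sample.int(length(pool), take)]
    }
    src <- rep(seq_len(n), lengths(partners))
    dst <- unlist(partners, use.names = FALSE)
    ia <- idx[src]; ib <- idx[dst]
    if (anyNA(ranks)) {
      rho <- vapply(seq_along(ia), function(p) {
        x <- ranks[ia[p], ]; y <- ranks[ib[p], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L) NA_real_ else .pearson(x[ok], y[ok])
      }, numeric(1))
    } else {
      ctr <- ranks - rowMeans(ranks)
      ss <- sqrt(rowSums(ctr^2))
      num <- rowSums(ctr[ia, , drop = FALSE] * ctr[ib, , drop = FALSE])
      den <- ss[ia] * ss[ib]
      rho <- ifelse(den > 0, num / den, NA_real_)
    }
    rho <- rho[!is.na(rho)]
    ci <- boot_median_ci(rho, n_boot = n_boot, conf = conf)
    list(median_rho = ci$median, ci_low = ci$ci_low, ci_high = ci$ci_high,
         n_pairs = length(rho), n_boot = as.integer(n_boot),
         seed = as.integer(seed))
  })
}
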