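#' Run the neighbor-correlation decay analysis end to end
#'
#' Convenience driver chaining the pipeline stages: neighbor pairing,
#' optional operon/duplicate filtering, TPM detection filtering,
#' within-experiment ranking, per-pair Spearman correlation, sliding-median
#' smoothing, and the exponential decay fit. The optional cross-chromosome
#' background is computed when `background = TRUE`.
#'
#' @param genes gene table ([load_gene_annotation()] / [simulate_genome()]).
#' @param expression expression matrix, genes x experiments (TPM scale;
#'   use [tpm_from_counts()] first for counts).
#' @param k neighbor rank window, default 100.
#' @param min_frac detection-filter fraction, default 0.8.
#' @param min_obs minimum joint observations per pair, default 10.
#' @param window sliding-median window, default 1000.
#' @param operon_sets,duplicate_pairs optional filter lists
#'   (see [apply_pair_filters()]).
#' @param drop_duplicates remove duplicated-gene pairs, default FALSE.
#' @param fit_on_raw fit the decay on raw pair correlations instead of the
#'   smoothed curve (sensitivity analysis), default FALSE.
#' @param background compute the cross-chromosome background, default FALSE.
#' @param n_per_gene,n_boot background sampling parameters.
#' @param seed RNG seed (needed when `background = TRUE`).
#' @return list with `pairs`, `correlations`, `curve`, `fit`, and
#'   (optionally) `background`.
#' @export
run_neighbor_analysis <- function(genes, expression, k = 100L,
                                  min_frac = 0.8, min_obs = 10L,
                                  window = 1000L,
                                  operon_sets = NULL, duplicate_pairs = NULL,
                                  drop_duplicates = FALSE,
                                  fit_on_raw = FALSE,
                                  background = FALSE,
                                  n_per_gene = 20L, n_boot = 10000L,
                                  seed = NULL) {
  pairs <- neighbor_pairs(genes, k = k)
  if (!is.null(operon_sets) || !is.null(duplicate_pairs)) {
    pairs <- apply_pair_filters(pairs, operon_sets, duplicate_pairs,
                                drop_duplicates = drop_duplicates,
                                known_genes = genes$gene_id)
  }
  filtered <- detection_filter(expression, min_frac = min_frac)
  ranks <- rank_by_experiment(filtered)
  cors <- pair_correlations(ranks, pairs, min_obs = min_obs)
  if (fit_on_raw) {
    curve <- sliding_median(cors$distance_bp, cors$rho, window = window)
    fit <- fit_exponential_decay(distance = cors$distance_bp, value = cors$rho)
  } else {
    curve <- sliding_median(cors$distance_bp, cors$rho, window = window)
    fit <- fit_exponential_decay(curve)
  }
  out <- list(pairs = pairs, correlations = cors, curve = curve, fit = fit)
  if (background) {
    if (is.null(seed)) stop("background = TRUE needs a seed")
    out$background <- background_correlation(ranks, genes,
                                             n_per_gene = n_per_gene,
                                             n_boot = n_boot, seed = seed)
  }
  out
}
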