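#' Read gene-to-tissue annotations
#'
#' TSV with columns `gene_id` and `tissue`, one row per assignment (the
#' layout of in situ hybridization annotation dumps). Tissue terms are
#' case-normalized to lower case and deduplicated per gene.
#'
#' @param path TSV path.
#' @return named list: gene_id -> character vector of tissue terms.
#' @export
read_tissue_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tissue") %in% names(tab))) {
    stop("tissue TSV needs columns gene_id and tissue")
  }
  tab$tissue <- tolower(trimws(tab$tissue))
  tab <- tab[nzchar(tab$tissue), , drop = FALSE]
  lapply(split(tab$tissue, tab$gene_id), unique)
}

#' Percentage tissue overlap of two annotation sets
#'
#' 100 * |intersection| / |union| (the Jaccard index on tissue terms, as a
#' percentage): 100 for identical sets, 0 for disjoint ones.
#'
#' @param a,b character vectors of tissue terms (non-empty).
#' @return overlap percentage in \[0, 100\].
#' @export
tissue_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("tissue overlap needs two non-empty sets")
  }
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Tissue-overlap decay with intergenic distance
#'
#' Computes the percentage tissue overlap for every pair whose two genes are
#' both annotated, then reuses the sliding-median / exponential-fit stack to
#' estimate the spatial correlation distance of tissue identity.
#'
#' @param annotations list from [read_tissue_annotations()] (or
#'   [simulate_tissue_annotations()]).
#' @param pairs pair table from [neighbor_pairs()].
#' @param window sliding-median window, default 1000.
#' @param exclude_terms optional tissue terms (e.g. ubiquitous/maternal
#'   catch-alls) stripped from every set before scoring; genes left with an
#'   empty set become unannotated.
#' @return list with `pairs` (scored subset with `overlap` column), `curve`
#'   (a [sliding_median()] data.frame, statistic "overlap") and `fit`
#'   (a `decay_fit`).
#' @export
overlap_vs_distance <- function(annotations, pairs, window = 1000L,
                                exclude_terms = NULL) {
  if (!is.null(exclude_terms)) {
    annotations <- lapply(annotations, setdiff, y = tolower(exclude_terms))
  }
  annotations <- annotations[lengths(annotations) > 0L]
  ok <- pairs$gene_a %in% names(annotations) & pairs$gene_b %in% names(annotations)
  n_skip <- sum(!ok)
  if (n_skip) {
    message(sprintf("overlap_vs_distance: %d pairs skipped (unannotated gene)", n_skip))
  }
  pr <- pairs[ok, , drop = FALSE]
  if (nrow(pr) < window) {
    stop(sprintf("only %d doubly-annotated pairs for window %d", nrow(pr), window))
  }
  # vectorized Jaccard via a gene x tissue membership matrix
  vocab <- unique(unlist(annotations, use.names = FALSE))
  member <- matrix(FALSE, length(annotations), length(vocab),
                   dimnames = list(names(annotations), vocab))
  member[cbind(rep(seq_along(annotations), lengths(annotations)),
               match(unlist(annotations, use.names = FALSE), vocab))] <- TRUE
  ia <- match(pr$gene_a, rownames(member))
  ib <- match(pr$gene_b, rownames(member))
  inter <- rowSums(member[ia, , drop = FALSE] & member[ib, , drop = FALSE])
  uni <- rowSums(member[ia, , drop = FALSE] | member[ib, , drop = FALSE])
  pr$overlap <- 100 * inter / uni
  curve <- sliding_median(pr$distance_bp, pr$overlap, window = window,
                          statistic_name = "overlap")
  fit <- fit_exponential_decay(curve)
  list(pairs = pr, curve = curve, fit = fit)
}
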