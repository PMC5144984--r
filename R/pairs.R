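#' Strand-aware TSS-to-TSS distance between two gene records
#'
#' The intergenic distance used throughout is the absolute difference of the
#' two genes' transcription start sites (the 5' gene ends), not the gap
#' between gene bodies. Symmetric in its arguments.
#'
#' @param a,b single-row gene records (data.frames with `chromosome`, `tss`).
#' @return distance in bp.
#' @export
intergenic_distance <- function(a, b) {
  if (a$chromosome != b$chromosome) {
    stop("intergenic distance is defined only within a chromosome")
  }
  abs(b$tss - a$tss)
}

#' Classify the relative orientation of an upstream/downstream gene pair
#'
#' `a` must be the upstream-by-TSS member. Same strands give `parallel`;
#' upstream `-` with downstream `+` is `divergent` (promoters back to back);
#' upstream `+` with downstream `-` is `convergent` (transcription head-on).
#'
#' @param strand_a,strand_b strands ("+"/"-") of the upstream and downstream
#'   gene; vectorized.
#' @return character vector in `{divergent, parallel, convergent}`.
#' @export
classify_orientation <- function(strand_a, strand_b) {
  out <- rep("parallel", length(strand_a))
  out[strand_a == "-" & strand_b == "+"] <- "divergent"
  out[strand_a == "+" & strand_b == "-"] <- "convergent"
  out
}

#' Build neighbor gene pairs within a rank window
#'
#' Pairs every gene with its `k` nearest neighbors on the same chromosome,
#' where "nearest" is rank separation in the TSS-sorted gene order. Each
#' unordered pair appears once, with `gene_a` the upstream-by-TSS member.
#' For a chromosome of n genes this yields sum_{i=1}^{n-1} min(i, k) pairs.
#'
#' @param genes gene table (see [load_gene_annotation()]).
#' @param k neighbor window (rank separation cutoff), >= 1. Default 100.
#' @return data.frame with columns `gene_a`, `gene_b`, `chromosome`,
#'   `distance_bp`, `rank_separation`, `orientation`, `is_operon_pair`,
#'   `is_duplicate_pair`; attribute `k` records the window.
#' @export
neighbor_pairs <- function(genes, k = 100L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  gt <- data.table::as.data.table(genes)
  data.table::setorder(gt, chromosome, tss, gene_id)
  per_chrom <- lapply(split(gt, by = "chromosome"), function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    smax <- min(k, n - 1L)
    i <- unlist(lapply(seq_len(smax), function(s) seq_len(n - s)), use.names = FALSE)
    s <- rep(seq_len(smax), times = (n - 1L):(n - smax))
    j <- i + s
    data.table::data.table(
      gene_a = g$gene_id[i], gene_b = g$gene_id[j],
      chromosome = g$chromosome[1L],
      distance_bp = g$tss[j] - g$tss[i],
      rank_separation = s,
      orientation = classify_orientation(g$strand[i], g$strand[j])
    )
  })
  pairs <- data.table::rbindlist(per_chrom)
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no pairable genes (need >= 2 genes on some chromosome)")
  pairs[, is_operon_pair := FALSE]
  pairs[, is_duplicate_pair := FALSE]
  out <- as.data.frame(pairs)
  attr(out, "k") <- k
  out
}

#' Read an operon list (one operon per line, tab-separated gene ids)
#' @param path TSV path.
#' @return list of character vectors, one per operon.
#' @export
read_operon_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "\t", fixed = TRUE), trimws)
}

#' Read duplicated gene pairs (two-column TSV, no header required)
#' @param path TSV path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_duplicate_pairs <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(tab[, 1:2], c("gene_a", "gene_b"))
}

# canonical unordered key for a pair of ids
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Flag and filter operonic and duplicated gene pairs
#'
#' Pairs whose two members share at least one operon are flagged and removed
#' (cotranscription would trivially correlate them). Duplicated-gene pairs
#' are flagged; their removal is left to the caller (`drop_duplicates`),
#' mirroring the robustness check of rerunning the analysis without them.
#'
#' @param pairs pair table from [neighbor_pairs()].
#' @param operon_sets list of character vectors of gene ids (one per operon),
#'   or NULL.
#' @param duplicate_pairs data.frame with `gene_a`,`gene_b` columns, or NULL.
#' @param drop_operons remove same-operon pairs (default TRUE).
#' @param drop_duplicates remove duplicated-gene pairs (default FALSE).
#' @param known_genes optional character vector of valid gene ids; list
#'   entries outside it trigger a warning, never an error.
#' @return filtered pair table with `is_operon_pair`/`is_duplicate_pair` set.
#' @export
apply_pair_filters <- function(pairs, operon_sets = NULL, duplicate_pairs = NULL,
                               drop_operons = TRUE, drop_duplicates = FALSE,
                               known_genes = NULL) {
  if (!is.null(known_genes)) {
    listed <- unique(c(unlist(operon_sets, use.names = FALSE),
                       duplicate_pairs$gene_a, duplicate_pairs$gene_b))
    unknown <- setdiff(listed, known_genes)
    if (length(unknown)) {
      warning(length(unknown), " gene ids in filter lists are absent from the gene table (e.g. ",
              paste(utils::head(unknown, 3), collapse = ", "), ")")
    }
  }
  op_flag <- rep(FALSE, nrow(pairs))
  if (length(operon_sets)) {
    for (op in operon_sets) {
      op_flag <- op_flag | (pairs$gene_a %in% op & pairs$gene_b %in% op)
    }
  }
  dup_flag <- rep(FALSE, nrow(pairs))
  if (!is.null(duplicate_pairs) && nrow(duplicate_pairs)) {
    dup_keys <- .pair_key(duplicate_pairs$gene_a, duplicate_pairs$gene_b)
    dup_flag <- .pair_key(pairs$gene_a, pairs$gene_b) %in% dup_keys
  }
  pairs$is_operon_pair <- op_flag
  pairs$is_duplicate_pair <- dup_flag
  keep <- rep(TRUE, nrow(pairs))
  if (drop_operons) keep <- keep & !op_flag
  if (drop_duplicates) keep <- keep & !dup_flag
  n_drop <- sum(!keep)
  if (n_drop) {
    message(sprintf("filtered %d pairs (%d operonic, %d duplicate-flagged)",
                    n_drop, sum(op_flag), sum(dup_flag)))
  }
  k <- attr(pairs, "k")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  out
}

#' Write a pair table to TSV
#' @param pairs pair table.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
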