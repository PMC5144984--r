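#' Read insulator binding intervals from BED
#'
#' BED is 0-based half-open on disk; rtracklayer converts to 1-based
#' inclusive ranges on load.
#'
#' @param path BED path.
#' @return a `GRanges` of binding intervals.
#' @export
read_interval_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Intersect two replicate interval sets
#'
#' Returns the maximal intervals covered by both replicates (standard
#' interval intersection), the conservative site definition for replicated
#' ChIP experiments.
#'
#' @param rep1,rep2 `GRanges` interval sets for the same factor.
#' @return intersected `GRanges`; empty (with a warning) if disjoint.
#' @export
intersect_replicates <- function(rep1, rep2) {
  out <- GenomicRanges::intersect(GenomicRanges::reduce(rep1),
                                  GenomicRanges::reduce(rep2),
                                  ignore.strand = TRUE)
  if (length(out) == 0L) warning("replicate intersection is empty")
  out
}

#' Flag pairs with an insulator site between their TSSs
#'
#' A pair is flanked by factor F when at least one F interval overlaps the
#' open genomic interval between the two genes' TSSs (`mode = "between"`).
#' The alternative reading — sites outside the pair, bracketing it on both
#' sides — is available as `mode = "bracketing"`.
#'
#' @param pairs pair table from [neighbor_pairs()].
#' @param genes gene table supplying TSS coordinates.
#' @param sites named list of `GRanges`, one per factor (e.g. the output of
#'   [intersect_replicates()]), or a single `GRanges` (factor "site").
#' @param mode `"between"` (default) or `"bracketing"`.
#' @return the pair table with a logical `flanked_<factor>` column per factor.
#' @export
flag_flanked_pairs <- function(pairs, genes, sites, mode = c("between", "bracketing")) {
  mode <- match.arg(mode)
  if (inherits(sites, "GRanges")) sites <- list(site = sites)
  tss <- stats::setNames(genes$tss, genes$gene_id)
  ta <- tss[pairs$gene_a]
  tb <- tss[pairs$gene_b]
  if (anyNA(ta) || anyNA(tb)) stop("pair genes missing from the gene table")
  if (is.null(pairs$chromosome)) {
    pairs$chromosome <- stats::setNames(genes$chromosome,
                                        genes$gene_id)[pairs$gene_a]
  }
  lo <- pmin(ta, tb)
  hi <- pmax(ta, tb)
  site_chroms <- unique(unlist(lapply(sites, function(g)
    as.character(unique(GenomeInfoDb::seqnames(g))))))
  shared <- intersect(unique(pairs$chromosome), site_chroms)
  if (length(shared) == 0L) {
    stop("no shared chromosome names between pairs and interval sets; pairs use {",
         paste(unique(pairs$chromosome), collapse = ", "), "} but sites use {",
         paste(site_chroms, collapse = ", "), "}")
  }
  # open interval between the TSSs, 1-based inclusive; degenerate when the
  # TSSs are adjacent (width <= 1): nothing can lie strictly between
  inner_ok <- hi - lo > 1
  gr_pairs <- GenomicRanges::GRanges(
    seqnames = pairs$chromosome[inner_ok],
    ranges = IRanges::IRanges(start = lo[inner_ok] + 1, end = hi[inner_ok] - 1))
  for (f in names(sites)) {
    gr_sites <- GenomicRanges::reduce(sites[[f]], ignore.strand = TRUE)
    flag <- rep(FALSE, nrow(pairs))
    if (mode == "between") {
      hit <- GenomicRanges::countOverlaps(gr_pairs, gr_sites,
                                          ignore.strand = TRUE) > 0
      flag[inner_ok] <- hit
    } else {
      up <- GenomicRanges::GRanges(pairs$chromosome,
                                   IRanges::IRanges(1, pmax(lo - 1, 1)))
      down <- GenomicRanges::GRanges(pairs$chromosome,
                                     IRanges::IRanges(hi + 1, hi + 1e9))
      flag <- GenomicRanges::countOverlaps(up, gr_sites, ignore.strand = TRUE) > 0 &
        GenomicRanges::countOverlaps(down, gr_sites, ignore.strand = TRUE) > 0
    }
    pairs[[paste0("flanked_", f)]] <- flag
  }
  pairs
}

.summarize_groups <- function(groups, n_boot = 1000L, conf = 0.95) {
  med <- vapply(groups, function(g) stats::median(g$rho), numeric(1))
  ci <- t(vapply(groups, function(g) {
    b <- boot_median_ci(g$rho, n_boot = n_boot, conf = conf)
    c(b$ci_low, b$ci_high)
  }, numeric(2)))
  colnames(ci) <- c("ci_low", "ci_high")
  list(median = med, ci = ci,
       n = vapply(groups, nrow, integer(1)),
       median_distance = vapply(groups, function(g) stats::median(g$distance_bp),
                                numeric(1)))
}

.ks_vs_reference <- function(groups) {
  ref <- groups[[1]]$distance_bp
  vapply(groups, function(g) {
    if (identical(g$distance_bp, ref)) return(0)
    unname(suppressWarnings(
      stats::ks.test(g$distance_bp, ref, exact = FALSE)$statistic))
  }, numeric(1))
}

# Mann-Whitney p-values of each group's correlations against the first
# group; descriptive annotation only, never a pass/fail gate.
.ranksum_vs_reference <- function(groups) {
  ref <- groups[[1]]$rho
  vapply(groups, function(g) {
    if (identical(g$rho, ref)) return(1)
    suppressWarnings(stats::wilcox.test(g$rho, ref)$p.value)
  }, numeric(1))
}

.new_group_comparison <- function(groups, control_mode, window = NULL,
                                  n_boot = 1000L, conf = 0.95) {
  s <- .summarize_groups(groups, n_boot = n_boot, conf = conf)
  out <- list(groups = groups, control_mode = control_mode,
              distance_window = window,
              median = s$median, ci = s$ci, n = s$n,
              median_distance = s$median_distance,
              ks_vs_reference = .ks_vs_reference(groups),
              p_ranksum_vs_reference = .ranksum_vs_reference(groups))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$control_mode, ")\n", sep = "")
  if (!is.null(x$distance_window)) {
    cat(sprintf("  distance window: [%g, %g) bp\n",
                x$distance_window[1], x$distance_window[2]))
  }
  tab <- data.frame(n = x$n, median_rho = round(x$median, 4),
                    ci_low = round(x$ci[, 1], 4), ci_high = round(x$ci[, 2], 4),
                    median_distance = round(x$median_distance),
                    ks_vs_reference = round(x$ks_vs_reference, 4))
  print(tab)
  invisible(x)
}

#' Restrict labeled pair groups to a shared distance window
#'
#' The coarse distance control: every group is cut to pairs with
#' lo <= distance < hi, removing the distance confound by brute force when
#' the window is narrow relative to the decay scale.
#'
#' @param groups named list of correlation tables (must carry `distance_bp`
#'   and `rho`).
#' @param lo,hi window bounds in bp (lo inclusive, hi exclusive).
#' @param min_pairs minimum pairs a group must retain, default 10.
#' @param n_boot bootstrap resamples for median CIs.
#' @return a `group_comparison` object.
#' @export
distance_window_subset <- function(groups, lo, hi, min_pairs = 10L,
                                   n_boot = 1000L) {
  stopifnot(is.list(groups), length(groups) >= 1L, lo < hi)
  trimmed <- lapply(groups, function(g) {
    g[g$distance_bp >= lo & g$distance_bp < hi, , drop = FALSE]
  })
  empty <- names(trimmed)[vapply(trimmed, nrow, integer(1)) < min_pairs]
  if (length(empty)) {
    stop("group(s) with fewer than ", min_pairs, " pairs in [", lo, ", ", hi,
         "): ", paste(empty, collapse = ", "))
  }
  .new_group_comparison(trimmed, control_mode = "window", window = c(lo, hi),
                        n_boot = n_boot)
}

#' Histogram-matched downsampling of pair groups
#'
#' The fine distance control: distances are binned at `bin_width` over the
#' groups' shared support, each group is downsampled to the per-bin minimum
#' count, and the resulting distance distributions are checked to agree
#' (two-sample Kolmogorov-Smirnov statistic against the first group).
#'
#' @param groups named list of correlation tables (>= 2 groups).
#' @param bin_width bin width in bp.
#' @param seed RNG seed for the downsampling.
#' @param n_boot bootstrap resamples for median CIs.
#' @return a `group_comparison` object (control_mode "matched").
#' @export
histogram_matched_sample <- function(groups, bin_width, seed, n_boot = 1000L) {
  stopifnot(is.list(groups), length(groups) >= 2L, bin_width > 0)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  lo <- max(vapply(groups, function(g) min(g$distance_bp), numeric(1)))
  hi <- min(vapply(groups, function(g) max(g$distance_bp), numeric(1)))
  if (lo >= hi) stop("groups have disjoint distance supports; nothing to match")
  breaks <- seq(floor(lo / bin_width) * bin_width, hi + bin_width, by = bin_width)
  binned <- lapply(groups, function(g) {
    b <- findInterval(g$distance_bp, breaks, rightmost.closed = FALSE)
    split(seq_len(nrow(g)), factor(b, levels = seq_len(length(breaks) - 1L)))
  })
  counts <- vapply(binned, function(bn) lengths(bn), integer(length(breaks) - 1L))
  take <- apply(counts, 1, min)
  if (all(take == 0L)) stop("no distance bin is populated by every group")
  with_seed(seed, {
    sampled <- lapply(seq_along(groups), function(gi) {
      idx <- unlist(lapply(which(take > 0L), function(b) {
        pool <- binned[[gi]][[b]]
        if (length(pool) == take[b]) pool else pool[sample.int(length(pool), take[b])]
      }), use.names = FALSE)
      groups[[gi]][sort(idx), , drop = FALSE]
    })
    names(sampled) <- names(groups)
    .new_group_comparison(sampled, control_mode = "matched", n_boot = n_boot)
  })
}

#' Write a group comparison to long and summary TSVs
#' @param cmp `group_comparison` object.
#' @param long_path,summary_path output paths (NULL to skip either).
#' @export
write_group_comparison <- function(cmp, long_path = NULL, summary_path = NULL) {
  if (!is.null(long_path)) {
    long <- data.table::rbindlist(lapply(names(cmp$groups), function(g) {
      data.table::data.table(group = g, control_mode = cmp$control_mode,
                             cmp$groups[[g]][, c("gene_a", "gene_b",
                                                 "distance_bp", "rho")])
    }))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    summ <- data.frame(group = names(cmp$groups), n = cmp$n,
                       median_rho = cmp$median,
                       ci_low = cmp$ci[, 1], ci_high = cmp$ci[, 2],
                       median_distance = cmp$median_distance,
                       ks_vs_reference = cmp$ks_vs_reference)
    utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(cmp)
}
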