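# Independent oracles and tiny fixture builders shared across tests.

# Classic rank-difference Spearman formula; valid only without ties.
spearman_formula_oracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Naive sliding median/quartiles: per-window recomputation with stats::median
# and stats::quantile (type 7), step 1, records sorted by distance.
sliding_median_oracle <- function(distance, value, window) {
  o <- order(distance)
  d <- distance[o]; v <- value[o]
  n <- length(v)
  starts <- seq_len(n - window + 1L)
  res <- vapply(starts, function(s) {
    win <- v[s:(s + window - 1L)]
    dw <- d[s:(s + window - 1L)]
    c(stats::median(dw), stats::median(win),
      stats::quantile(win, 0.25, names = FALSE, type = 7),
      stats::quantile(win, 0.75, names = FALSE, type = 7))
  }, numeric(4))
  data.frame(distance_bp = res[1, ], median_value = res[2, ],
             q25 = res[3, ], q75 = res[4, ])
}

# Hand-rolled gene table: tss positions on one or more chromosomes.
make_genes <- function(tss, chromosome = "chrI", strand = NULL,
                       prefix = "g") {
  n <- length(tss)
  if (is.null(strand)) strand <- rep("+", n)
  as_gene_table(data.frame(
    gene_id = sprintf("%s%03d", prefix, seq_len(n)),
    chromosome = chromosome,
    start = ifelse(strand == "+", tss, pmax(1, tss - 500)),
    end = ifelse(strand == "+", tss + 500, tss),
    strand = strand,
    biotype = "protein_coding",
    stringsAsFactors = FALSE))
}

# Brute-force neighbor enumeration: all pairs with rank gap <= k in the
# TSS-sorted order, per chromosome.
neighbor_pairs_oracle <- function(genes, k) {
  out <- 0L
  for (chrom in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chrom, ]
    g <- g[order(g$tss, g$gene_id), ]
    n <- nrow(g)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (j - i <= k) out <- out + 1L
      }
    }
  }
  out
}

# Small simulation config for fast tests.
small_config <- function(...) {
  simulation_config(n_chromosomes = 2L, genes_per_chromosome = 300L,
                    n_experiments = 50L, ...)
}
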