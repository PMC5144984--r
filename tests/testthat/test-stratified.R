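gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

# Per-bp bitmap oracle on a toy chromosome.
bitmap <- function(g, len = 10000) {
  x <- logical(len)
  for (i in seq_along(g)) {
    s <- max(1, GenomicRanges::start(g)[i])
    e <- min(len, GenomicRanges::end(g)[i])
    if (s <= e) x[s:e] <- TRUE
  }
  x
}

test_that("replicate intersection is exact interval algebra", {
  out <- intersect_replicates(gr("chr1", 100, 200), gr("chr1", 150, 300))
  expect_equal(GenomicRanges::start(out), 150)
  expect_equal(GenomicRanges::end(out), 200)
  expect_warning(
    empty <- intersect_replicates(gr("chr1", 1, 10), gr("chr1", 50, 60)),
    "empty")
  expect_equal(length(empty), 0L)
})

test_that("intersection matches a per-bp bitmap oracle and its algebra", {
  set.seed(71)
  rand_set <- function() {
    s <- sample.int(9900, 300, replace = TRUE)
    GenomicRanges::reduce(gr("toy", s, s + sample.int(120, 300, replace = TRUE)))
  }
  a <- rand_set(); b <- rand_set(); c <- rand_set()
  ab <- suppressWarnings(intersect_replicates(a, b))
  expect_identical(bitmap(ab), bitmap(a) & bitmap(b))
  # commutative, idempotent, associative on the bitmap
  expect_identical(bitmap(suppressWarnings(intersect_replicates(b, a))),
                   bitmap(ab))
  expect_identical(bitmap(suppressWarnings(intersect_replicates(a, a))),
                   bitmap(a))
  expect_identical(
    bitmap(suppressWarnings(intersect_replicates(ab, c))),
    bitmap(suppressWarnings(intersect_replicates(
      a, suppressWarnings(intersect_replicates(b, c))))))
})

test_that("flanking flags mark sites between TSSs only", {
  genes <- make_genes(c(1000, 5000))
  pairs <- neighbor_pairs(genes, k = 1)
  flagged <- flag_flanked_pairs(pairs, genes,
                                list(f = gr("chrI", 2000, 2100)))
  expect_true(flagged$flanked_f)
  outside <- flag_flanked_pairs(pairs, genes,
                                list(f = gr("chrI", 6000, 6100)))
  expect_false(outside$flanked_f)
  expect_error(
    flag_flanked_pairs(pairs, genes, list(f = gr("chrX", 1, 10))),
    "shared chromosome")
})

test_that("flanking flags match a quadratic scan and ignore member order", {
  set.seed(72)
  genes <- make_genes(cumsum(sample.int(4000, 40)))
  pairs <- neighbor_pairs(genes, k = 6)
  s <- sample.int(max(genes$tss), 60)
  sites <- gr("chrI", s, s + sample.int(300, 60, replace = TRUE))
  flagged <- flag_flanked_pairs(pairs, genes, list(f = sites))
  tss_of <- setNames(genes$tss, genes$gene_id)
  oracle <- vapply(seq_len(nrow(pairs)), function(p) {
    lo <- min(tss_of[pairs$gene_a[p]], tss_of[pairs$gene_b[p]])
    hi <- max(tss_of[pairs$gene_a[p]], tss_of[pairs$gene_b[p]])
    any(GenomicRanges::end(sites) >= lo + 1 &
          GenomicRanges::start(sites) <= hi - 1)
  }, logical(1))
  expect_equal(flagged$flanked_f, oracle)
  swapped <- pairs
  swapped$gene_a <- pairs$gene_b
  swapped$gene_b <- pairs$gene_a
  expect_equal(flag_flanked_pairs(swapped, genes, list(f = sites))$flanked_f,
               flagged$flanked_f)
})

test_that("distance windows subset groups and flag empty ones", {
  set.seed(73)
  mk <- function(n, dmin, dmax) {
    data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
               distance_bp = runif(n, dmin, dmax), rho = rnorm(n, 0.1, 0.05))
  }
  groups <- list(g1 = mk(300, 0, 50000), g2 = mk(300, 0, 50000))
  all_in <- distance_window_subset(groups, 0, 60000, n_boot = 100)
  expect_equal(unname(all_in$n), c(300L, 300L))   # identity window
  win <- distance_window_subset(groups, 30000, 40000, n_boot = 100)
  expect_true(all(vapply(win$groups, function(g)
    all(g$distance_bp >= 30000 & g$distance_bp < 40000), logical(1))))
  groups$g3 <- mk(50, 0, 10000)
  expect_error(distance_window_subset(groups, 30000, 40000), "g3")
})

test_that("histogram matching equalizes distance distributions", {
  set.seed(74)
  near <- data.frame(gene_a = "x", gene_b = "y",
                     distance_bp = rexp(3000, 1 / 5000) + 100,
                     rho = rnorm(3000, 0.2, 0.05))
  far <- data.frame(gene_a = "x", gene_b = "y",
                    distance_bp = rexp(2000, 1 / 12000) + 100,
                    rho = rnorm(2000, 0.2, 0.05))
  cmp <- histogram_matched_sample(list(near = near, far = far),
                                  bin_width = 1000, seed = 5, n_boot = 100)
  expect_true(all(cmp$ks_vs_reference <= 0.05))
  expect_equal(nrow(cmp$groups$near), nrow(cmp$groups$far))
  # identical groups pass through with KS exactly 0
  self <- histogram_matched_sample(list(a = near, b = near),
                                   bin_width = 1000, seed = 6, n_boot = 100)
  expect_equal(unname(self$ks_vs_reference), c(0, 0))
  # disjoint supports cannot be matched
  lo <- near; lo$distance_bp <- runif(3000, 0, 1000)
  hi <- near; hi$distance_bp <- runif(3000, 5000, 9000)
  expect_error(histogram_matched_sample(list(lo = lo, hi = hi),
                                        bin_width = 500, seed = 7),
               "disjoint")
})
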