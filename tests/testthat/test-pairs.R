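test_that("neighbor pair counts follow the rank-window formula and oracle", {
  # tiny cases by hand
  expect_equal(nrow(neighbor_pairs(make_genes(c(10, 20, 30)), k = 100)), 3L)
  expect_equal(nrow(neighbor_pairs(make_genes(seq(10, 50, by = 10)), k = 1)), 4L)
  # formula and brute force across sizes
  set.seed(7)
  for (case in list(c(n = 200, k = 7), c(n = 300, k = 20), c(n = 37, k = 5))) {
    n <- case[["n"]]; k <- case[["k"]]
    genes <- make_genes(cumsum(sample.int(5000, n)))
    pairs <- neighbor_pairs(genes, k = k)
    formula <- sum(pmin(seq_len(n - 1), k))
    expect_equal(nrow(pairs), formula)
    expect_equal(nrow(pairs), neighbor_pairs_oracle(genes, k))
    expect_true(all(pairs$rank_separation >= 1 & pairs$rank_separation <= k))
  }
  expect_error(neighbor_pairs(make_genes(c(1, 2)), k = 0), "k must be")
})

test_that("pairs never span chromosomes, self-pair, or repeat", {
  set.seed(8)
  genes <- rbind(make_genes(cumsum(sample.int(2000, 80)), "chrA", prefix = "a"),
                 make_genes(cumsum(sample.int(2000, 60)), "chrB", prefix = "b"))
  genes <- as_gene_table(genes)
  pairs <- neighbor_pairs(genes, k = 10)
  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  expect_true(all(chrom_of[pairs$gene_a] == chrom_of[pairs$gene_b]))
  expect_true(all(pairs$gene_a != pairs$gene_b))
  key <- paste(pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b))
  expect_false(anyDuplicated(key) > 0)
  # gene_a is the upstream-by-tss member
  tss_of <- setNames(genes$tss, genes$gene_id)
  expect_true(all(tss_of[pairs$gene_a] <= tss_of[pairs$gene_b]))
})

test_that("TSS distance is strand-aware, symmetric, and shift-invariant", {
  a <- data.frame(chromosome = "chrI", tss = 1000)
  b <- data.frame(chromosome = "chrI", tss = 5000)
  expect_equal(intergenic_distance(a, b), 4000)
  # minus-strand partner: tss is its end coordinate
  gm <- as_gene_table(data.frame(gene_id = c("p", "m"), chromosome = "chrI",
                                 start = c(2000, 3000), end = c(2600, 6000),
                                 strand = c("+", "-"),
                                 biotype = "protein_coding"))
  expect_equal(abs(diff(gm$tss)), 4000)
  expect_error(intergenic_distance(a, data.frame(chromosome = "chrII", tss = 1)),
               "chromosome")
  set.seed(9)
  for (i in 1:200) {
    t1 <- sample.int(1e7, 1); t2 <- sample.int(1e7, 1)
    x <- data.frame(chromosome = "c", tss = t1)
    y <- data.frame(chromosome = "c", tss = t2)
    expect_identical(intergenic_distance(x, y), intergenic_distance(y, x))
  }
  # global coordinate shift leaves pair distances unchanged
  genes <- make_genes(cumsum(sample.int(3000, 50)))
  shifted <- genes; shifted$tss <- shifted$tss + 123456
  p1 <- neighbor_pairs(genes, k = 5)
  p2 <- neighbor_pairs(shifted, k = 5)
  expect_equal(p1$distance_bp, p2$distance_bp)
})

test_that("orientation classes are correct, exhaustive, and exclusive", {
  expect_equal(classify_orientation("+", "+"), "parallel")
  expect_equal(classify_orientation("-", "-"), "parallel")
  expect_equal(classify_orientation("-", "+"), "divergent")
  expect_equal(classify_orientation("+", "-"), "convergent")
  set.seed(10)
  genes <- make_genes(cumsum(sample.int(2000, 100)),
                      strand = sample(c("+", "-"), 100, replace = TRUE))
  pairs <- neighbor_pairs(genes, k = 8)
  expect_true(all(pairs$orientation %in%
                    c("divergent", "parallel", "convergent")))
  strand_of <- setNames(genes$strand, genes$gene_id)
  redo <- classify_orientation(strand_of[pairs$gene_a], strand_of[pairs$gene_b])
  expect_equal(unname(redo), pairs$orientation)
})

test_that("operon pairs are removed and duplicate pairs flagged", {
  genes <- make_genes(seq(1000, 10000, by = 1000))
  ids <- genes$gene_id
  pairs <- neighbor_pairs(genes, k = 2)
  operons <- list(c(ids[1], ids[2]), c(ids[4], ids[5]))
  out <- suppressMessages(
    apply_pair_filters(pairs, operon_sets = operons))
  # same-operon pairs gone
  expect_false(any(out$gene_a == ids[1] & out$gene_b == ids[2]))
  expect_false(any(out$gene_a == ids[4] & out$gene_b == ids[5]))
  # cross-operon pair (ids[2], ids[4]) retained: different operons
  expect_true(any(out$gene_a == ids[2] & out$gene_b == ids[4]))
  expect_equal(nrow(out), nrow(pairs) - 2L)

  # duplicates: flag exactly the listed unordered pairs
  set.seed(11)
  dup_rows <- pairs[sample(nrow(pairs), 3), ]
  dups <- data.frame(gene_a = dup_rows$gene_b, gene_b = dup_rows$gene_a)
  flagged <- apply_pair_filters(pairs, duplicate_pairs = dups,
                                drop_operons = FALSE)
  expect_equal(sum(flagged$is_duplicate_pair), 3L)
  dropped <- suppressMessages(
    apply_pair_filters(pairs, duplicate_pairs = dups, drop_duplicates = TRUE))
  expect_equal(nrow(dropped), nrow(pairs) - 3L)
  # unknown ids warn but do not error
  expect_warning(
    apply_pair_filters(pairs, operon_sets = list(c("nope1", "nope2")),
                       known_genes = ids),
    "absent")
})
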