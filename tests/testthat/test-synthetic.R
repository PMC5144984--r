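test_that("simulated genomes are deterministic, sorted, and complete", {
  cfg <- small_config(seed = 81)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 600L)
  expect_false(anyDuplicated(g1$gene_id) > 0)
  for (chrom in unique(g1$chromosome)) {
    tss <- g1$tss[g1$chromosome == chrom]
    expect_true(all(diff(tss) > 0))
  }
  g3 <- simulate_genome(cfg, seed = 82)
  expect_false(identical(g1$tss, g3$tss))
})

test_that("orientation confound puts divergent pairs in small gaps", {
  med_gap <- function(seed, confound) {
    cfg <- small_config(orientation_confound = confound, seed = seed)
    genes <- simulate_genome(cfg)
    pairs <- neighbor_pairs(genes, k = 1)
    c(div = median(pairs$distance_bp[pairs$orientation == "divergent"]),
      con = median(pairs$distance_bp[pairs$orientation == "convergent"]))
  }
  gaps <- vapply(1:10, med_gap, numeric(2), confound = TRUE)
  expect_true(all(gaps["div", ] < gaps["con", ]))
  # without the confound the gap is not systematically ordered
  null_gaps <- vapply(1:10, med_gap, numeric(2), confound = FALSE)
  expect_gt(sum(null_gaps["div", ] >= null_gaps["con", ]), 1)
})

test_that("pure-noise expression has no neighbor correlation", {
  cfg <- small_config(amplitude = 0, baseline = 0, seed = 83)
  genes <- simulate_genome(cfg)
  expr <- simulate_expression(genes, cfg)
  ranks <- rank_by_experiment(expr)
  cors <- pair_correlations(ranks, neighbor_pairs(genes, k = 5))
  expect_lt(abs(median(cors$rho)), 2 / sqrt(cfg$n_experiments))
})

test_that("the latent kernel reaches the configured amplitude at zero gap", {
  # adjacent genes 1 bp apart with delta = 10 kb: phi ~ 1, correlation ~ a;
  # distant filler genes keep the TPM closure from tying the pair together
  genes <- make_genes(c(1000, 1001, seq(2e6, 2e6 + 99e6, by = 1e6)))
  cfg <- simulation_config(n_chromosomes = 1, genes_per_chromosome = 2,
                           amplitude = 0.5, baseline = 0,
                           n_experiments = 3000, seed = 84)
  expr <- simulate_expression(genes, cfg)
  rho <- spearman_rho(expr[1, ], expr[2, ])
  # Spearman of a bivariate normal at rho = 0.5: (6/pi) asin(0.25) ~ 0.483
  expect_equal(rho, (6 / pi) * asin(0.25), tolerance = 0.05)
})

test_that("the autoregressive construction reproduces the target kernel", {
  # near-pure latent field so observed correlations expose the kernel
  cfg <- simulation_config(n_chromosomes = 1, genes_per_chromosome = 150,
                           amplitude = 0.97, baseline = 0,
                           n_experiments = 500, delta = 10000, seed = 85)
  genes <- simulate_genome(cfg)
  expr <- simulate_expression(genes, cfg)
  x <- log(expr)  # undo the exponential link (monotone, Pearson-friendly)
  cc <- cor(t(x))
  d <- abs(outer(genes$tss, genes$tss, "-"))
  target <- 0.97 * exp(-d / cfg$delta)
  off <- upper.tri(cc)
  expect_lt(max(abs(cc[off] - target[off])), 3 / sqrt(500) + 0.05)
})

test_that("binned Spearman medians track the configured decay curve", {
  cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 1000,
                           seed = 86)
  genes <- simulate_genome(cfg)
  expr <- simulate_expression(genes, cfg)
  ranks <- rank_by_experiment(expr)
  cors <- pair_correlations(ranks, neighbor_pairs(genes, k = 50))
  bins <- cut(cors$distance_bp, c(0, 5000, 10000, 20000, 50000, 150000))
  med <- tapply(cors$rho, bins, median)
  dmid <- tapply(cors$distance_bp, bins, median)
  target <- cfg$amplitude * exp(-dmid / cfg$delta) + cfg$baseline
  # rank attenuation + factor-block mixture allow a modest band
  expect_lt(max(abs(med - target)), 0.12)
  expect_true(all(diff(med) < 0))
})

test_that("insulator placement follows the gap-size confound only when on", {
  flank_gaps <- function(seed, confound) {
    cfg <- small_config(insulator_confound = confound, seed = seed)
    genes <- simulate_genome(cfg)
    pairs <- neighbor_pairs(genes, k = 1)
    ins <- simulate_insulators(genes, cfg)
    sites <- suppressWarnings(
      intersect_replicates(ins[[1]]$rep1, ins[[1]]$rep2))
    fl <- flag_flanked_pairs(pairs, genes, list(f = sites))$flanked_f
    c(fl = median(pairs$distance_bp[fl]), un = median(pairs$distance_bp[!fl]))
  }
  on <- vapply(1:8, flank_gaps, numeric(2), confound = TRUE)
  expect_true(all(on["fl", ] > on["un", ]))
  # confound off: placement probability is flat, but only wide gaps can hold
  # a site, so compare against the placeable-gap distribution via KS
  cfg <- small_config(insulator_confound = FALSE, seed = 90)
  genes <- simulate_genome(cfg)
  pairs <- neighbor_pairs(genes, k = 1)
  ins <- simulate_insulators(genes, cfg)
  sites <- suppressWarnings(intersect_replicates(ins[[1]]$rep1, ins[[1]]$rep2))
  fl <- flag_flanked_pairs(pairs, genes, list(f = sites))$flanked_f
  placeable <- pairs$distance_bp > cfg$site_width + 2 * (cfg$replicate_jitter + 2)
  ks <- suppressWarnings(stats::ks.test(pairs$distance_bp[fl & placeable],
                                        pairs$distance_bp[!fl & placeable]))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero replicate jitter makes replicates identical", {
  cfg <- small_config(replicate_jitter = 0, seed = 87)
  genes <- simulate_genome(cfg)
  ins <- simulate_insulators(genes, cfg)
  r1 <- ins[[1]]$rep1
  r2 <- ins[[1]]$rep2
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
  inter <- intersect_replicates(r1, r2)
  expect_equal(length(inter), length(GenomicRanges::reduce(r1)))
})

test_that("tissue sets lose spatial structure as delta_t vanishes", {
  cfg <- small_config(delta_t = 1, seed = 88)   # 1 bp: no neighbor memory
  genes <- simulate_genome(cfg)
  ann <- simulate_tissue_annotations(genes, cfg)
  pairs <- neighbor_pairs(genes, k = 1)
  both <- pairs$gene_a %in% names(ann) & pairs$gene_b %in% names(ann)
  neigh <- vapply(which(both), function(p) {
    tissue_overlap(ann[[pairs$gene_a[p]]], ann[[pairs$gene_b[p]]])
  }, numeric(1))
  set.seed(89)
  ids <- names(ann)
  rand <- vapply(1:400, function(i) {
    ab <- sample(ids, 2)
    tissue_overlap(ann[[ab[1]]], ann[[ab[2]]])
  }, numeric(1))
  expect_lt(abs(mean(neigh) - mean(rand)), 3)
})

test_that("genes at identical positions get identical tissue sets", {
  genes <- make_genes(c(5000, 5000, 40000))
  cfg <- simulation_config(n_chromosomes = 1, genes_per_chromosome = 3,
                           seed = 91)
  ann <- simulate_tissue_annotations(genes, cfg)
  if (all(genes$gene_id[1:2] %in% names(ann))) {
    expect_setequal(ann[[genes$gene_id[1]]], ann[[genes$gene_id[2]]])
  }
})

test_that("write_simulation emits a consumable on-disk bundle", {
  dir <- tempfile("simbundle")
  cfg <- small_config(seed = 92)
  objs <- suppressWarnings(write_simulation(cfg, dir))
  genes <- load_gene_annotation(file.path(dir, "genes.tsv"), format = "tsv")
  expect_equal(genes$gene_id, objs$genes$gene_id)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(objs$expression))
  expect_equal(unname(expr[3, 4]), unname(objs$expression[3, 4]),
               tolerance = 1e-6)
  ann <- read_tissue_annotations(file.path(dir, "tissues.tsv"))
  expect_equal(length(ann), length(objs$tissues))
  bed <- read_interval_bed(file.path(dir, "insulator_insA_rep1.bed"))
  expect_equal(length(bed), length(objs$insulators$insA$rep1))
  expect_equal(GenomicRanges::start(bed),
               GenomicRanges::start(objs$insulators$insA$rep1))
  ops <- read_operon_list(file.path(dir, "operons.tsv"))
  expect_equal(ops, objs$fixtures$operons)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$delta, cfg$delta)
})
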