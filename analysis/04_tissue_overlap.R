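#!/usr/bin/env Rscript
# Spatial (in situ style) analysis: percentage tissue overlap
# (100 * common / unique tissues) for every doubly-annotated neighbor
# pair, smoothed and fitted with the same sliding-median / exponential
# stack as the expression correlations. The generator's tissue identity
# decays at delta_t = 20 kb. Run analysis/01_simulate.R first.

library(coexdecay)

sim_dir <- "results/sim"
out_dir <- "results/tissue"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genes <- load_gene_annotation(file.path(sim_dir, "genes.tsv"), format = "tsv")
ann <- read_tissue_annotations(file.path(sim_dir, "tissues.tsv"))
truth <- jsonlite::read_json(file.path(sim_dir, "ground_truth.json"))

pairs <- neighbor_pairs(genes, k = 100)
res <- overlap_vs_distance(ann, pairs, window = 1000)

write_curve(res$curve, file.path(out_dir, "overlap_curve.tsv"))
write_fit(res$fit, file.path(out_dir, "overlap_fit.json"))

cat(sprintf("%d of %d genes annotated; %d doubly-annotated pairs scored\n",
            length(ann), nrow(genes), nrow(res$pairs)))
print(res$fit)
cat(sprintf("generating delta_t was %s bp -> recovery ratio %.3f\n",
            truth$delta_t, res$fit$dexp / as.numeric(truth$delta_t)))
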