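# coexdecay

Genome-wide analysis of how the transcriptional correlation of neighboring
genes decays with the distance between them.

Across eukaryotes, genes that sit close together on a chromosome tend to be
expressed together, plausibly because nearby promoters share enhancers by
physical proximity. `coexdecay` is for computational biologists who want to
quantify that effect in an annotated genome plus an RNA-seq compendium: it
measures the correlation-versus-distance relationship, estimates the
characteristic distance over which neighbors stay correlated, and runs the
distance-controlled comparisons needed to tell a genuine group effect
(gene orientation, insulator binding) from a distance confound.

## The statistic and the model

Every protein-coding gene is paired with its *k* = 100 nearest neighbors on
the same chromosome (rank window in TSS-sorted order; same-operon pairs
removed, duplicated pairs optionally removed). For each pair the package
computes the Spearman correlation across experiments,

    rho = cov(r1, r2) / (sd(r1) sd(r2)),

where `r1`, `r2` are the genes' within-experiment expression ranks (TPM
scale; genes detected in < 80% of experiments are discarded). Pairs sorted
by intergenic distance *d* (strand-aware TSS-to-TSS) are smoothed with a
1000-pair sliding median and fit to an exponential decay

    rho(d) = rho0 * exp(-lambda * d) + c,      dexp = 1 / lambda,

so `dexp` is the mean distance over which a pair of neighbors remains
correlated above the baseline `c`. A cross-chromosome background (20 random
partners per gene, bootstrap CI of the median) anchors the baseline, and
group comparisons (divergent/parallel/convergent orientation;
insulator-flanked versus not) are re-run under two distance controls: a
shared 30–40 kb window and histogram matching of the distance
distributions.

Everything is exercisable end to end on a built-in synthetic genome whose
expression has a known Ornstein–Uhlenbeck correlation structure
(`correlation = amplitude * exp(-d/delta) + baseline`), with optional
orientation/insulator confounds that have no direct expression effect —
the ground truth the pipeline must recover. See the methods vignette
(`vignettes/neighbor-coexpression-decay.Rmd`) for the design choices and
calibrations.

## Worked example

Simulate the default study conditions (4 chromosomes x 1,000 genes,
200 experiments, delta = 10 kb, amplitude 0.3, baseline 0.05) and run the
full pipeline:

```r
library(coexdecay)

cfg   <- simulation_config(seed = 1)
genes <- simulate_genome(cfg)
expr  <- simulate_expression(genes, cfg)
res   <- run_neighbor_analysis(genes, expr, background = TRUE,
                               n_boot = 10000, seed = 1)
print(res$fit)
str(res$background)
```

```
Exponential decay fit: rho(d) = rho0 * exp(-lambda d) + c
  rho0   = 0.4686
  lambda = 0.0001067 per bp
  c      = 0.04133
  dexp   = 9368 bp
  rss    = 30.64 over 378801 points
List of 6
 $ median_rho: num 0.0421
 $ ci_low    : num 0.0403
 $ ci_high   : num 0.044
 $ n_pairs   : int 80000
 $ n_boot    : int 10000
 $ seed      : int 1
```

The fitted `dexp` of 9,368 bp recovers the generating correlation length of
10 kb within 7%; the baseline `c` (0.041) agrees with the independent
cross-chromosome background median (0.042, CI [0.040, 0.044]) — neighbors
further apart than a few `dexp` are no more correlated than random
cross-chromosome pairs. The fitted `rho0` reads higher than the generating
amplitude for reasons explained in the vignette (rank-domain attenuation of
the baseline factor).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow writing tables under `results/`: `01_simulate.R` (synthetic
dataset bundle on disk), `02_neighbor_decay.R` (decay curve, fit,
background; a diagnostic figure if ggplot2 is available),
`03_stratified.R` (orientation and insulator contrasts, raw and
distance-controlled), `04_tissue_overlap.R` (in situ style tissue-overlap
decay, `dexp` on the spatial axis).

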