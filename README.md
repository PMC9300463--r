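# baitminer

Bait-anchored co-expression mining for biosynthetic pathway gene discovery.

## What problem this solves

Genes of plant specialized-metabolism pathways — such as the monoterpene
indole alkaloid pathway that makes strychnine, brucine and diaboline in
*Strychnos* species — are typically co-regulated with each other and
expressed preferentially in the tissue where the metabolites accumulate
(here, the roots). When a few pathway members are known, the rest can be
nominated from multi-tissue RNA-seq alone by a chain of thresholded set
operations:

1. **tissue filter** — mean root FPKM ≥ 20 (inclusive),
2. **co-expression filter** — Pearson *r* of `log2(FPKM + 1)` against one
   bait gene (*r* ≥ 0.95) or against several baits simultaneously
   (*r* > 0.6, intersection), and
3. **family filter** — full-length members of enzyme families that fit the
   missing chemistry (P450, α/β hydrolase, MDR, BAHD, OMT).

`baitminer` implements this screen and the stages that surround it in a
discovery campaign, for computational biologists who want the procedure as
tested, reusable functions rather than a one-off analysis:

* FPKM quantification (`compute_fpkm`), tissue summaries and filters
  (`tissue_mean`, `filter_expressed`);
* bait-anchored co-expression sets and multi-bait intersections
  (`bait_set`, `multi_bait_set`), candidate tables (`select_candidates`);
* global protein alignment with affine gaps (Needleman–Wunsch, BLOSUM62,
  gap open/extend 11/1; Rcpp kernel), percent identity under explicit
  denominator conventions, and reciprocal-best-hit orthologue maps between
  producer and non-producer proteomes (`global_align`, `percent_identity`,
  `reciprocal_best_hits`, `comparative_presence`);
* neighbor-joining trees from identity distances and outgroup-rooted clade
  tests (`neighbor_joining`, `is_monophyletic`);
* Michaelis–Menten fits of initial-rate data with delta-method errors, and
  catalytic-efficiency (`kcat/Km`) comparisons (`fit_mm`,
  `compare_efficiency`);
* a synthetic-data generator that plants a known root-preferential pathway
  module inside a negative-binomial transcriptome, plus orthologous
  proteomes at controlled identity and simulated kinetics
  (`simulate_transcriptome`, `mutate_orthologue`, `simulate_kinetics`) —
  so every stage can be validated against ground truth;
* an end-to-end, seed-deterministic pipeline (`run_discovery`) driven by a
  single YAML/R configuration, with a thin CLI at
  `inst/scripts/baitminer-cli.R`.

The model at the core of the screen is simply the sample Pearson
correlation on log-scale FPKM combined with inclusive thresholding; the
model at the core of the kinetics stage is the steady-state
Michaelis–Menten rate law *v* = *k*~cat~·E₀·S/(*K*~m~ + S), reported as
*k*~cat~, *K*~m~ and the efficiency *k*~cat~/*K*~m~.

## Worked example

```r
library(baitminer)

d <- simulate_transcriptome(sim_config(n_genes = 1000, pathway_size = 10, seed = 1))
d
#> synthetic_dataset: 1000 genes x 6 samples (3 tissues), 10 planted module genes, bait gene00032

expr <- compute_fpkm(counts_matrix(d$counts, d$gene_lengths, d$design))
coex <- bait_set(expr, d$bait_id, 0.95)
coex
#> coexpression_result: 11 member(s) at r >= 0.95 against bait(s) gene00032

ann <- gene_annotations(data.frame(
  gene_id = rownames(d$counts),
  family = ifelse(rownames(d$counts) %in% d$truth_module, "P450", "other"),
  full_length = TRUE))
tab <- select_candidates(expr, ann, baits = d$bait_id, family = "P450")
head(tab[, c("gene_id", "family", "root_mean_fpkm", "min_r")])
#>     gene_id family root_mean_fpkm     min_r
#> 1 gene00032   P450       6456.319 1.0000000
#> 2 gene00126   P450       5269.473 0.9785330
#> 3 gene00716   P450       7910.980 0.9751217
#> 4 gene00122   P450       7151.843 0.9749559
#> 5 gene00097   P450       4493.151 0.9743869
#> 6 gene00389   P450      18623.130 0.9731267
all(tab$gene_id %in% d$truth_module)
#> [1] TRUE
```

The screen at FPKM ≥ 20 and *r* ≥ 0.95 returns 11 genes: the 10 planted
pathway genes (the bait at *r* = 1, members at *r* ≈ 0.97) and here a single
background gene — the kind of near-threshold passenger a real screen also
admits. The candidate table is ranked by the minimum correlation over baits,
ties broken by root expression.

Kinetics of one enzyme against two alternative substrates:

```r
S <- c(1, 2, 5, 10, 20, 50)                      # uM
fit5 <- fit_mm(simulate_kinetics(2.97, 10, 0.1, S))   # kcat/Km = 0.297
fit4 <- fit_mm(simulate_kinetics(0.68, 10, 0.1, S))   # kcat/Km = 0.068
compare_efficiency(fit5, fit4)$ratio
#> [1] 4.367647
```

i.e. a ~4.4-fold preference for the first substrate.

## Method details

The methods vignette (`vignettes/pathway-discovery-methods.Rmd`) documents
the generative model of the synthetic transcriptome (shared latent state,
fixed-norm perturbation frame, calibration of the within-module
correlation), the alignment conventions (tie-breaks, gap model, identity
denominators), the tree and kinetics choices, and the limitations of
planted-truth validation.
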