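# fragmark

Fragment-level methylation marker discovery and cfDNA lung-cancer
subtyping in R.

Lung adenocarcinoma (LUAD) and lung squamous cell carcinoma (LUSC) call
for different treatments, but tissue biopsies are invasive. Plasma
cell-free DNA (cfDNA) contains a small fraction of tumor-derived
fragments whose methylation retains the tumor subtype. `fragmark`
implements the full analysis path for MspI-enrichment bisulfite assays
(RRBS in tissue, cfMethyl-Seq in plasma):

- **In-silico MspI digestion** of a genome FASTA into the CpG-enriched
  regions between adjacent CCGG cut sites (< 350 bp) that these assays
  cover.
- **Fragment-based marker discovery.** Each fragment's alpha value is
  the fraction of methylated CpGs it carries. Per region and direction
  the scan picks a threshold alpha\* over the observed alpha support:
  fragments with alpha <= alpha\* (hypo) or >= alpha\* (hyper) are
  subtype-specific reads; a candidate marker needs fewer than two
  other-subtype samples with such reads (n_other < 2), is ranked by the
  number of target-subtype samples with them (n_target), filtered
  against noncancer plasma (> 20% background carriers removed), and the
  top 2,500 per (class, direction) cell are kept, ties included.
- **Merged-marker features.** Size-constrained K-means pools 45-55
  markers per cluster; a sample's feature per merged marker is
  ln(mean(1e9 x count / total fragments) + 1).
- **Classification.** L2-penalised logistic regression (C = 0.1),
  pooled-ROC leave-one-out or stratified 10-fold cross-validation,
  Mann-Whitney AUC with DeLong 95% confidence intervals.
- **Marker validation.** Fold-change reproducibility in an independent
  fragment cohort; 450K probe-to-region mapping, region-averaged beta,
  Student t + Benjamini-Hochberg; promoter-overlap gene association
  with an empirical differential-expression p value against 500 random
  gene sets.
- **Copy-number reporting.** Gain/loss thresholding of per-bin log2
  ratios (+/-0.3, strict), 9p21.3 (CDKN2A/B, MTAP) loss detection, and
  tumor-fraction-stratified accuracy (detectable >= 3%).
- **A seeded synthetic-data generator** (beta-binomial fragment
  methylation, planted subtype markers, tumor purity in tissue,
  tumor-fraction mixtures in plasma) standing in for the
  controlled-access cohorts, so the whole pipeline is testable offline.

## Worked example

```r
library(fragmark)

# a stated synthetic world: 10,000 regions, 200 planted markers
# (50 per LUAD/LUSC x hypo/hyper cell), 30 tissue samples per subtype
# at purity 0.6 and depth 50, 30 noncancer plasma samples
world <- synthetic_discovery_world(seed = 1)

markers <- discover_markers(world$luad, world$lusc, world$background, k = 50)
table(markers$target_class, markers$direction)
#>        hyper hypo
#>   LUAD    50   50
#>   LUSC    50   50
unlist(marker_recovery(markers, world$truth)[c("precision", "recall")])
#> precision    recall
#>         1         1

merged <- build_merged_markers(markers, c(world$luad, world$lusc), seed = 1)
evaluate_plasma_classification(world, merged, theta = 0.10, seed = 3)
#> <roc_result> loocv: AUC 1.000 (95% DeLong CI 1.000-1.000), accuracy 1.000, n = 60
```

Every marker satisfies its invariants (`n_other < 2`,
`bg_fraction <= 0.2`); at tumor fraction 0.10 and ~22x plasma depth the
planted subtype signal separates the cohorts completely, and at
tumor fraction 0 the features degenerate to zero (see the vignette for
why pooled LOOCV then reports an AUC far *below* 0.5 — a known
estimator artifact, not signal).

A command-line front end wraps the same API:

```sh
Rscript -e 'fragmark::fragmark_cli()' -- digest --fasta genome.fa --out regions.bed
Rscript -e 'fragmark::fragmark_cli()' -- discover --luad luad.tsv --lusc lusc.tsv \
    --background nc.tsv --k 2500 --out markers.tsv
```

## Package layout

- `R/` — digestion, io, synthetic generator, discovery, features,
  classifier, validation, CNA, CLI
- `tests/testthat/` — unit + property tests per module, brute-force
  oracles in `helper-fixtures.R`, acceptance criteria in
  `test-acceptance.R`
- `vignettes/fragment-methylation-subtyping.Rmd` — methods notes:
  model, parameters, synthetic-world assumptions, numerical choices,
  known limitations
- `scripts/acceptance.R` — the acceptance report
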