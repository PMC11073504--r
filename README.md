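# hallmarkTasks

Transcription and translation are decoupled in eukaryotes, and mRNA
abundance is only a moderate predictor of protein abundance. Treating
cancer cell lines as lineages with a shared origin and divergent
evolutionary histories, and the ten cancer hallmarks as *tasks* a cell can
specialize in, this package quantifies where that decoupling concentrates
and what it costs in growth. It is aimed at computational biologists with
paired gene-level mRNA (RPKM-like) and protein (MS-intensity-like)
profiles of a cell-line panel, plus division rates and drug-response data.

The pipeline computes, per cell line:

* **Concordance** — the Pearson/Spearman correlation of each cell's mRNA
  profile with every cell's protein profile over the shared genes. The
  diagonal ("same cell") is contrasted with the off-diagonal ("other
  cells") by a Welch *t*-test and a one-sided Kolmogorov–Smirnov *D*⁺, and
  hallmark-restricted correlations are contrasted with a 500-gene random
  set by per-hallmark Wilcoxon rank-sum tests and a one-way ANOVA.
* **Task enrichment** — a preranked gene-set enrichment per cell and
  modality. With genes ranked by abundance and member weights
  *w*ᵢ = |*s*ᵢ|ᵖ (default *p* = 1 on log₂-scaled abundance), the running
  sum gains *w*ᵢ/*N*ᴿ at members and loses 1/(*N* − *N*ₕ) at non-members;
  the enrichment score ES ∈ [−1, 1] is its signed extreme. A gene-label
  permutation null gives NES = ES / mean(same-sign |null ES|), one-tailed
  permutation *p*, and Benjamini–Hochberg *q* per ranked list (threshold
  FDR < 0.2).
* **Decoupling statistics** — the per-(cell, hallmark) difference
  Δ = NES(mRNA) − NES(protein) (sign convention configurable) with a
  pooled bootstrap null for each hallmark's mean difference
  (*N* = 10,000 draws), and the per-(cell, modality) enrichment range
  max NES − min NES.
* **Growth associations** — Pearson correlations of Δ and range with
  division rate and per-(cell, drug) growth inhibition; a
  hallmark-fixed-factor OLS of division rate on Δ returning the common
  slope (the fixed effect of decoupling on growth); per-hallmark OLS
  slopes; ECDF comparisons (standard *D* plus the scaled
  √(*nm*/(*n*+*m*))·*D* variant).

A synthetic-cohort generator (`generateCohort()`) emulates the statistical
structure of paired LINCS-style breast-cancer panels — 32 cell lines,
~3,000 genes, same-cell mRNA–protein coupling 0.6 inside hallmarks versus
0.25 outside, elevated hallmark transcription, translation-selective
hallmarks whose transcription boost never reaches protein, a −1.88 linear
effect of decoupling on division rate, and drug inhibition independent of
all of it — and returns the generating truth for parameter-recovery tests.

## Worked example

```r
library(hallmarkTasks)

cohort <- generateCohort(cohortParams(nCells = 8, nGenes = 1500, seed = 1))

cc <- crossCorrelation(cohort$mrna, cohort$protein)
cc
#> CorrelationMatrix (pearson, 1500 genes): 8 x 8 cells
#>   same-cell mean 0.293, other-cell mean 0.219
sameVsOther(cc)$welch
#>   statistic_name statistic       df      p_value direction
#> 1        welch_t  11.30332 9.019962 1.255607e-06 two_sided

rec <- enrichAllCells(cohort$mrna, cohort$protein, cohort$geneSets,
                      nPerm = 200, seed = 2)
stats <- taskStatistics(rec[rec$modality == "mRNA", ],
                        rec[rec$modality == "protein", ])
stats
#> TaskStats (mrna_minus_protein): 80 (cell, set) deltas, 16 ranges
#>   mean delta 0.473; mean range 0.634

d <- deltaTable(stats)[deltaTable(stats)$set_name == "Resisting_Cell_Death", ]
bt <- bootstrapDeltaTest(d$nes_mrna, d$nes_protein, nBoot = 10000, seed = 3)
sprintf("MD = %.3f, bootstrap p = %.4f", bt$observed_md, bt$p_value)
#> [1] "MD = 0.419, bootstrap p = 0.0012"

fixedEffectModel(deltaTable(stats), cohort$growth)
#>      estimate std_error   p_value df               model  n
#> 1 -0.07787955 0.3106245 0.8027763 69 pooled_fixed_effect 80
```

Reading the output: each cell's mRNA profile agrees with its own protein
profile (mean r = 0.29) more than with other cells' (0.22); the Welch test
confirms the gap (t = 11.3, p ≈ 1e-06). The mean Δ of 0.47 says hallmark
enrichment is transcription-favored in this cohort, and the
death-resistance hallmark's mean difference (MD = 0.42) is far outside its
pooled bootstrap null (p = 0.0012). The fixed-effect slope on the
*realized* NES deltas is attenuated toward zero relative to the generating
−1.88 because the realized delta is a noisy estimate of the latent
decoupling — the recovery experiment in the test suite therefore regresses
on the generator's latent offsets (see the methods vignette).

The same analysis runs end to end from one config:

```r
runPipeline(list(simulate = list(), seed = 42), outputDir = "results_run")
```

or from the shell via the installed CLI
(`exec/hallmarktasks` under the installed package):

```sh
hallmarktasks run-all --config config.yaml --output-dir results_run
```

writing the cohort TSV/GMT files, `correlations.tsv`,
`setwise_correlations.tsv`, `enrichment.tsv`, `task_delta.tsv`,
`task_range.tsv`, `bootstrap_tests.tsv`, `associations.tsv`,
`effects.tsv`, a `report.json` of all test summaries, and a `MANIFEST` of
completed stages. Identical configs give byte-identical outputs.

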