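# pascloud

In-silico screening and ranking of candidate geroprotective drugs by
signaling-pathway-cloud regulation.

Aging shifts the transcriptome: relative to young tissue, many signaling and
metabolic pathways in old samples are activated or suppressed. `pascloud`
treats the collection of aging-associated pathways — the *pathway cloud* — as
the scoring unit. It quantifies, per pathway, how far an old expression
profile has drifted from the young reference, and then asks which drug (or
drug pair), modeled through fold-change effects on its target genes, pulls
that activation profile back toward the young state.

The package is aimed at computational biologists prototyping
signature-reversal drug screens on bulk (or pseudo-bulked single-cell)
expression data, and ships a fully synthetic data generator with known ground
truth so the entire pipeline is testable without any external downloads.

## The model

For a gene *n* in an old sample, with young-cohort mean and standard
deviation taken gene-wise over the (normalized) young samples:

- **OYR** (old-to-young ratio): `OYR_n = old_n / mean(young_n)`, with an
  epsilon floor (default 1e-6) on numerator and denominator.
- **BTIF** (beyond-tolerance-interval flag): 1 only if *both*
  `OYR_n > 3/2` or `OYR_n < 2/3`, *and*
  `|old_n − mean(young_n)| > 2 · sd(young_n)`; strict inequalities.
- **ARR** (activator/repressor role): a discrete per-gene weight in
  {−1, −0.5, 0, 0.5, 1} carried by each pathway definition.
- **PAS** (pathway activation strength), per pathway *p*:

  `PAS_p = Σ_n ARR_np · BTIF_n · log10(OYR_n)`

  A pathway whose genes all sit inside the tolerance interval scores exactly
  0. The multiplicative **SPCD** estimator
  `∏ activator levels / ∏ repressor levels` is exposed as well; its log is
  the additive form of the same quantity.
- **Disturbance** `D = ‖PAS‖` (L1 by default, L2 optional) over the cloud.
  Drugs are applied in silico as multiplicative fold-changes on their target
  genes in the old samples only, and ranked by the treated `D` of the
  mean-of-old PAS profile: the best candidate drives all PAS values as close
  to zero as possible.

The cloud itself can be built from an aging gene list by hypergeometric
over-representation analysis (`runORA`) with a minimum overlap of 2 genes
and a p < 0.01 cutoff, BH-FDR corrected; a 44-pathway KEGG enrichment
summary for a longevity-gene candidate list is bundled as a plain-text
reference fixture (`agingEnrichmentTable()`).

## Worked example

```r
library(pascloud)

sim <- simulateStudy(simulationConfig(seed = 42))   # 50 genes, 5 pathways,
                                                    # 5 young + 5 old samples,
                                                    # pathway 1 activated 4-fold
rep <- scoreStudy(sim$study, sim$cloud)
rep
#> DisturbanceReport: 5 pathway(s) x 5 old sample(s)
#>   norm L1, log base 10, epsilon 1e-06
#>   D (mean-of-old profile): 4.24
#>   per-sample D: 4.245, 4.031, 4.292, 4.283, 4.35
round(pasMean(rep), 3)
#> SIMP01 SIMP02 SIMP03 SIMP04 SIMP05
#>   4.24   0.00   0.00   0.00   0.00

lib <- simulateDrugLibrary(sim$truth)   # exact antidote + partial + 10
                                        # distractors + null drug
head(screenDrugs(sim$study, sim$cloud, lib$library), 4)
#>   rank          drug_id baseline_D treated_D delta
#> 1    1         antidote       4.24     0.000 4.240
#> 2    2 partial_antidote       4.24     1.509 2.731
#> 3    3    distractor_04       4.24     4.131 0.109
#> 4    4             null       4.24     4.240 0.000
```

The planted pathway (`SIMP01`) is the only one with a nonzero PAS — its
members moved 4-fold, coherently with their activator/repressor roles, so
the score is positive and every undisturbed pathway is exactly 0. The
screen ranks the exact antidote first with a treated disturbance of 0 (it
restores every old value to the young mean), the half-coverage antidote
second, and the null drug reproduces the baseline exactly.

File-based workflows use `readExpression()`, `readPathwayFile()` /
`importGMT()` and `readDrugLibrary()`; a thin command-line wrapper with
`pas`, `ora`, `screen` and `simulate` subcommands is installed at
`system.file("scripts", "pathcloud.R", package = "pascloud")`.

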