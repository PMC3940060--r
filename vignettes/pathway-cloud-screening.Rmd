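---
title: "Pathway-cloud disturbance scoring and in silico geroprotector screening"
author: "pascloud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-cloud disturbance scoring and in silico geroprotector screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascloud)
```

# The model

`pascloud` scores the difference between old and young transcriptomes not
gene-by-gene but pathway-by-pathway, over a *pathway cloud*: a curated
collection of signaling and metabolic pathways implicated in aging, each
member gene annotated with a discrete activator/repressor role (ARR) weight
in $\{-1, -0.5, 0, 0.5, 1\}$. The underlying assumption is a linear
signaling regime: signal-transduction proteins operate far from saturation,
so every activator or repressor contributes with equal importance and
pathway activation can be treated additively on a log scale, without
kinetic modeling.

For each gene $n$ in an old sample, against the young cohort of the same
tissue:

$$OYR_n = \frac{x_n^{old}}{\overline{x_n^{young}}}, \qquad
BTIF_n = \mathbf{1}\!\left[\left(OYR_n > \tfrac{3}{2} \lor OYR_n <
\tfrac{2}{3}\right) \land |x_n^{old} - \overline{x_n^{young}}| >
2\,\sigma_n^{young}\right]$$

$$PAS_p = \sum_{n \in p} ARR_{np} \cdot BTIF_n \cdot \log_{10} OYR_n$$

The double criterion in $BTIF$ is deliberately conservative: a gene must be
outside the 3/2–2/3 fold tolerance *and* more than two young-cohort standard
deviations from the young mean before it contributes at all. Consequently
$PAS_p = 0$ exactly for any pathway whose members all sit inside tolerance
— the score has a true null, not merely a small value.

The multiplicative estimator
$SPCD = \prod_i [AGEL]_i \,/\, \prod_j [RGEL]_j$ over a pathway's activator
and repressor expression levels is exposed as `computeSPCD()`; taking
logarithms turns it into exactly the additive form above (with unit ARR
magnitudes and all flags on), and the package asserts this identity in its
tests. The cloud-level objective is the cumulative disturbance
$D = \lVert PAS \rVert_1$ (L2 optional): $D = 0$ iff the old activation
profile is indistinguishable from the young state under the tolerance rules.

Drug screening applies each candidate as multiplicative fold-changes on its
target genes in the *old* samples only (the young reference is the
therapeutic goal and stays fixed), rescores, and ranks by treated $D$
ascending. Pairs are combined by gene-wise fold-change product.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `logBase` | 10 | — | only rescales PAS (base-2 values are base-10 values times $\log_2 10$), so rankings are base-invariant; 10 keeps "one unit = tenfold" readability. |
| `floor` ($\varepsilon$) | 1e-6 | expression units | floors numerator and denominator of every ratio and every factor of SPCD, so OYR and PAS are finite for unexpressed genes. Any value well below real expression levels behaves identically. |
| `norm` | `"L1"` | — | $D$ aggregates signed per-pathway scores; L1 rewards shrinking every pathway, L2 concentrates on the largest. The screening objective was stated only as "all PAS as close to zero as possible", so the simplest norm is the default and both are offered. |
| `sdZero` | `"pass"` | — | with a zero young SD, the deviation criterion is taken as passed when the old value differs from the mean at all (deviation $+\infty$) and failed when equal (0). The alternative `"fail"` makes zero-SD genes never flag. Zero SDs are common in noise-free simulations; on real data they signal degenerate input. |
| `minOverlap`, `pCutoff` | 2, 0.01 | genes, probability | the over-representation limits used to admit a pathway into the cloud. Thresholds are strict (`p < cutoff`); a cutoff of 1 disables the p filter so zero-overlap rows (p = 1) can still be listed. |
| `universeSize` | required, no default | genes | hypergeometric p-values depend entirely on the annotation universe, which differs between databases; making it explicit keeps every result reproducible. |
| fold-change defaults | 0.5 / 2 | — | when a drug library gives only a direction (inhibit/activate), a twofold effect on each target is the minimal quantitative encoding. |

# Numerical and design choices

- **PAS assembly.** The log-additivity, OYR, ARR and BTIF ingredients admit
  exactly one natural combination, $\sum ARR \cdot BTIF \cdot \log OYR$,
  and that is what `computePAS()` fixes. Sign convention: an *activated*
  pathway (activators up, repressors down in old samples) scores positive.
- **Strict boundaries.** "Higher than 3/2", "lower than 2/3" and "more than
  two standard deviations" are read literally: $OYR = 1.5$ exactly, or a
  deviation of exactly 2 SD, does not flag. The boundary is measure-zero on
  real data; fixing it strictly makes the contract testable.
- **Young reference.** Arithmetic mean and $n-1$ sample SD on the linear
  scale, over young samples only — the plainest reading of "average" and
  "standard deviations". The package's I/O contract is linear-scale
  non-negative expression; already-logged matrices must be unlogged first.
- **Normalization.** `none` is the default: scoring assumes pre-normalized
  input, and silently renormalizing would change OYR ratios. `median_scale`
  rescales every sample so all medians equal the median of the per-sample
  medians (a permutation-stable reference); `quantile` delegates to
  `limma::normalizeQuantiles`. The 2-SD criterion is evaluated on the
  (normalized) linear scale.
- **Missing genes.** Pathway members absent from the matrix are skipped and
  counted (`skippedGenes()`), never imputed; a pathway with no measured
  member scores 0 and triggers a warning. Imputation would manufacture
  signal where there is no data.
- **Cohort aggregation.** Old samples are scored individually and averaged
  at the PAS level into the mean-of-old profile; screening ranks on the
  mean-of-old $D$. Averaging expression first would hide per-patient
  heterogeneity and break the per-sample profiles needed for personalized
  use.
- **Drug model.** Effects are multiplicative fold-changes on target-gene
  expression, applied upstream of all scoring. Acting on PAS or on the
  flags directly were considered and rejected: expression is where target
  knowledge lives, and everything downstream then follows from one model.
  Pair combination is the gene-wise product — composable, commutative, and
  exact for the antidote-plus-null case. Only pairs are enumerated;
  combinatorial growth makes larger arities a separate problem.
- **Enrichment.** Upper-tail hypergeometric including the observed overlap
  (`stats::phyper`), BH step-up FDR (`stats::p.adjust`) over the pathways
  that pass the overlap filter, output ordered by overlap percent
  descending, then p ascending, then pathway id — fully deterministic.
  Overlap percent is rounded half away from zero to one decimal, matching
  the arithmetic of the bundled table's self-consistent rows.
- **The bundled enrichment table.** 44 KEGG pathways with background and
  overlap counts for a longevity-candidate gene list. Thirteen of the 44
  printed percentage cells disagree with their own printed counts, always
  upward by about a tenth of a percent (e.g. Ribosome: 21/136 = 15.4
  printed as 15.7; Adipocytokine: 6/71 = 8.5 printed as 8.6), indicating an
  undisclosed, slightly smaller effective background in the source
  database; the package recomputes percentages from the counts and
  documents the discrepancy rather than matching those cells. The p-value
  and FDR columns additionally depend on the source's unprinted gene
  universe and tested-pathway count, so they are shipped as reference text
  only and are not regenerated.
- **File dialects.** Plain GMT cannot carry per-gene roles, so the native
  pathway format is a 3-column TSV (`pathway_id`, `gene`, `arr`) with
  optional `# name:` comments; `importGMT()` is provided and documented as
  lossy (all ARR = 1). Gene identifiers are case-insensitive and
  normalized to uppercase throughout.

# What the simulator emulates — and what it does not

`simulateStudy()` draws per-gene baselines from a log-normal (defaults:
meanlog 4, sdlog 1 — typical levels around 55 units spanning roughly two
orders of magnitude, the shape of linear-scale expression data), adds
i.i.d. Gaussian noise on the log scale (default SD 0.1, about 10% CV, a
plausible within-cohort biological-plus-technical spread), and plants
per-pathway fold-shifts in the old cohort that respect ARR signs, so an
"activated" pathway has a well-defined positive expected PAS. Pathways are
non-overlapping by default so planted signal is attributable to a single
pathway. The default scenario — 50 genes, 5 pathways of 10, 5 young and 5
old samples, one pathway activated 4-fold — is small enough to run hundreds
of replicates in seconds yet large enough that the young SD, the tolerance
flags and the distractor drugs all behave non-trivially.

What it deliberately does not emulate: probe/library-size artifacts, batch
effects, gene-gene correlation beyond pathway co-perturbation, dropout, or
overlapping pathway membership (available but off by default). Passing the
recovery experiments therefore shows the *method* is implemented correctly
and is self-consistent under its own assumptions — not that it is robust to
the technical structure of real microarray or RNA-seq data, which must be
normalized and batch-corrected upstream.

`simulateDrugLibrary()` builds the matching screen: the exact antidote
(reciprocal fold-changes on every planted shift, so on a noise-free study
treated old values equal the young means gene-wise and $D = 0$ exactly), a
half-coverage partial antidote, random-target distractors with twofold
effects, and a null drug. The validation experiments in the test suite and
acceptance script use 100 seeded screening replicates (plus 20 noise-free
replicates) and 20 planted-pathway ORA replicates; the enumeration oracle
for the hypergeometric tail is run exhaustively for every universe up to
$N = 25$ — sizes chosen so the whole suite runs in a couple of minutes
while keeping Monte-Carlo error far from the pass margins.

# Known limitations

- ARR assignment is an input, not a computation: the package validates the
  5-value domain but has no literature-mining to derive roles.
- Drug target knowledge enters only as fold-changes on expression; binding
  affinity, dose, PK/PD and off-target chemistry are out of scope.
- The hypergeometric model assumes an unstructured gene universe; gene-set
  overlap and annotation bias are not corrected beyond BH-FDR.
- With `sdZero = "pass"` and noise-free data, any fold-change beyond
  tolerance flags a gene regardless of cohort spread; on real data the SD
  criterion dominates and small cohorts (the minimum is 2 young samples)
  estimate it poorly — more young samples directly stabilize both OYR and
  BTIF.
- Cross-species ortholog mapping, epigenetic profiles, and in
  vitro/in vivo validation of ranked candidates are explicitly outside the
  package.
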