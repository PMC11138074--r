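# mavemap

Scoring, classification, and clinical calibration of deep mutational scans
(multiplexed assays of variant effect, MAVEs) of a small membrane protein —
modelled on saturation-mutagenesis maps of KCNE1, the 129-residue subunit
of the cardiac IKs potassium channel whose loss-of-function variants cause
type 5 long QT syndrome. Most KCNE1 variants seen in patients are variants
of uncertain significance; a calibrated MAVE measures them all at once and
contributes ACMG/AMP PS3/BS3 functional evidence toward reclassification.

The package covers the full analysis path from sequencing counts to
clinical evidence:

* **Library model** — the 21-outcomes-per-residue variant space
  (19 missense + 1 synonymous + 1 stop; 129 × 21 = 2709 outcomes), NNK
  degenerate-codon combinatorics (32 codons, 20 amino acids + TAG), SNV
  accessibility and transition/transversion labelling, Wallace-rule primer
  melting temperatures.
* **Subassembly** — linking each random 18-mer barcode to its variant from
  read evidence, with read-support and consensus filters.
* **Trafficking scores** — weighted-average bin scores from four-bin
  sort-seq counts: with bin weights `w = (0, 1/3, 2/3, 1)` and
  depth-normalized bin shares `p`, the raw score is `sum(w * p)`.
* **Functional scores** — OLS slopes of log2 barcode frequency over days
  0/8/20 of a fitness selection that depletes cells carrying functional
  channels.
* **Normalization & CIs** — scores rescaled so the synonymous median is 1
  and the early-nonsense median 0; 95% CIs by hierarchical bootstrap over
  barcodes within replicates.
* **Classification** — six categories (loss, partial loss, possible loss,
  normal, possible gain, gain) from a deterministic decision tree over the
  estimate and CI against data-derived percentile cutoffs.
* **Calibration** — curated presumed benign/pathogenic controls, assay
  readouts, and the OddsPath likelihood ratio
  `OddsPath = P2(1 − P1) / ((1 − P2) P1)` mapped to ClinGen SVI PS3/BS3
  evidence strengths.
* **Evaluation & structure** — Spearman correlations with patch-clamp
  data, ROC/sensitivity/specificity, Wilcoxon contrasts, per-residue
  intolerance, splice-score flags, and heavy-atom contact analysis of the
  channel complex structure.
* **Synthetic data** — a fully seeded generator for the barcoded library,
  the FACS sort, and the depletion time course, used throughout the test
  suite to validate recovery of known truth.

## Worked example

Simulate a depletion experiment for a 40-residue protein, score it,
and classify every variant:

```r
library(mavemap)

cfg <- sim_config(protein_length = 40, n_barcodes_mean = 15,
                  reads_per_sample = 1e6, cells_per_replicate = 1e6,
                  seed = 2024)
lib    <- simulate_library(cfg)
bt     <- sim_barcode_table(lib)
depl   <- simulate_depletion(lib)
scores <- score_fitness(depl$counts, depl$sample_info, bt,
                        n_boot = 200, seed = 1)
scores <- classify_scores(scores)

head(scores[, c("hgvs_pro", "score", "ci_lower", "ci_upper",
                "n_barcodes", "category")])
#>      hgvs_pro    score ci_lower ci_upper n_barcodes     category
#> A20*     A20* -0.00804  -0.0210  0.00627         17         loss
#> A20=     A20=  1.29328   1.2563  1.32611         11       normal
#> A20C     A20C  0.04676   0.0253  0.06475         10 partial_loss
#> A20D     A20D  0.24662   0.2353  0.26554         20 partial_loss
#> A20E     A20E  0.93843   0.8906  0.98628          2       normal
#> A20F     A20F  0.93390   0.8963  0.97349         12       normal

table(scores$category)
#>          loss  partial_loss possible_loss        normal possible_gain
#>           123           200             9           467            30
#>          gain
#>            11
```

Scores are anchored so 1 is wild-type-like (the variant's cells deplete
like synonymous controls — the channel works) and 0 is non-functional (the
cells persist like early truncations). The stop at residue 20 (`A20*`)
scores 0 and is called loss; the synonymous recoding `A20=` sits in the
normal range. The cutoffs behind the categories are percentiles of the
experiment's own anchor distributions:

```r
unlist(attr(scores, "cutoffs"))
#>    lower  mid_low mid_high
#>   0.0415   0.6064   1.3514
```

Recovery against the simulation's ground truth is essentially exact at
this depth (Spearman rho = 0.998 between estimated scores and true latent
activity).

Calibrating the assay on clinically classified controls (7 benign/likely
benign, all reading out normal; 4 pathogenic/likely pathogenic, 3 abnormal
and 1 normal):

```r
report <- oddspath(
  labels   = c(rep("benign", 7), rep("pathogenic", 4)),
  readouts = c(rep("normal", 7), rep("abnormal_low", 3), "normal"))
c(report$oddspath_pathogenic, report$oddspath_benign)
#> [1] 5.25 0.25
report$strengths
#>               PS3               BS3
#>    "PS3_moderate" "BS3_supporting"
```

An abnormal readout multiplies the odds of pathogenicity by 5.25
(moderate-strength PS3 evidence); a normal readout multiplies them by 0.25
(supporting-strength BS3 evidence).

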