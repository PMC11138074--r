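---
title: "Scoring and calibrating a deep mutational scan of an ion-channel subunit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and calibrating a deep mutational scan of an ion-channel subunit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemap)
```

## The experiment this package models

`mavemap` analyses multiplexed assays of variant effect (MAVEs) of the kind
used to map KCNE1, the 129-residue single-pass subunit that assembles with
the KCNQ1 pore and calmodulin to form the cardiac IKs potassium channel.
Loss-of-function variants in this subunit cause type 5 long QT syndrome,
but most observed variants are variants of uncertain significance; a MAVE
measures thousands of variants at once and, after calibration, contributes
ACMG/AMP PS3/BS3 functional evidence toward their classification.

Two coupled experiments are modelled:

* **Trafficking (sort-seq)**: every cell expresses one barcoded variant;
  surface protein is immunolabelled and cells are FACS-sorted into four
  bins of approximately equal occupancy; each bin is deep sequenced. A
  variant that reaches the surface skews toward the bright bins.
* **Function (depletion)**: against a constitutively open channel
  background, a functioning subunit raises potassium efflux and slows
  growth, so cells carrying functional variants are depleted from the pool
  between days 0, 8, and 20. Persistence signals loss of function.

Both experiments count barcodes, not variants: a saturation-mutagenesis
library (degenerate NNK codons, one mutated codon per molecule) is tagged
with random 18-mers, and a subassembly sequencing run links each barcode to
its variant before any assay is scored.

## Variant space and library model

Each residue has 21 single-amino-acid outcomes — 19 missense, one
synonymous recoding, one stop — so a 129-residue protein has
`r 21 * 129` possible outcomes (`enumerate_site_outcomes()`). The NNK
alphabet (N = A/C/G/T, K = G/T) contains 32 codons covering all 20 amino
acids plus the single stop codon TAG (`nnk_codons()`), which is why one
nonsense variant per residue is expected in the library.
`snv_accessibility()` reports how many nucleotide substitutions separate
the reference codon from the nearest codon of an alternate residue and
whether single-step paths are transitions or transversions, supporting
contrasts of variant effect by mutational accessibility.

## Subassembly

`build_barcode_map()` retains a barcode when it has at least `min_reads`
total reads (default 5) and its plurality variant call accounts for at
least `min_consensus` of them (default 0.9); reads with more than one
mutated codon or a length change are rejected rather than repaired, because
the NNK design produces only single-codon substitutions. These thresholds
are deliberately conservative: a mis-assigned barcode contaminates every
downstream score it touches, whereas a discarded barcode only costs a
little precision. Plurality ties break lexicographically so the map is
independent of input order.

## Scoring

**Trafficking.** Within each replicate, barcode counts in the four bins are
pseudocounted (0.5 per cell), converted to proportions of each sample's
depth, renormalized across bins, and summarised as a weighted average with
equally spaced weights (0, 1/3, 2/3, 1) — 0 means all reads in the dimmest
bin, 1 all in the brightest. Equally spaced weights are the natural default
when per-bin mean fluorescence is not available; the weights are
configurable, so measured bin means can be substituted.

**Function.** Within each replicate, each barcode's log2 frequency is
regressed on day (0, 8, 20) by ordinary least squares. Using all three days
rather than the endpoint ratio keeps the day-8 information and coincides
with the endpoint ratio when the points are collinear.

**Aggregation and normalization.** Barcodes are independent clonal
measurements, so a variant's replicate score is the unweighted mean of its
barcodes (a read-weighted mean is available). Scores are then linearly
rescaled so the synonymous median is exactly 1 and the early-nonsense
median exactly 0. "Early nonsense" means stops at residues 1–55, the
truncations that abolish surface expression; in the functional assay the
loss plateau extends through residue 104, so the anchor boundary is a
configurable argument (default 55 for symmetry between the assays). On the
functional side, more negative slopes (faster depletion, working channel)
map to higher scores, so 1 is wild-type-like and 0 is non-functional in
both assays.

**Confidence intervals.** 95% CIs come from a hierarchical percentile
bootstrap: barcodes are resampled with replacement within each replicate,
replicate means are averaged, and the 2.5th/97.5th percentiles over
`n_boot` draws (seeded) give the interval. The bootstrap is deliberately
performed at the barcode level — barcodes are the independent sampling
units — and the normalization map is held fixed across draws because the
anchor medians are estimated from hundreds of variants and contribute
negligible uncertainty relative to a single variant's ~30 barcodes.

## Classification

Cutoffs are data-derived: the 97.5th percentile of early-nonsense scores
(`lower`), and the 2.5th/97.5th percentiles of synonymous scores
(`mid_low`, `mid_high`), all Hyndman–Fan type-7 percentiles for
reproducibility. The decision tree in `classify_variant()` is evaluated in
a fixed order: a point estimate below `lower` is *loss*; a CI inside
(`lower`, `mid_low`) is *partial loss*; a CI spanning `mid_low` is
*possible loss*; a CI inside the synonymous range is *normal*; a CI
spanning `mid_high` is *possible gain*; a CI above it is *gain*. The
published analyses these rules mirror used 0.2/0.83/1.18 (trafficking) and
0.09/0.44/1.53 (function). Verbal definitions of the "possible"
categories ("point estimate near the cutoff") are operationalised purely by
CI spanning, with residual boundary cases resolved by where the point
estimate sits; this keeps the rule total, deterministic, and monotone —
shifting an estimate and its CI upward can never move a variant toward
loss, a property the test suite checks exhaustively on a grid.

## ACMG/AMP calibration

Controls are curated ClinVar-first: clinically classified
pathogenic/likely-pathogenic and benign/likely-benign missense variants
keep their labels; otherwise a variant seen in at least one case with
population allele frequency below 2.5e-5 is presumed pathogenic, and a
variant with estimated penetrance below 10% (cases over literature carriers
plus population allele counts) and frequency above 3e-5 is presumed benign.
A control's assay readout compares its whole CI to the calibration cutoffs
0.44 and 1.43 (the synonymous 2.5th/97.5th percentiles used for
calibration, kept distinct from the classification cutoffs above);
intervals overlapping a cutoff are indeterminate and excluded.

OddsPath is the likelihood ratio of pathogenicity attributable to a
readout: with prior `P1` (pathogenic fraction of determinate controls) and
posterior `P2` (pathogenic fraction within a readout class),

```
OddsPath = P2 (1 - P1) / ((1 - P2) P1)
```

When a readout class contains no discordant control, one hypothetical
discordant variant is added to that class before computing its `P2` — the
standard conservative zero-cell correction, flagged in the report; `P1`
always uses the uncorrected counts. Thresholds on the ClinGen SVI scale map
the two ratios to PS3/BS3 strengths (supporting/moderate/strong/very
strong at 2.1/4.3/18.7/350 and 0.48/0.23/0.053/0.0029).

```{r oddspath}
report <- oddspath(
  labels   = c(rep("benign", 7), rep("pathogenic", 4)),
  readouts = c(rep("normal", 7), rep("abnormal_low", 3), "normal"))
c(report$oddspath_pathogenic, report$oddspath_benign)
report$strengths
```

## The synthetic-data generator

No raw sequencing data ship with the package; `simulate_library()`,
`simulate_sortseq()` and `simulate_depletion()` generate the whole
experiment from a seeded configuration, and the test suite validates the
pipeline by round-tripping known truth through it.

Each variant carries two latent values: surface expression `tau` and
functional activity `phi`, anchored at 1 (wild-type-like) and 0 (complete
loss). Defaults encode the biology the pipeline must cope with:

* synonymous variants scatter around 1 with sd 0.09 (`tau`) and 0.2
  (`phi`), matching the width of the synonymous score distributions
  implied by the published percentile cutoffs;
* nonsense variants are complete-loss before the assay-specific boundary
  (residue 55 for trafficking, 104 for function) and wild-type-like after
  it;
* missense variants come from a four-component mixture
  (loss/partial/normal/gain) with weights chosen so the simulated category
  proportions resemble the published maps (roughly a quarter of missense
  variants functionally deleterious, ~13% gain-of-trafficking).

Mechanistically, barcode counts per variant are zero-truncated negative
binomial with mean 30.7 (cloning dispersion); each replicate draws cell
allotments multinomially, cell fluorescence is lognormal around `tau`
(sd 0.5), bins are the pooled population quartiles, and reads are drawn
multinomially per sample at fixed depth. Depletion follows
`exp(-sigma * phi * t)` with `sigma = log(10)/20`, so a fully active
variant depletes tenfold by day 20, consistent with the validation
competitions the assay design was based on. Default depths are the
experiment's stated scales — 2.5e7 reads per sample and 3.2e6 sorted cells
per replicate (four bins of 8e5); tests that only need qualitative
behaviour use explicitly scaled-down configurations (a 20-residue protein,
2e5 reads) to stay fast.

What the generator does *not* emulate: sequencing error within barcode
reads (subassembly fixtures use a separate read generator), PCR jackpots,
replicate-level batch effects, barcode-specific expression biases, or
selection kinetics beyond a single exponential. Passing recovery tests
therefore demonstrates that the estimators and decision rules invert the
generative model they were designed for — not that real data are free of
these additional artifacts.

A lognormal fluorescence model was chosen for positivity and the heavy
right tail typical of surface immunostaining; a single shared seed drives
library, sorting, and depletion through independent substreams, so every
simulated artifact is byte-reproducible.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 everywhere a frequency is formed: avoids log-of-zero and
  biases all entities identically. Exact depth invariance holds when
  counts dominate the pseudocount; the tests check it at 1000-fold counts.
* Percentiles are always type 7 (linear interpolation).
* All-zero barcodes are dropped with a reason; variants with no surviving
  barcodes are reported unscored rather than imputed.
* Degenerate anchors (equal synonymous and nonsense medians) and inverted
  cutoffs are hard errors — they signal a failed experiment, not a
  tolerable edge case.
* A single barcode in a single replicate yields a collapsed CI flagged
  `no_variance`.
* Plurality ties in subassembly break lexicographically; bin ties in the
  simulated sort break by random rank within the seeded stream.

## Structure contacts

`min_residue_distances()` reads a complex structure (PDB or mmCIF via
bio3d), keeps the first model, resolves altlocs by occupancy, ignores
hydrogens, and reports each subunit residue's minimum heavy-atom distance
to each partner chain; contact means strictly less than 5 angstroms. In
the mapped experiment, 22 of 30 residues intolerant of variation (more
than 70% of missense variants loss or partial-loss) sit in contact with
the pore subunit or calmodulin — `intolerance_contact_overlap()` computes
exactly this intersection plus the complementary check that tolerant
residues avoid the interface.

## Problem sizes used in validation

The recovery experiment in the test suite simulates the full 129-residue
protein (2709 variants, ~83,000 barcodes) at default depth and requires
rank correlation of at least 0.9 between estimated and true latents, at
least 90% of loss-component variants classified loss/partial-loss, and at
least 90% of synonymous variants classified normal. The bootstrap-coverage
experiment uses 1000 null variants of 30 barcodes each against a
30,000-barcode reference variant whose mean pins down the true score, with
400 bootstrap draws per variant; empirical 95% CI coverage must land in
93–97%. Desk-scale module tests use a 20-residue protein.

## Known limitations

* The functional assay (like the experiment it models) is poorly powered
  for gain-of-function: active and hyperactive variants both deplete.
* Scores are relative to the synonymous/early-nonsense anchors of the same
  experiment; cross-experiment comparisons need re-anchoring.
* The subassembly module handles substitutions only — no indel calling,
  and no error-correcting barcode clustering (merging barcodes within
  Hamming distance 1 is future work).
* OddsPath calibration inherits the circularity of presumed control sets;
  the zero-cell correction makes small contingencies conservative but
  cannot make 11 controls informative beyond moderate evidence.
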