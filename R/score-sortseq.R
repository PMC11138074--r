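#' Score cell-surface expression from four-bin sort-seq counts
#'
#' Full trafficking-score pipeline: per replicate, barcode counts in the
#' four sorted bins are converted to pseudocounted, depth-normalized bin
#' shares ([bin_frequencies()]) and summarised as a weighted-average bin
#' score ([weighted_bin_score()]); barcode scores are averaged per variant
#' within replicate, replicate scores averaged, and all scores normalized so
#' the synonymous median is 1 and the early-nonsense median 0
#' ([normalize_scores()]). 95% CIs come from a hierarchical bootstrap over
#' barcodes within replicates.
#'
#' @param counts Integer matrix, barcodes x samples, with rownames the
#'   barcode sequences.
#' @param sample_info Data frame with columns `sample`, `replicate`, `bin`
#'   describing the columns of `counts`.
#' @param barcode_table Data frame linking barcodes to variants: columns
#'   `barcode`, `name`, `position`, `ref_aa`, `alt_aa`, `vclass`. Barcodes
#'   absent from the table are ignored.
#' @param weights Bin weights for [weighted_bin_score()].
#' @param early_boundary Last residue of the early-nonsense anchor set
#'   (default 55: truncations up to here abolish surface expression).
#' @param pseudocount Pseudocount for [bin_frequencies()].
#' @param n_boot Bootstrap draws for the CIs (default 200).
#' @param seed Integer seed governing the bootstrap.
#' @return A score table (data frame): `hgvs_pro`, variant identity columns,
#'   `raw_score`, normalized `score`, `ci_lower`, `ci_upper`, `n_barcodes`,
#'   and one `score_rep<r>` column per replicate. The raw anchor medians are
#'   attached as attribute `"anchors"`.
#' @export
score_sortseq <- function(counts, sample_info, barcode_table,
                          weights = c(0, 1 / 3, 2 / 3, 1),
                          early_boundary = 55L, pseudocount = 0.5,
                          n_boot = 200L, seed = 1L) {
  barcode_table <- barcode_table[barcode_table$barcode %in% rownames(counts), ]
  counts <- counts[barcode_table$barcode, , drop = FALSE]
  reps <- sort(unique(sample_info$replicate))
  stat <- matrix(NA_real_, nrow(counts), length(reps),
                 dimnames = list(rownames(counts), NULL))
  for (i in seq_along(reps)) {
    info_r <- sample_info[sample_info$replicate == reps[i], ]
    info_r <- info_r[order(info_r$bin), ]
    stopifnot(nrow(info_r) == 4)
    bf <- bin_frequencies(counts[, info_r$sample, drop = FALSE],
                          pseudocount = pseudocount)
    sc <- weighted_bin_score(bf$shares, weights)
    stat[rownames(bf$shares), i] <- sc
  }
  score_assay(stat, barcode_table, early_boundary = early_boundary,
              n_boot = n_boot, seed = seed, assay = "trafficking")
}
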