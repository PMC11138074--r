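#' Log2-frequency depletion slope
#'
#' Ordinary least-squares slope of `log2(frequency)` against day, the raw
#' statistic of the depletion assay. With the three standard time points
#' the fit uses all of them, and for collinear points the slope equals the
#' endpoint log-ratio divided by the elapsed time.
#'
#' @param freq Frequencies at each day: a numeric vector, or a matrix with
#'   one row per entity and one column per day. Zero or `NA` frequencies are
#'   treated as missing; entities with fewer than 2 usable points get `NA`.
#' @param days Numeric vector of days, strictly increasing.
#' @return Slope(s) in log2 frequency per day.
#' @examples
#' depletion_slope(c(1, 2^-0.8, 2^-2), c(0, 8, 20)) # exactly -0.1
#' @export
depletion_slope <- function(freq, days) {
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1)
  stopifnot(ncol(freq) == length(days), all(diff(days) > 0))
  lf <- log2(freq)
  lf[!is.finite(lf)] <- NA_real_
  ok <- !is.na(lf)
  n_ok <- rowSums(ok)
  day_mat <- matrix(days, nrow(freq), length(days), byrow = TRUE)
  day_mat[!ok] <- NA_real_
  dbar <- rowMeans(day_mat, na.rm = TRUE)
  lbar <- rowMeans(lf, na.rm = TRUE)
  dc <- day_mat - dbar
  num <- rowSums(dc * lf, na.rm = TRUE)
  den <- rowSums(dc^2, na.rm = TRUE)
  slope <- num / den
  slope[n_ok < 2] <- NA_real_
  drop(slope)
}

#' Score variant function from depletion across days 0/8/20
#'
#' Full functional-score pipeline: per replicate, barcode counts at each
#' day are pseudocounted and depth-normalized to frequencies, each
#' barcode's log2-frequency depletion slope is fit by OLS
#' ([depletion_slope()]), barcode slopes are averaged per variant within
#' replicate and across replicates, and scores are normalized so the
#' synonymous median (fast depletion, functional channel) maps to 1 and the
#' early-nonsense median (persistence, no function) to 0. 95% CIs come from
#' the same hierarchical barcode bootstrap as the trafficking assay.
#'
#' @inheritParams score_sortseq
#' @param sample_info Data frame with columns `sample`, `replicate`, `day`.
#' @param early_boundary Last residue of the early-nonsense anchor set for
#'   the functional assay. Default 55 (the same anchor residues as the
#'   trafficking assay, for symmetry); truncations through residue 104 are
#'   loss-of-function, so 104 is a reasonable alternative.
#' @return A score table with the same columns as [score_sortseq()].
#' @export
score_fitness <- function(counts, sample_info, barcode_table,
                          early_boundary = 55L, pseudocount = 0.5,
                          n_boot = 200L, seed = 1L) {
  barcode_table <- barcode_table[barcode_table$barcode %in% rownames(counts), ]
  counts <- counts[barcode_table$barcode, , drop = FALSE]
  reps <- sort(unique(sample_info$replicate))
  stat <- matrix(NA_real_, nrow(counts), length(reps),
                 dimnames = list(rownames(counts), NULL))
  for (i in seq_along(reps)) {
    info_r <- sample_info[sample_info$replicate == reps[i], ]
    info_r <- info_r[order(info_r$day), ]
    sub <- counts[, info_r$sample, drop = FALSE] + pseudocount
    freq <- sweep(sub, 2, colSums(sub), "/")
    stat[, i] <- depletion_slope(freq, info_r$day)
  }
  score_assay(stat, barcode_table, early_boundary = early_boundary,
              n_boot = n_boot, seed = seed, assay = "functional")
}
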