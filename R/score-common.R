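# Shared scoring machinery for the sort-seq (trafficking) and depletion
# (functional) assays: per-barcode statistics are aggregated to variants as
# unweighted barcode means within replicate, averaged across replicates,
# normalized against synonymous / early-nonsense anchors, and given 95%
# percentile CIs by hierarchical bootstrap (resample barcodes within
# replicate, then average replicate means).

#' Convert sorted-bin counts to per-barcode bin frequencies
#'
#' Adds a pseudocount to every cell, converts each sample's counts to
#' proportions of that sample's total (depth normalization), then
#' renormalizes each row across the four bins to sum to 1. Rows whose raw
#' counts are zero in all four bins are dropped.
#'
#' @param counts Integer matrix, entities x 4 bins (one replicate, bins in
#'   order).
#' @param pseudocount Added to every cell before normalization (default 0.5).
#' @return A list with `shares` (rows sum to 1) and `dropped` (rownames of
#'   all-zero entities).
#' @export
bin_frequencies <- function(counts, pseudocount = 0.5) {
  stopifnot(ncol(counts) == 4, all(counts >= 0))
  keep <- rowSums(counts) > 0
  x <- counts[keep, , drop = FALSE] + pseudocount
  x <- sweep(x, 2, colSums(counts) + nrow(counts) * pseudocount, "/")
  shares <- x / rowSums(x)
  list(shares = shares, dropped = rownames(counts)[!keep] %||% which(!keep))
}

#' Weighted-average bin score
#'
#' The raw sort-seq score of an entity is the weighted average of its bin
#' shares, with non-decreasing weights scaled to `[0, 1]` (default equally
#' spaced: 0, 1/3, 2/3, 1). An entity entirely in the dimmest bin scores 0;
#' entirely in the brightest bin scores 1.
#'
#' @param shares Numeric vector of 4 bin shares, or a matrix with 4 columns;
#'   each row must sum to 1 (tolerance 1e-9).
#' @param weights Bin weights, non-decreasing, length 4.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
weighted_bin_score <- function(shares, weights = c(0, 1 / 3, 2 / 3, 1)) {
  if (is.null(dim(shares))) shares <- matrix(shares, nrow = 1)
  stopifnot(ncol(shares) == 4, length(weights) == 4, !is.unsorted(weights))
  if (any(abs(rowSums(shares) - 1) > 1e-9)) {
    stop("bin shares must sum to 1")
  }
  drop(shares %*% weights)
}

#' Aggregate barcode scores to a per-variant score
#'
#' Barcodes are independent clonal measurements of the same variant, so the
#' variant score within a replicate is the unweighted mean of its barcodes'
#' scores (a read-weighted mean is available via `read_weights`).
#'
#' @param barcode_scores Named numeric vector of per-barcode scores.
#' @param barcode_names Character vector, parallel to `barcode_scores`,
#'   giving each barcode's variant name.
#' @param read_weights Optional per-barcode weights (e.g. read counts) for a
#'   weighted mean; default unweighted.
#' @return A data frame with `name`, `score`, `n_barcodes`.
#' @export
aggregate_variant_score <- function(barcode_scores, barcode_names,
                                    read_weights = NULL) {
  keep <- !is.na(barcode_scores)
  barcode_scores <- barcode_scores[keep]
  barcode_names <- barcode_names[keep]
  if (is.null(read_weights)) {
    read_weights <- rep(1, length(barcode_scores))
  } else {
    read_weights <- read_weights[keep]
  }
  num <- rowsum(barcode_scores * read_weights, barcode_names)
  den <- rowsum(read_weights, barcode_names)
  n <- as.vector(rowsum(rep(1L, length(barcode_names)), barcode_names))
  data.frame(name = rownames(num), score = as.vector(num / den),
             n_barcodes = n, row.names = NULL)
}

#' Normalize raw scores against synonymous and early-nonsense anchors
#'
#' Applies the linear map `(x - median(early_nonsense)) /
#' (median(synonymous) - median(early_nonsense))`, so the synonymous median
#' is exactly 1 (wild-type-like) and the early-nonsense median exactly 0
#' (complete loss).
#'
#' @param x Raw scores to normalize.
#' @param synonymous,early_nonsense Raw scores of the anchor variant sets.
#' @return Normalized scores.
#' @export
normalize_scores <- function(x, synonymous, early_nonsense) {
  if (!length(synonymous) || !length(early_nonsense)) {
    stop("both anchor sets must be non-empty")
  }
  m_syn <- median(synonymous, na.rm = TRUE)
  m_non <- median(early_nonsense, na.rm = TRUE)
  if (isTRUE(all.equal(m_syn, m_non))) {
    stop("degenerate anchors: synonymous and early-nonsense medians coincide")
  }
  (x - m_non) / (m_syn - m_non)
}

#' Bootstrap confidence interval for one variant's score
#'
#' Hierarchical percentile bootstrap: barcodes are resampled with
#' replacement within each replicate, replicate means are averaged, and the
#' 2.5th/97.5th percentiles of the bootstrap distribution give the 95% CI.
#' The point estimate is the mean of the replicate means.
#'
#' @param scores_by_rep List with one numeric vector of barcode scores per
#'   replicate.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return A list with `estimate`, `ci_low`, `ci_high`, and `no_variance`
#'   (TRUE when a single barcode in a single replicate makes the interval
#'   collapse to the point).
#' @export
score_ci <- function(scores_by_rep, n_boot = 1000L, seed = 1L) {
  stopifnot(length(scores_by_rep) >= 1)
  scores_by_rep <- lapply(scores_by_rep, function(x) x[!is.na(x)])
  scores_by_rep <- Filter(length, scores_by_rep)
  if (!length(scores_by_rep)) stop("no scores to bootstrap")
  set.seed(seed)
  est <- mean(vapply(scores_by_rep, mean, numeric(1)))
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(vapply(scores_by_rep,
                function(x) mean(x[sample.int(length(x), replace = TRUE)]),
                numeric(1)))
  }, numeric(1))
  ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
  list(estimate = est, ci_low = ci[1], ci_high = ci[2],
       no_variance = length(scores_by_rep) == 1L &&
         length(scores_by_rep[[1]]) == 1L)
}

# Vectorised hierarchical bootstrap for all variants at once.
# stat: barcodes x replicates matrix of per-barcode statistics (NA allowed);
# names: variant name per barcode row. Returns variants x 2 matrix of
# percentile CI bounds on the raw scale.
boot_ci_all <- function(stat, names, n_boot, seed) {
  set.seed(seed)
  variants <- sort(unique(names))
  acc <- matrix(0, length(variants), n_boot,
                dimnames = list(variants, NULL))
  nrep_used <- setNames(numeric(length(variants)), variants)
  for (r in seq_len(ncol(stat))) {
    ok <- !is.na(stat[, r])
    s <- stat[ok, r]
    v <- names[ok]
    ord <- order(v)
    s <- s[ord]
    v <- v[ord]
    k <- tabulate(factor(v, levels = unique(v)))
    offset <- rep.int(cumsum(c(0L, k[-length(k)])), k)
    ksize <- rep.int(k, k)
    n <- length(s)
    samp <- matrix(
      s[offset + floor(runif(n * n_boot) * ksize) + 1L],
      nrow = n, ncol = n_boot)
    means <- rowsum(samp, v, reorder = TRUE) / as.vector(rowsum(rep(1, n), v))
    present <- rownames(means)
    acc[present, ] <- acc[present, , drop = FALSE] + means
    nrep_used[present] <- nrep_used[present] + 1
  }
  if (any(nrep_used == 0)) acc <- acc[nrep_used > 0, , drop = FALSE]
  nrep_used <- nrep_used[nrep_used > 0]
  acc <- acc / nrep_used
  t(apply(acc, 1, quantile, probs = c(0.025, 0.975), type = 7, names = FALSE))
}

# Shared variant-level scoring: per-barcode statistic matrix -> score table.
score_assay <- function(stat, barcode_table, early_boundary, n_boot, seed,
                        assay = c("trafficking", "functional")) {
  assay <- match.arg(assay)
  names <- barcode_table$name
  rep_scores <- lapply(seq_len(ncol(stat)), function(r) {
    aggregate_variant_score(stat[, r], names)
  })
  variants <- sort(unique(names))
  rep_mat <- matrix(NA_real_, length(variants), length(rep_scores),
                    dimnames = list(variants,
                                    paste0("score_rep", seq_along(rep_scores))))
  for (r in seq_along(rep_scores)) {
    rep_mat[rep_scores[[r]]$name, r] <- rep_scores[[r]]$score
  }
  raw <- rowMeans(rep_mat, na.rm = TRUE)
  meta <- barcode_table[!duplicated(barcode_table$name),
                        c("name", "position", "ref_aa", "alt_aa", "vclass")]
  rownames(meta) <- meta$name
  meta <- meta[variants, ]
  syn_raw <- raw[meta$vclass == "synonymous"]
  non_raw <- raw[meta$vclass == "nonsense" & meta$position <= early_boundary]
  norm <- function(x) normalize_scores(x, syn_raw, non_raw)
  ci_raw <- boot_ci_all(stat, names, n_boot = n_boot, seed = seed)
  ci_part <- norm(ci_raw)
  if (median(syn_raw, na.rm = TRUE) < median(non_raw, na.rm = TRUE)) {
    ci_part <- ci_part[, 2:1, drop = FALSE]
  }
  ci <- matrix(NA_real_, length(variants), 2, dimnames = list(variants, NULL))
  ci[rownames(ci_part), ] <- ci_part
  # the point estimate is always inside its own interval (guards the
  # degenerate single-barcode case against floating-point jitter)
  norm_raw <- norm(raw)
  ci[, 1] <- pmin(ci[, 1], norm_raw)
  ci[, 2] <- pmax(ci[, 2], norm_raw)
  any_ok <- rowSums(!is.na(stat)) > 0
  nb <- table(factor(names[any_ok], levels = variants))
  out <- data.frame(
    hgvs_pro = variants,
    position = meta$position, ref_aa = meta$ref_aa, alt_aa = meta$alt_aa,
    vclass = meta$vclass,
    raw_score = unname(raw), score = unname(norm_raw),
    ci_lower = unname(ci[variants, 1]), ci_upper = unname(ci[variants, 2]),
    n_barcodes = as.integer(nb),
    row.names = NULL)
  out <- cbind(out, norm(rep_mat[variants, , drop = FALSE]))
  attr(out, "assay") <- assay
  attr(out, "anchors") <- c(synonymous_median = unname(median(syn_raw)),
                            early_nonsense_median = unname(median(non_raw)))
  out
}
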