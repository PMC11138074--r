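# Downstream statistics relating assay scores to external measurements,
# clinical labels, and per-residue constraint.

#' Spearman rank correlation with tie-aware ranks
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return A list with `rho` (Spearman correlation on average ranks), `p`
#'   (two-sided, t approximation, as appropriate with ties), and `n`.
#' @export
rank_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' ROC curve and AUC for score-based pathogenicity prediction
#'
#' Low scores indicate functional loss, so a variant is called positive
#' (pathogenic-like) when its score falls below a threshold. The curve
#' sweeps all observed thresholds; the AUC is computed by the trapezoidal
#' rule.
#'
#' @param labels Logical (or coercible) vector: `TRUE` for the pathogenic
#'   class.
#' @param scores Numeric assay scores.
#' @return A list with `curve` (data frame: `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.logical(labels)
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]
  scores <- scores[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] < t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(c(0, fpr[ord], 1)) *
               (c(0, sens[ord]) + c(sens[ord], 1)) / 2)
  list(curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec), auc = auc)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' @inheritParams roc_curve
#' @param cutoff Scores strictly below `cutoff` are called positive.
#' @return A list with `sensitivity`, `specificity`, and the confusion
#'   counts `tp`, `fn`, `tn`, `fp`.
#' @export
operating_point <- function(labels, scores, cutoff) {
  labels <- as.logical(labels)
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]
  scores <- scores[ok]
  pos_call <- scores < cutoff
  tp <- sum(labels & pos_call)
  fn <- sum(labels & !pos_call)
  tn <- sum(!labels & !pos_call)
  fp <- sum(!labels & pos_call)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Two-group score contrast (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test; exact null distribution when both
#' groups have at most 10 observations and no ties, normal approximation
#' with continuity correction otherwise.
#'
#' @param x,y Numeric score vectors for the two groups.
#' @return A list with `statistic` (W), `p`, and group sizes.
#' @export
group_contrast <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  wt <- wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)))
}

#' Chi-square test of independence for a category cross-tabulation
#'
#' @param tab A contingency table (e.g. from [category_crosstab()]), or two
#'   parallel category vectors.
#' @param ... Second category vector when `tab` is a vector.
#' @return A list with `statistic`, `df`, `p`.
#' @export
crosstab_independence <- function(tab, ...) {
  if (!is.table(tab) && !is.matrix(tab)) tab <- table(tab, ...)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("degenerate margins")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Per-residue intolerance to missense variation
#'
#' A residue is flagged intolerant when more than 70% of its scored
#' missense variants are loss or partial-loss (strict inequality), and
#' tolerant when more than 50% are category normal. Residues without scored
#' missense variants are flagged unscorable.
#'
#' @param scores Classified score table (columns `position`, `vclass`,
#'   `category`).
#' @param intolerant_fraction,tolerant_fraction Flag thresholds (defaults
#'   0.70 and 0.50).
#' @return Data frame: `position`, `n_missense`, `frac_lof`, `frac_normal`,
#'   `intolerant`, `tolerant`, `unscorable`.
#' @export
residue_intolerance <- function(scores, intolerant_fraction = 0.70,
                                tolerant_fraction = 0.50) {
  mis <- scores[scores$vclass == "missense" & !is.na(scores$category), ]
  positions <- sort(unique(scores$position))
  res <- lapply(positions, function(p) {
    cat <- mis$category[mis$position == p]
    n <- length(cat)
    frac_lof <- if (n) mean(cat %in% c("loss", "partial_loss")) else NA_real_
    frac_normal <- if (n) mean(cat == "normal") else NA_real_
    data.frame(position = p, n_missense = n, frac_lof = frac_lof,
               frac_normal = frac_normal,
               intolerant = isTRUE(frac_lof > intolerant_fraction),
               tolerant = isTRUE(frac_normal > tolerant_fraction),
               unscorable = n == 0L)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag variants by precomputed splice-disruption scores
#'
#' Compares each variant's maximum splice delta score to the conventional
#' "recommended" (0.5) and "high recall" (0.2) thresholds.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param recommended,high_recall Thresholds (defaults 0.5, 0.2); a score
#'   strictly above `recommended` is flagged `"recommended"`, above
#'   `high_recall` only is `"high_recall"`, else `"none"`.
#' @return Character vector of flags.
#' @export
splice_flags <- function(score, recommended = 0.5, high_recall = 0.2) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("splice scores must lie in [0, 1]")
  }
  out <- rep("none", length(score))
  out[score > high_recall] <- "high_recall"
  out[score > recommended] <- "recommended"
  out[is.na(score)] <- NA_character_
  out
}
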