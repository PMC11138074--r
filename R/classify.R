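CATEGORY_LEVELS <- c("loss", "partial_loss", "possible_loss", "normal",
                     "possible_gain", "gain")

#' Data-derived classification cutoffs
#'
#' Three cutoffs delimit the six effect categories: `lower` is the 97.5th
#' percentile of the early-nonsense score distribution (complete loss),
#' `mid_low` and `mid_high` are the 2.5th and 97.5th percentiles of the
#' synonymous score distribution (wild-type-like range). Percentiles use
#' linear interpolation (Hyndman-Fan type 7). In the assays this package
#' models, the published trafficking cutoffs are 0.2 / 0.83 / 1.18 and the
#' functional cutoffs 0.09 / 0.44 / 1.53.
#'
#' @param synonymous,early_nonsense Normalized scores of the anchor sets.
#' @return A list of class `"effect_cutoffs"`: `lower`, `mid_low`,
#'   `mid_high`.
#' @export
compute_cutoffs <- function(synonymous, early_nonsense) {
  if (!length(synonymous) || !length(early_nonsense)) {
    stop("both anchor sets must be non-empty")
  }
  lower <- unname(quantile(early_nonsense, 0.975, type = 7, na.rm = TRUE))
  mid_low <- unname(quantile(synonymous, 0.025, type = 7, na.rm = TRUE))
  mid_high <- unname(quantile(synonymous, 0.975, type = 7, na.rm = TRUE))
  if (lower >= mid_low || mid_low >= mid_high) {
    stop("inverted or degenerate cutoffs (", signif(lower, 3), ", ",
         signif(mid_low, 3), ", ", signif(mid_high, 3),
         "): anchor distributions overlap or collapse")
  }
  structure(list(lower = lower, mid_low = mid_low, mid_high = mid_high),
            class = "effect_cutoffs")
}

#' Manually specified cutoffs
#'
#' @param lower,mid_low,mid_high Cutoff values, strictly increasing.
#' @return An `"effect_cutoffs"` object.
#' @export
effect_cutoffs <- function(lower, mid_low, mid_high) {
  stopifnot(lower < mid_low, mid_low < mid_high)
  structure(list(lower = lower, mid_low = mid_low, mid_high = mid_high),
            class = "effect_cutoffs")
}

#' Assign each variant to one of six effect categories
#'
#' Decision tree over the point estimate and its 95% CI, evaluated in
#' order: (1) estimate below `lower` is `loss`; (2) CI inside
#' `(lower, mid_low)` is `partial_loss`; (3) CI spanning `mid_low` is
#' `possible_loss`; (4) CI inside `(mid_low, mid_high)` is `normal`;
#' (5) CI spanning `mid_high` is `possible_gain`; (6) CI above `mid_high`
#' is `gain`. A CI that spans `lower` with the estimate at or above `lower`
#' falls back to `partial_loss` when the estimate is below `mid_low` and
#' `possible_loss` otherwise, keeping the rule total and deterministic.
#'
#' @param estimate,ci_low,ci_high Numeric vectors (equal length), with
#'   `ci_low <= estimate <= ci_high`.
#' @param cutoffs An `"effect_cutoffs"` object.
#' @return Factor of categories with levels loss < partial_loss <
#'   possible_loss < normal < possible_gain < gain.
#' @export
classify_variant <- function(estimate, ci_low, ci_high, cutoffs) {
  stopifnot(inherits(cutoffs, "effect_cutoffs"),
            length(estimate) == length(ci_low),
            length(estimate) == length(ci_high))
  bad <- !is.na(estimate) & (ci_low > estimate | estimate > ci_high)
  if (any(bad)) stop("malformed CI: ci_low <= estimate <= ci_high required")
  lo <- cutoffs$lower
  ml <- cutoffs$mid_low
  mh <- cutoffs$mid_high
  out <- rep(NA_character_, length(estimate))
  done <- is.na(estimate) | is.na(ci_low) | is.na(ci_high)
  rule <- function(cond, label) {
    hit <- !done & cond
    out[hit] <<- label
    done <<- done | hit
  }
  rule(estimate < lo, "loss")
  rule(ci_low >= lo & ci_high <= ml, "partial_loss")
  rule(ci_low < ml & ci_high > ml, "possible_loss")
  rule(ci_low >= ml & ci_high <= mh, "normal")
  rule(ci_low < mh & ci_high > mh, "possible_gain")
  rule(ci_low > mh, "gain")
  # residuals: CIs touching a cutoff exactly, or spanning `lower` with the
  # estimate at or above it; resolved by where the estimate sits
  rule(estimate < ml, "partial_loss")
  rule(estimate <= mh, "possible_loss")
  rule(rep(TRUE, length(estimate)), "possible_gain")
  factor(out, levels = CATEGORY_LEVELS, ordered = TRUE)
}

#' Early/late regime of a nonsense variant
#'
#' Truncations behave in two regimes per assay: in the trafficking assay,
#' stops through residue 55 abolish surface expression while later stops
#' traffic normally; in the functional assay the boundary is residue 104.
#'
#' @param residue 1-based residue index (vectorised).
#' @param assay `"trafficking"` or `"functional"`.
#' @param protein_length Protein length for range checking (default 129).
#' @return Character vector `"early"` / `"late"`.
#' @examples
#' nonsense_regime(55, "trafficking") # "early"
#' nonsense_regime(56, "trafficking") # "late"
#' @export
nonsense_regime <- function(residue, assay = c("trafficking", "functional"),
                            protein_length = 129L) {
  assay <- match.arg(assay)
  if (any(residue < 1 | residue > protein_length)) {
    stop("residue out of range 1..", protein_length)
  }
  boundary <- if (assay == "trafficking") 55L else 104L
  ifelse(residue <= boundary, "early", "late")
}

#' Classify every variant in a score table
#'
#' Computes cutoffs from the table's own synonymous and early-nonsense
#' scores (unless `cutoffs` is supplied) and appends a `category` column.
#'
#' @param scores A score table from [score_sortseq()] or [score_fitness()].
#' @param cutoffs Optional `"effect_cutoffs"`; by default derived from the
#'   table via [compute_cutoffs()].
#' @param early_boundary Early-nonsense anchor boundary used when deriving
#'   cutoffs (default 55).
#' @return The score table with a `category` column; the cutoffs used are
#'   attached as attribute `"cutoffs"`.
#' @export
classify_scores <- function(scores, cutoffs = NULL, early_boundary = 55L) {
  if (is.null(cutoffs)) {
    syn <- scores$score[scores$vclass == "synonymous"]
    non <- scores$score[scores$vclass == "nonsense" &
                          scores$position <= early_boundary]
    cutoffs <- compute_cutoffs(syn, non)
  }
  scores$category <- classify_variant(scores$score, scores$ci_lower,
                                      scores$ci_upper, cutoffs)
  attr(scores, "cutoffs") <- cutoffs
  scores
}

#' Cross-tabulate trafficking and functional categories
#'
#' @param trafficking,functional Classified score tables (with `category`),
#'   joined on `hgvs_pro`.
#' @return A contingency table (trafficking rows x functional columns) over
#'   the variants present in both tables.
#' @export
category_crosstab <- function(trafficking, functional) {
  common <- intersect(trafficking$hgvs_pro, functional$hgvs_pro)
  t_cat <- trafficking$category[match(common, trafficking$hgvs_pro)]
  f_cat <- functional$category[match(common, functional$hgvs_pro)]
  table(trafficking = t_cat, functional = f_cat)
}
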