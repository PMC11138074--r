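# ACMG/AMP functional-evidence calibration (ClinGen SVI OddsPath framework):
# presumed benign / pathogenic control sets are curated from clinical
# classifications, literature case counts, and population allele
# frequencies; assay readouts on those controls yield a likelihood ratio of
# pathogenicity (OddsPath) for each readout class, mapped to PS3/BS3
# evidence strengths.

#' Estimated penetrance of a variant
#'
#' Cases observed in the literature divided by total carriers: literature
#' carriers plus population (gnomAD) allele counts.
#'
#' @param n_cases Cases reported in the literature.
#' @param n_carriers_literature Total carriers reported in the literature.
#' @param gnomad_ac Population allele count.
#' @return Penetrance as a fraction.
#' @examples
#' estimate_penetrance(2, 5, 45) # 0.04
#' @export
estimate_penetrance <- function(n_cases, n_carriers_literature, gnomad_ac) {
  denom <- n_carriers_literature + gnomad_ac
  if (any(denom <= 0)) stop("penetrance denominator must be positive")
  n_cases / denom
}

#' Curate presumed benign and pathogenic control variants
#'
#' Assembly rules, applied ClinVar-first: ClinVar pathogenic/likely
#' pathogenic variants are presumed pathogenic and benign/likely benign
#' presumed benign regardless of frequency; otherwise a variant seen in at
#' least one case with population allele frequency below `af_pathogenic`
#' is presumed pathogenic, and a variant with estimated penetrance below
#' `max_penetrance` and allele frequency above `af_benign` is presumed
#' benign. Everything else is excluded (with the high-penetrance/common
#' combination flagged explicitly).
#'
#' @param controls Data frame with columns `name`, `clinvar` (`"P/LP"`,
#'   `"B/LB"`, or anything else for unclassified), `n_cases`,
#'   `n_carriers_literature`, `gnomad_ac`, `gnomad_af`.
#' @param af_pathogenic Allele-frequency ceiling for literature-case-based
#'   pathogenic controls (default 2.5e-5).
#' @param af_benign Allele-frequency floor for population-based benign
#'   controls (default 3e-5).
#' @param max_penetrance Penetrance ceiling for benign controls (default
#'   0.10).
#' @return The input with `penetrance`, `presumed_label` (`"pathogenic"`,
#'   `"benign"`, `"excluded"`) and `label_source` columns.
#' @export
curate_controls <- function(controls, af_pathogenic = 2.5e-5,
                            af_benign = 3e-5, max_penetrance = 0.10) {
  need <- c("name", "clinvar", "n_cases", "n_carriers_literature",
            "gnomad_ac", "gnomad_af")
  if (!all(need %in% names(controls))) {
    stop("controls needs columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(suppressWarnings(as.numeric(controls$gnomad_af))))) {
    stop("unparseable allele frequency")
  }
  controls$gnomad_af <- as.numeric(controls$gnomad_af)
  denom <- controls$n_carriers_literature + controls$gnomad_ac
  controls$penetrance <- ifelse(denom > 0, controls$n_cases / denom, NA_real_)
  label <- rep("excluded", nrow(controls))
  source <- rep("none", nrow(controls))
  lit_path <- controls$n_cases >= 1 & controls$gnomad_af < af_pathogenic
  pop_ben <- !is.na(controls$penetrance) &
    controls$penetrance < max_penetrance & controls$gnomad_af > af_benign
  label[lit_path] <- "pathogenic"
  source[lit_path] <- "literature_case"
  label[pop_ben] <- "benign"
  source[pop_ben] <- "population"
  # ClinVar wins conflicts
  cv_p <- controls$clinvar %in% c("P/LP", "P", "LP",
                                  "pathogenic", "likely_pathogenic")
  cv_b <- controls$clinvar %in% c("B/LB", "B", "LB",
                                  "benign", "likely_benign")
  label[cv_p] <- "pathogenic"
  source[cv_p] <- "clinvar_plp"
  label[cv_b] <- "benign"
  source[cv_b] <- "clinvar_blb"
  controls$presumed_label <- label
  controls$label_source <- source
  controls
}

#' Assay readout of a score estimate for calibration
#'
#' A control's functional readout is `abnormal_low` when the estimate and
#' its whole CI fall below `lo_cutoff`, `abnormal_high` when entirely above
#' `hi_cutoff`, `normal` when entirely inside the interval, and
#' `indeterminate` when the CI overlaps a cutoff. The default cutoffs
#' (0.44, 1.43) are the 2.5th/97.5th synonymous percentiles used for
#' calibration, intentionally kept distinct from the classification
#' module's category cutoffs.
#'
#' @param estimate,ci_low,ci_high Numeric vectors (equal length).
#' @param lo_cutoff,hi_cutoff Calibration cutoffs (defaults 0.44 and 1.43).
#' @return Character vector of readouts.
#' @export
assay_readout <- function(estimate, ci_low, ci_high,
                          lo_cutoff = 0.44, hi_cutoff = 1.43) {
  stopifnot(length(estimate) == length(ci_low),
            length(estimate) == length(ci_high))
  if (any(ci_low > estimate | estimate > ci_high, na.rm = TRUE)) {
    stop("malformed CI: ci_low <= estimate <= ci_high required")
  }
  out <- rep("indeterminate", length(estimate))
  out[ci_high < lo_cutoff] <- "abnormal_low"
  out[ci_low > hi_cutoff] <- "abnormal_high"
  out[ci_low > lo_cutoff & ci_high < hi_cutoff] <- "normal"
  out[is.na(estimate) | is.na(ci_low) | is.na(ci_high)] <- NA_character_
  out
}

#' OddsPath likelihood ratios from control readouts
#'
#' Computes the prior proportion pathogenic `P1` among determinate controls
#' and the posterior proportions pathogenic among abnormal (`P2_abnormal`)
#' and normal (`P2_normal`) readouts, then the likelihood ratios
#' `OddsPath = P2 (1 - P1) / ((1 - P2) P1)` for each side. When a readout
#' class contains no discordant control (no benign among abnormal, or no
#' pathogenic among normal), one hypothetical discordant variant is added
#' to that class before computing its posterior — the standard conservative
#' zero-cell correction — and flagged; `P1` is always computed from the
#' uncorrected counts. Indeterminate readouts are excluded throughout.
#'
#' @param labels Character vector of presumed labels (`"pathogenic"` /
#'   `"benign"`; others dropped).
#' @param readouts Parallel vector of readouts from [assay_readout()].
#' @return A list of class `"oddspath_report"`: counts, `P1`,
#'   `P2_abnormal`, `P2_normal`, `oddspath_pathogenic`, `oddspath_benign`,
#'   `corrections_applied`, and mapped `strengths`.
#' @export
oddspath <- function(labels, readouts) {
  stopifnot(length(labels) == length(readouts))
  keep <- labels %in% c("pathogenic", "benign") & !is.na(readouts) &
    readouts != "indeterminate"
  labels <- labels[keep]
  readouts <- readouts[keep]
  abnormal <- readouts %in% c("abnormal_low", "abnormal_high")
  normal <- readouts == "normal"
  path_ab <- sum(labels == "pathogenic" & abnormal)
  ben_ab <- sum(labels == "benign" & abnormal)
  path_no <- sum(labels == "pathogenic" & normal)
  ben_no <- sum(labels == "benign" & normal)
  n_path <- sum(labels == "pathogenic")
  n_det <- length(labels)
  if (n_path == 0 || n_path == n_det) {
    stop("need at least one determinate control on each side")
  }
  p1 <- n_path / n_det
  corrections <- character(0)
  ab_path <- path_ab
  ab_ben <- ben_ab
  if (ab_ben == 0) {
    ab_ben <- 1
    corrections <- c(corrections, "abnormal")
  }
  no_path <- path_no
  no_ben <- ben_no
  if (no_path == 0) {
    no_path <- 1
    corrections <- c(corrections, "normal")
  }
  p2_ab <- ab_path / (ab_path + ab_ben)
  p2_no <- no_path / (no_path + no_ben)
  op_path <- (p2_ab * (1 - p1)) / ((1 - p2_ab) * p1)
  op_ben <- (p2_no * (1 - p1)) / ((1 - p2_no) * p1)
  report <- structure(list(
    counts = c(pathogenic_abnormal = path_ab, benign_abnormal = ben_ab,
               pathogenic_normal = path_no, benign_normal = ben_no),
    P1 = p1, P2_abnormal = p2_ab, P2_normal = p2_no,
    oddspath_pathogenic = op_path, oddspath_benign = op_ben,
    corrections_applied = corrections), class = "oddspath_report")
  report$strengths <- evidence_strength(report)
  report
}

#' Map OddsPath values to ACMG/AMP evidence strengths
#'
#' ClinGen SVI scale: the pathogenic-side OddsPath earns PS3 at supporting
#' (> 2.1), moderate (> 4.3), strong (> 18.7), or very strong (> 350)
#' level; the benign-side OddsPath earns BS3 at supporting (< 0.48),
#' moderate (< 0.23), strong (< 0.053), or very strong (< 0.0029) level.
#'
#' @param report An `"oddspath_report"`, or a list with elements
#'   `oddspath_pathogenic` and `oddspath_benign`.
#' @return Character vector of length 2: `PS3` and `BS3` strengths (`"none"`
#'   when the threshold is not met).
#' @examples
#' evidence_strength(list(oddspath_pathogenic = 5.25, oddspath_benign = 0.25))
#' @export
evidence_strength <- function(report) {
  op <- report$oddspath_pathogenic
  ob <- report$oddspath_benign
  ps3 <- if (op > 350) "PS3_very_strong" else if (op > 18.7) "PS3_strong"
  else if (op > 4.3) "PS3_moderate" else if (op > 2.1) "PS3_supporting"
  else "none"
  bs3 <- if (ob < 0.0029) "BS3_very_strong" else if (ob < 0.053) "BS3_strong"
  else if (ob < 0.23) "BS3_moderate" else if (ob < 0.48) "BS3_supporting"
  else "none"
  c(PS3 = ps3, BS3 = bs3)
}

#' Calibrate an assay against curated controls
#'
#' Joins curated controls to a score table, derives readouts, and computes
#' the OddsPath report.
#'
#' @param controls Output of [curate_controls()] (needs `name` and
#'   `presumed_label`).
#' @param scores Score table with `hgvs_pro`, `score`, `ci_lower`,
#'   `ci_upper`.
#' @param lo_cutoff,hi_cutoff Readout cutoffs (see [assay_readout()]).
#' @return A list with `controls` (the joined table plus `readout`) and
#'   `report` (the `"oddspath_report"`).
#' @export
calibrate_assay <- function(controls, scores, lo_cutoff = 0.44,
                            hi_cutoff = 1.43) {
  idx <- match(controls$name, scores$hgvs_pro)
  controls$score <- scores$score[idx]
  controls$ci_lower <- scores$ci_lower[idx]
  controls$ci_upper <- scores$ci_upper[idx]
  controls$readout <- assay_readout(controls$score, controls$ci_lower,
                                    controls$ci_upper, lo_cutoff, hi_cutoff)
  report <- oddspath(controls$presumed_label, controls$readout)
  list(controls = controls, report = report)
}
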