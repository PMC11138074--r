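#' Enumerate the single-amino-acid outcome space of a protein
#'
#' For every residue of a protein there are 21 possible single-amino-acid
#' outcomes of saturation mutagenesis: 19 missense substitutions, one
#' synonymous outcome (recoding the residue to itself), and one nonsense
#' (stop) outcome. A 129-residue protein therefore has 129 x 21 = 2709
#' possible outcomes.
#'
#' @param reference Either the reference protein as a one-letter amino-acid
#'   string (preferred; reference residues are then filled in), or a single
#'   positive integer giving the protein length, in which case `ref_aa` is
#'   `NA` and missense alternates are left unspecified.
#' @return A data frame with one row per outcome and columns `position`,
#'   `ref_aa`, `alt_aa` (`"*"` for stop, `"="` for synonymous), `vclass`
#'   (`"missense"`, `"synonymous"`, or `"nonsense"`) and `name`.
#' @examples
#' nrow(enumerate_site_outcomes(129)) # 2709
#' enumerate_site_outcomes("MA")
#' @export
enumerate_site_outcomes <- function(reference) {
  if (is.numeric(reference)) {
    if (length(reference) != 1L || is.na(reference) || reference < 1 ||
        reference != round(reference)) {
      stop("protein length must be a single positive integer")
    }
    len <- as.integer(reference)
    refs <- rep(NA_character_, len)
  } else {
    refs <- strsplit(toupper(as.character(reference)), "")[[1]]
    if (length(refs) < 1L) stop("protein length must be >= 1")
    bad <- setdiff(refs, AA_STANDARD)
    if (length(bad)) stop("non-standard residues in reference: ",
                          paste(bad, collapse = ", "))
    len <- length(refs)
  }
  per_site <- function(pos) {
    ref <- refs[pos]
    if (is.na(ref)) {
      alt <- c(rep(NA_character_, 19L), "=", "*")
    } else {
      alt <- c(setdiff(AA_STANDARD, ref), "=", "*")
    }
    data.frame(position = pos, ref_aa = ref, alt_aa = alt,
               vclass = c(rep("missense", 19L), "synonymous", "nonsense"),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(len), per_site))
  out$name <- ifelse(is.na(out$ref_aa) | (out$vclass == "missense" & is.na(out$alt_aa)),
                     NA_character_,
                     variant_name(out$position, out$ref_aa, out$alt_aa)$short)
  rownames(out) <- NULL
  out
}

#' The 32 NNK degenerate codons and their translations
#'
#' NNK codons (N = A/C/G/T, K = G/T) are the standard saturation-mutagenesis
#' alphabet: the 32 codons encode all 20 amino acids plus a single stop
#' codon, TAG.
#'
#' @return A data frame with columns `codon` and `aa` (one-letter amino acid,
#'   `"*"` for stop), 32 rows.
#' @examples
#' tab <- nnk_codons()
#' nrow(tab)                       # 32
#' sort(unique(tab$aa))            # the 20 amino acids and "*"
#' @export
nnk_codons <- function() {
  n <- c("A", "C", "G", "T")
  k <- c("G", "T")
  grid <- expand.grid(p1 = n, p2 = n, p3 = k, stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$p1, grid$p2, grid$p3))
  data.frame(codon = codons, aa = unname(codon_table()[codons]),
             stringsAsFactors = FALSE)
}

# Hamming distance between equal-length nucleotide strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

#' Single-nucleotide accessibility of an amino-acid change from a codon
#'
#' Given the reference codon at a site, reports the minimum number of
#' nucleotide substitutions needed to reach any codon encoding the
#' alternate amino acid, and labels each single-substitution path as a
#' transition (A<->G, C<->T) or transversion. Transition SNVs arise more
#' often in nature, and the genetic code buffers their chemical impact, so
#' this annotation supports contrasts of variant effect by mutation type.
#'
#' @param ref_codon Reference codon (3 nucleotides, ACGT).
#' @param alt_aa Target amino acid (one letter), `"*"` for stop, or `"="`
#'   for a synonymous recoding (a different codon for the same residue).
#' @return A list with `accessible_by_1_snv` (logical), `min_snvs` (1-3),
#'   and `mutation_types`: for each codon reachable in one substitution, a
#'   character vector naming the changed position and whether the step is a
#'   transition or transversion (empty when `min_snvs > 1`).
#' @examples
#' snv_accessibility("AAA", "N")$accessible_by_1_snv # TRUE
#' snv_accessibility("AAA", "F")$min_snvs            # 2
#' @export
snv_accessibility <- function(ref_codon, alt_aa) {
  ref_codon <- toupper(ref_codon)
  if (!grepl("^[ACGT]{3}$", ref_codon)) stop("ref_codon must be 3 ACGT bases")
  ct <- codon_table()
  ref_aa <- unname(ct[ref_codon])
  target <- if (identical(alt_aa, "=")) ref_aa else alt_aa
  cands <- names(ct)[ct == target]
  cands <- setdiff(cands, ref_codon)
  if (!length(cands)) stop("no codon encodes '", alt_aa, "'")
  d <- vapply(cands, hamming, integer(1), a = ref_codon)
  min_snvs <- min(d)
  types <- character(0)
  if (min_snvs == 1L) {
    for (cand in cands[d == 1L]) {
      rb <- strsplit(ref_codon, "")[[1]]
      cb <- strsplit(cand, "")[[1]]
      pos <- which(rb != cb)
      lab <- if (is_transition(rb[pos], cb[pos])) "transition" else "transversion"
      types <- c(types, setNames(lab, paste0(ref_codon, ">", cand)))
    }
  }
  list(accessible_by_1_snv = min_snvs == 1L,
       min_snvs = as.integer(min_snvs),
       mutation_types = types)
}

#' Name a single-amino-acid variant
#'
#' Produces a protein-HGVS-like long form (`"p.L51H"`, `"p.L51Ter"`,
#' `"p.G10="`) and the short form customary in the deep-mutational-scanning
#' literature (`"L51H"`, `"L51*"`, `"G10="`).
#'
#' @param position 1-based residue index (vectorised).
#' @param ref_aa Reference residue, one letter.
#' @param alt_aa Alternate residue, `"*"` for stop, or `"="` (or the
#'   reference residue itself) for synonymous.
#' @return A list with character vectors `long` and `short`.
#' @examples
#' variant_name(51, "L", "H")$short # "L51H"
#' variant_name(76, "D", "N")$short # "D76N"
#' variant_name(10, "G", "G")$short # "G10="
#' @export
variant_name <- function(position, ref_aa, alt_aa) {
  stopifnot(length(position) == length(ref_aa),
            length(position) == length(alt_aa))
  alt <- ifelse(alt_aa == ref_aa, "=", alt_aa)
  long_alt <- ifelse(alt == "*", "Ter", alt)
  list(long = paste0("p.", ref_aa, position, long_alt),
       short = paste0(ref_aa, position, alt))
}

#' Classify a substitution as missense, synonymous, or nonsense
#'
#' @param ref_aa,alt_aa One-letter residues; `"*"` marks stop and `"="`
#'   marks synonymous.
#' @return Character vector of `"missense"`, `"synonymous"`, `"nonsense"`.
#' @export
variant_class <- function(ref_aa, alt_aa) {
  ifelse(alt_aa == "*", "nonsense",
         ifelse(alt_aa == "=" | alt_aa == ref_aa, "synonymous", "missense"))
}
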