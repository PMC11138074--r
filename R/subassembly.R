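#' Call the variant carried by a single subassembly read
#'
#' Compares a read covering the full mutated region against the reference
#' CDS codon-by-codon. The NNK mutagenesis design introduces exactly one
#' substituted codon per molecule, so reads with more than one altered codon
#' (template switching, PCR chimeras) and reads whose length differs from
#' the reference (indels) are rejected rather than repaired.
#'
#' @param read_seq Nucleotide string covering the CDS region.
#' @param ref A `"reference_model"`.
#' @return A list with `status` (`"wt"`, `"variant"`, or `"rejected"`),
#'   `name` (variant short name, `"WT"`, or `NA`), `reason` (for rejects:
#'   `"multi-codon"` or `"indel/length"`), and for variants the fields
#'   `position`, `ref_aa`, `alt_aa`, `vclass`.
#' @export
call_variant <- function(read_seq, ref) {
  read_seq <- toupper(read_seq)
  if (nchar(read_seq) != nchar(ref$cds)) {
    return(list(status = "rejected", name = NA_character_,
                reason = "indel/length"))
  }
  rb <- strsplit(ref$cds, "")[[1]]
  qb <- strsplit(read_seq, "")[[1]]
  diff_codons <- unique((which(rb != qb) - 1L) %/% 3L + 1L)
  if (!length(diff_codons)) {
    return(list(status = "wt", name = "WT", reason = NA_character_))
  }
  if (length(diff_codons) > 1L) {
    return(list(status = "rejected", name = NA_character_,
                reason = "multi-codon"))
  }
  pos <- diff_codons
  ref_aa <- unname(codon_table()[codon_at(ref, pos)])
  alt_codon <- substr(read_seq, 3 * pos - 2, 3 * pos)
  alt_raw <- unname(codon_table()[alt_codon])
  alt_aa <- if (alt_raw == ref_aa) "=" else alt_raw
  list(status = "variant",
       name = variant_name(pos, ref_aa, alt_aa)$short,
       reason = NA_character_, position = pos, ref_aa = ref_aa,
       alt_aa = alt_aa, vclass = variant_class(ref_aa, alt_aa))
}

#' Link barcodes to variants from subassembly read evidence
#'
#' Groups reads by barcode, calls the variant on each distinct read
#' sequence, and retains a barcode when (a) its total read support reaches
#' `min_reads` and (b) the plurality variant call accounts for at least
#' `min_consensus` of all its reads (uncallable reads count against the
#' consensus). Plurality ties are broken lexicographically by variant name
#' so the map is independent of input order.
#'
#' @param evidence Data frame with columns `barcode`, `read_seq`, `count`.
#' @param ref A `"reference_model"`.
#' @param min_reads Minimum total reads per barcode (default 5).
#' @param min_consensus Minimum plurality fraction in (0.5, 1] (default 0.9).
#' @return A list of class `"barcode_map_call"` with `map` (retained
#'   barcodes: `barcode`, `name`, `position`, `ref_aa`, `alt_aa`, `vclass`,
#'   `reads`, `consensus`) and `rejected` (`barcode`, `reason`, `reads`).
#'   Wild-type barcodes are retained with `name == "WT"`.
#' @export
build_barcode_map <- function(evidence, ref, min_reads = 5L,
                              min_consensus = 0.9) {
  stopifnot(min_reads >= 1, min_consensus > 0.5, min_consensus <= 1)
  need <- c("barcode", "read_seq", "count")
  if (!all(need %in% names(evidence))) {
    stop("evidence needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(evidence)) {
    empty_map <- data.frame(barcode = character(), name = character(),
                            position = integer(), ref_aa = character(),
                            alt_aa = character(), vclass = character(),
                            reads = integer(), consensus = numeric())
    return(structure(list(map = empty_map,
                          rejected = data.frame(barcode = character(),
                                                reason = character(),
                                                reads = integer())),
                     class = "barcode_map_call"))
  }
  stopifnot(all(evidence$count >= 1))
  # call each distinct read sequence once
  seqs <- unique(evidence$read_seq)
  calls <- lapply(seqs, call_variant, ref = ref)
  names(calls) <- seqs
  map_rows <- list()
  rej_rows <- list()
  ev_split <- split(evidence[c("read_seq", "count")], evidence$barcode)
  for (bc in sort(names(ev_split))) {
    ev <- ev_split[[bc]]
    total <- sum(ev$count)
    if (total < min_reads) {
      rej_rows[[bc]] <- data.frame(barcode = bc, reason = "low support",
                                   reads = total)
      next
    }
    bc_calls <- calls[ev$read_seq]
    callable <- !vapply(bc_calls, function(x) x$status == "rejected",
                        logical(1))
    votes <- tapply(ev$count[callable],
                    vapply(bc_calls[callable], `[[`, "", "name"), sum)
    if (!length(votes)) {
      rej_rows[[bc]] <- data.frame(barcode = bc, reason = "no callable reads",
                                   reads = total)
      next
    }
    votes <- votes[order(-votes, names(votes))] # plurality, ties lexicographic
    top <- names(votes)[1]
    consensus <- unname(votes[1]) / total
    if (consensus < min_consensus) {
      rej_rows[[bc]] <- data.frame(barcode = bc, reason = "low consensus",
                                   reads = total)
      next
    }
    call <- bc_calls[[which(vapply(bc_calls, `[[`, "", "name") == top)[1]]]
    map_rows[[bc]] <- data.frame(
      barcode = bc, name = top,
      position = if (call$status == "variant") call$position else NA_integer_,
      ref_aa = if (call$status == "variant") call$ref_aa else NA_character_,
      alt_aa = if (call$status == "variant") call$alt_aa else NA_character_,
      vclass = if (call$status == "variant") call$vclass else "wt",
      reads = total, consensus = consensus)
  }
  bind <- function(rows, proto) {
    if (length(rows)) {
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    } else proto
  }
  structure(list(
    map = bind(map_rows, data.frame(barcode = character(), name = character(),
                                    position = integer(), ref_aa = character(),
                                    alt_aa = character(), vclass = character(),
                                    reads = integer(), consensus = numeric())),
    rejected = bind(rej_rows, data.frame(barcode = character(),
                                         reason = character(),
                                         reads = integer()))),
    class = "barcode_map_call")
}

#' Extract barcode/CDS evidence from FASTQ reads at fixed coordinates
#'
#' Thin ingestion helper for pre-demultiplexed, oriented reads where the
#' barcode and the mutated CDS window sit at fixed positions. Substrings
#' are taken with 0-based half-open coordinates and tallied into the
#' evidence table consumed by [build_barcode_map()].
#'
#' @param fastq Path to an (uncompressed or gzipped) FASTQ file.
#' @param barcode_window,cds_window Integer pairs `c(start, end)`, 0-based
#'   half-open, locating the barcode and variant region within each read.
#' @return Evidence data frame (`barcode`, `read_seq`, `count`).
#' @export
fastq_evidence <- function(fastq, barcode_window, cds_window) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  bc <- substr(reads, barcode_window[1] + 1L, barcode_window[2])
  cds <- substr(reads, cds_window[1] + 1L, cds_window[2])
  tab <- aggregate(list(count = rep(1L, length(bc))),
                   by = list(barcode = bc, read_seq = cds), FUN = sum)
  tab[order(tab$barcode, tab$read_seq), , drop = FALSE]
}
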