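#' Build a reference model from a coding sequence
#'
#' @param cds Coding nucleotide sequence (length divisible by 3). A trailing
#'   stop codon is permitted and trimmed from the protein.
#' @return A list of class `"reference_model"` with elements `cds` and
#'   `protein`.
#' @export
reference_model <- function(cds) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                no.init.codon = TRUE))
  # allow (and trim) a terminal stop; reject internal stops
  if (endsWith(protein, "*")) protein <- substr(protein, 1, nchar(protein) - 1)
  if (grepl("\\*", protein)) stop("reference CDS contains an internal stop codon")
  structure(list(cds = cds, protein = protein), class = "reference_model")
}

#' Read a reference coding sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return A `"reference_model"` (see [reference_model()]).
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path)
  reference_model(as.character(seqs[[1]]))
}

# Codon at 1-based residue index.
codon_at <- function(ref, position) {
  substr(ref$cds, 3 * position - 2, 3 * position)
}

#' Generate a random coding sequence for a protein of given length
#'
#' Used by the synthetic-data generator when no reference FASTA is supplied.
#' Draws sense codons uniformly (no stop codons), so the translated protein
#' has no internal stops by construction. Uses the current RNG state.
#'
#' @param protein_length Number of residues.
#' @return A `"reference_model"`.
#' @export
random_reference <- function(protein_length) {
  ct <- codon_table()
  sense <- names(ct)[ct != "*"]
  reference_model(paste(sample(sense, protein_length, replace = TRUE),
                        collapse = ""))
}
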