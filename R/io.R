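# Readers and writers for the pipeline's tabular formats: count matrices
# with "rep:bin" / "rep:day" sample metadata in the header, barcode maps,
# and MaveDB-style score CSVs.

#' Write a count matrix with sample-role headers
#'
#' Samples are encoded in column names as `rep<r>_bin<b>` (sort-seq) or
#' `rep<r>_day<d>` (depletion), so the file round-trips through
#' [read_count_matrix()] without a sidecar.
#'
#' @param counts Integer matrix with barcode/variant rownames.
#' @param path Output TSV path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix and parse sample roles from its header
#'
#' @param path TSV written by [write_count_matrix()] (first column `id`,
#'   remaining columns named `rep<r>_bin<b>` or `rep<r>_day<d>`).
#' @return A list with `counts` (integer matrix) and `sample_info` (data
#'   frame with `sample`, `replicate`, and `bin` or `day`).
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  samples <- colnames(counts)
  m <- regmatches(samples, regexec("^rep([0-9]+)_(bin|day)([0-9]+)$", samples))
  if (any(lengths(m) != 4)) {
    stop("sample columns must be named rep<r>_bin<b> or rep<r>_day<d>")
  }
  role <- vapply(m, `[`, "", 3)
  info <- data.frame(sample = samples,
                     replicate = as.integer(vapply(m, `[`, "", 2)))
  info[[unique(role)]] <- as.integer(vapply(m, `[`, "", 4))
  list(counts = counts, sample_info = info)
}

#' Write / read a barcode-to-variant table
#'
#' @param barcode_table Data frame with at least `barcode` and `name`.
#' @param path TSV path.
#' @export
write_barcode_table <- function(barcode_table, path) {
  write.table(barcode_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a score table as a MaveDB-style CSV
#'
#' Columns: `hgvs_pro`, `score`, `ci_lower`, `ci_upper`, `n_barcodes`,
#' per-replicate score columns, plus the variant identity columns used by
#' downstream classification.
#'
#' @param scores Score table from [score_sortseq()] / [score_fitness()]
#'   (optionally classified).
#' @param path Output CSV path.
#' @export
write_score_csv <- function(scores, path) {
  lead <- c("hgvs_pro", "score", "ci_lower", "ci_upper", "n_barcodes")
  rest <- setdiff(names(scores), lead)
  write.csv(scores[, c(lead, rest)], path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_score_csv
#' @export
read_score_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("category" %in% names(df)) {
    df$category <- factor(df$category, levels = CATEGORY_LEVELS,
                          ordered = TRUE)
  }
  df
}

#' Barcode-to-variant table of a simulated library
#'
#' Flattens a `"sim_library"` into the `barcode_table` format consumed by
#' [score_sortseq()] and [score_fitness()] (columns `barcode`, `name`,
#' `position`, `ref_aa`, `alt_aa`, `vclass`).
#'
#' @param lib A `"sim_library"` from [simulate_library()].
#' @return Data frame with one row per barcode.
#' @export
sim_barcode_table <- function(lib) {
  cbind(lib$barcode_map["barcode"],
        lib$truth[lib$barcode_map$variant,
                  c("name", "position", "ref_aa", "alt_aa", "vclass")],
        row.names = NULL)
}
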