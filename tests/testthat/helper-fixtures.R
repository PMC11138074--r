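# Shared fixtures, all generated in code at test time.

# One small desk-scale simulation, computed lazily and cached for the run.
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(protein_length = 20, n_barcodes_mean = 10,
                      reads_per_sample = 2e5, cells_per_replicate = 2e5,
                      seed = 7)
    lib <- simulate_library(cfg)
    bt <- sim_barcode_table(lib)
    sortseq <- simulate_sortseq(lib)
    depletion <- simulate_depletion(lib)
    traffic <- score_sortseq(sortseq$counts, sortseq$sample_info, bt,
                             n_boot = 100, seed = 3)
    func <- score_fitness(depletion$counts, depletion$sample_info, bt,
                          n_boot = 100, seed = 3)
    .fixture_cache$small <- list(cfg = cfg, lib = lib, bt = bt,
                                 sortseq = sortseq, depletion = depletion,
                                 traffic = traffic, func = func)
  }
  .fixture_cache$small
}

# Effect model in which every class is drawn from the same point mass.
flat_effect_model <- function(tau = 1, phi = 1) {
  em <- default_effect_model()
  em$synonymous$tau <- c(mean = tau, sd = 0)
  em$synonymous$phi <- c(mean = phi, sd = 0)
  for (f in c("tau_early", "tau_late")) em$nonsense[[f]] <- c(mean = tau, sd = 0)
  for (f in c("phi_early", "phi_late")) em$nonsense[[f]] <- c(mean = phi, sd = 0)
  em$missense$tau$mean[] <- tau
  em$missense$tau$sd[] <- 0
  em$missense$phi$mean[] <- phi
  em$missense$phi$sd[] <- 0
  em
}

# Hand-built two-variant library for limit-case simulations.
two_variant_library <- function(tau, phi, n_barcodes = 50, cfg) {
  truth <- data.frame(position = c(1L, 2L), ref_aa = "A",
                      alt_aa = c("V", "G"), vclass = "missense",
                      name = c("A1V", "A2G"), tau = tau, phi = phi)
  if (length(n_barcodes) == 1) n_barcodes <- rep(n_barcodes, 2)
  owner <- rep(1:2, times = n_barcodes)
  bmap <- data.frame(barcode = paste0("bc", seq_along(owner)),
                     name = truth$name[owner], variant = owner)
  structure(list(truth = truth, barcode_map = bmap, config = cfg),
            class = "sim_library")
}

# Subassembly read-evidence generator: per barcode, `reads` reads of its
# true variant sequence, each independently hit by a random single-base
# miscall with probability `error_rate`.
make_evidence <- function(ref, barcode_truth, reads = 20, error_rate = 0) {
  rows <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(barcode_truth))) {
    true_seq <- barcode_truth$read_seq[i]
    seqs <- rep(true_seq, reads)
    hit <- runif(reads) < error_rate
    for (j in which(hit)) {
      pos <- sample.int(nchar(true_seq), 1)
      wrong <- sample(setdiff(bases, substr(seqs[j], pos, pos)), 1)
      substr(seqs[j], pos, pos) <- wrong
    }
    tab <- table(seqs)
    rows[[i]] <- data.frame(barcode = barcode_truth$barcode[i],
                            read_seq = names(tab),
                            count = as.integer(tab))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mutate one codon of a CDS to the given codon.
mutate_codon <- function(cds, position, codon) {
  paste0(substr(cds, 1, 3 * position - 3), codon,
         substr(cds, 3 * position + 1, nchar(cds)))
}

# Minimal fixed-width PDB writer for toy structures.
write_toy_pdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), atoms$name, atoms$alt %||% "", atoms$resn,
    atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    atoms$occ %||% 1, 0, atoms$elem)
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
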