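#' Wallace-rule melting temperature of a mutagenesis primer
#'
#' The 2+4 (Wallace) rule used to design inverse-PCR saturation mutagenesis
#' primers: Tm = 4 x (#G + #C) + 2 x (#A + #T), with a typical design target
#' of 58 degrees C.
#'
#' @param seq Nucleotide string over ACGT (case-insensitive; may be empty).
#' @return Integer temperature in degrees C.
#' @examples
#' primer_tm("ATGC") # 12
#' @export
primer_tm <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("primer contains non-ACGT characters")
  bases <- strsplit(seq, "")[[1]]
  4L * sum(bases %in% c("G", "C")) + 2L * sum(bases %in% c("A", "T"))
}

#' Default latent effect model for the simulator
#'
#' Each variant carries two latent values: a surface-expression level `tau`
#' and a functional activity `phi`, both on a scale anchored at 1 for
#' wild-type-like variants and 0 for complete loss. Synonymous variants
#' scatter around 1; nonsense variants are early (complete loss) or late
#' (wild-type-like) depending on whether the truncation falls before the
#' assay-specific boundary residue (55 for surface expression, 104 for
#' function); missense variants are drawn from a four-component mixture
#' (loss / partial / normal / gain). Values are truncated at 0.
#'
#' @return A nested list of class means/sds and mixture weights, suitable
#'   for the `effect_model` field of [sim_config()].
#' @export
default_effect_model <- function() {
  list(
    synonymous = list(tau = c(mean = 1, sd = 0.09), phi = c(mean = 1, sd = 0.2)),
    nonsense = list(
      tau_early = c(mean = 0.02, sd = 0.03), tau_late = c(mean = 1, sd = 0.15),
      phi_early = c(mean = 0.02, sd = 0.03), phi_late = c(mean = 1, sd = 0.12),
      tau_boundary = 55L, phi_boundary = 104L),
    missense = list(
      tau = list(prob = c(loss = 0.12, partial = 0.12, normal = 0.63, gain = 0.13),
                 mean = c(loss = 0.05, partial = 0.5, normal = 1, gain = 1.5),
                 sd = c(loss = 0.05, partial = 0.12, normal = 0.09, gain = 0.15)),
      phi = list(prob = c(loss = 0.17, partial = 0.17, normal = 0.655, gain = 0.005),
                 mean = c(loss = 0.05, partial = 0.3, normal = 1, gain = 1.6),
                 sd = c(loss = 0.05, partial = 0.1, normal = 0.2, gain = 0.1))))
}

#' Simulation configuration
#'
#' @param protein_length Residues in the simulated protein (default 129).
#' @param reference Optional `"reference_model"`; when `NULL` a random
#'   stop-free coding sequence of `protein_length` residues is drawn.
#' @param n_barcodes_mean Mean barcodes per variant (default 30.7), realised
#'   through a zero-truncated negative binomial to mimic cloning dispersion.
#' @param barcode_length Barcode length in nucleotides (default 18).
#' @param n_replicates Independent experimental replicates (default 3).
#' @param reads_per_sample Sequencing reads per sample (default 2.5e7, the
#'   stated sequencing floor of the experiments this generator emulates;
#'   scale down for quick tests).
#' @param cells_per_replicate Sorted/cultured cells per replicate (default
#'   3.2e6, i.e. four sorted bins of 8e5 cells).
#' @param bin_count Number of FACS bins (fixed at 4).
#' @param fluorescence_sd Cell-level lognormal spread of surface fluorescence
#'   around the variant's latent `tau` (default 0.5).
#' @param growth_coupling Fitness cost per unit activity per day; default
#'   `log(10)/20` so a fully active variant depletes 10-fold by day 20.
#' @param days Sampling days for the depletion assay (default 0, 8, 20).
#' @param effect_model Latent effect model; see [default_effect_model()].
#' @param barcode_dispersion Negative-binomial size parameter for barcode
#'   counts per variant (default 3).
#' @param seed Integer seed; every simulation stage derives its own
#'   substream from it, so identical configs give identical output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(protein_length = 129L, reference = NULL,
                       n_barcodes_mean = 30.7, barcode_length = 18L,
                       n_replicates = 3L, reads_per_sample = 2.5e7,
                       cells_per_replicate = 3.2e6, bin_count = 4L,
                       fluorescence_sd = 0.5, growth_coupling = log(10) / 20,
                       days = c(0, 8, 20), effect_model = default_effect_model(),
                       barcode_dispersion = 3, seed = 1L) {
  stopifnot(protein_length >= 1, n_barcodes_mean > 0, barcode_length >= 1,
            n_replicates >= 1, reads_per_sample >= 1, cells_per_replicate >= 1,
            bin_count == 4L, length(days) >= 2, days[1] == 0,
            all(diff(days) > 0))
  structure(as.list(environment()), class = "sim_config")
}

# Mean of a zero-truncated NB(size, mu) is mu / (1 - P(X = 0)); invert so the
# truncated mean hits the requested barcode count.
ztnb_mu <- function(target_mean, size) {
  f <- function(mu) mu / (1 - (size / (size + mu))^size) - target_mean
  uniroot(f, c(1e-6, target_mean * 2))$root
}

rztnb <- function(n, size, mu) {
  x <- rnbinom(n, size = size, mu = mu)
  while (any(x == 0L)) {
    idx <- which(x == 0L)
    x[idx] <- rnbinom(length(idx), size = size, mu = mu)
  }
  x
}

draw_trunc_norm <- function(n, par) pmax(0, rnorm(n, par[["mean"]], par[["sd"]]))

# Draw one latent value (tau or phi) per variant according to class.
draw_latents <- function(variants, em, which = c("tau", "phi")) {
  which <- match.arg(which)
  n <- nrow(variants)
  val <- numeric(n)
  cls <- character(n)
  syn <- variants$vclass == "synonymous"
  non <- variants$vclass == "nonsense"
  mis <- variants$vclass == "missense"
  val[syn] <- draw_trunc_norm(sum(syn), em$synonymous[[which]])
  cls[syn] <- "synonymous"
  boundary <- em$nonsense[[paste0(which, "_boundary")]]
  early <- non & variants$position <= boundary
  late <- non & !variants$position <= boundary
  val[early] <- draw_trunc_norm(sum(early), em$nonsense[[paste0(which, "_early")]])
  cls[early] <- "nonsense_early"
  val[late] <- draw_trunc_norm(sum(late), em$nonsense[[paste0(which, "_late")]])
  cls[late] <- "nonsense_late"
  mix <- em$missense[[which]]
  comp <- sample(names(mix$prob), sum(mis), replace = TRUE,
                 prob = mix$prob / sum(mix$prob))
  val[mis] <- pmax(0, rnorm(sum(mis), mix$mean[comp], mix$sd[comp]))
  cls[mis] <- comp
  list(value = val, class = cls)
}

random_barcodes <- function(n, len) {
  draw <- function(k) {
    apply(matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                 nrow = k), 1, paste, collapse = "")
  }
  bc <- draw(n)
  for (i in 1:100) {
    dup <- duplicated(bc)
    if (!any(dup)) return(bc)
    bc[dup] <- draw(sum(dup))
  }
  stop("barcode space exhausted")
}

#' Simulate a barcoded saturation-mutagenesis library
#'
#' Enumerates all 21 single-amino-acid outcomes per residue, draws latent
#' surface-expression (`tau`) and functional (`phi`) values per variant from
#' the configured effect model, and assigns each variant a zero-truncated
#' negative-binomial number of unique random barcodes.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_library"` with `reference`, `truth` (one
#'   row per variant: identity, latent values, component labels) and
#'   `barcode_map` (one row per barcode: `barcode`, `name`, `variant` index
#'   into `truth`), plus the `config`.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ref <- cfg$reference %||% random_reference(cfg$protein_length)
  truth <- enumerate_site_outcomes(ref$protein)
  tau <- draw_latents(truth, cfg$effect_model, "tau")
  phi <- draw_latents(truth, cfg$effect_model, "phi")
  truth$tau <- tau$value
  truth$phi <- phi$value
  truth$tau_class <- tau$class
  truth$phi_class <- phi$class
  mu <- ztnb_mu(cfg$n_barcodes_mean, cfg$barcode_dispersion)
  nbc <- rztnb(nrow(truth), cfg$barcode_dispersion, mu)
  owner <- rep(seq_len(nrow(truth)), nbc)
  barcode_map <- data.frame(
    barcode = random_barcodes(length(owner), cfg$barcode_length),
    name = truth$name[owner], variant = owner, stringsAsFactors = FALSE)
  structure(list(reference = ref, truth = truth, barcode_map = barcode_map,
                 config = cfg), class = "sim_library")
}

# Per-replicate cloning/transfection abundance for each barcode.
barcode_abundance <- function(n) rgamma(n, shape = 5, rate = 5)

sample_reads <- function(weights, depth) {
  if (sum(weights) <= 0) return(integer(length(weights)))
  as.integer(rmultinom(1, depth, weights))
}

#' Simulate a four-bin sort-seq experiment
#'
#' For each replicate, cells are allotted to barcodes multinomially, each
#' cell's surface fluorescence is drawn lognormally around its variant's
#' latent `tau`, cells are split into four equal-occupancy bins at the
#' pooled population quartiles, and `reads_per_sample` sequencing reads are
#' drawn multinomially from each bin's cell pool.
#'
#' @param lib A `"sim_library"` from [simulate_library()].
#' @param cfg Optional config override (defaults to `lib$config`).
#' @return A list with `counts` (integer matrix, barcodes x samples) and
#'   `sample_info` (data frame: `sample`, `replicate`, `bin`).
#' @export
simulate_sortseq <- function(lib, cfg = lib$config) {
  nb <- nrow(lib$barcode_map)
  tau <- lib$truth$tau[lib$barcode_map$variant]
  counts <- matrix(0L, nb, cfg$n_replicates * cfg$bin_count,
                   dimnames = list(lib$barcode_map$barcode, NULL))
  info <- expand.grid(bin = seq_len(cfg$bin_count),
                      replicate = seq_len(cfg$n_replicates))[, 2:1]
  colnames(counts) <- paste0("rep", info$replicate, "_bin", info$bin)
  info <- data.frame(sample = colnames(counts), replicate = info$replicate,
                     bin = info$bin)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(cfg$seed + 1000L + r)
    f0 <- barcode_abundance(nb)
    ncells <- as.integer(rmultinom(1, cfg$cells_per_replicate, f0))
    cell_bc <- rep.int(seq_len(nb), ncells)
    fluor <- tau[cell_bc] * exp(cfg$fluorescence_sd * rnorm(length(cell_bc)))
    bin <- ceiling(cfg$bin_count * rank(fluor, ties.method = "random") /
                     length(fluor))
    cell_tab <- matrix(tabulate(cell_bc + nb * (bin - 1L), nb * cfg$bin_count),
                       nrow = nb)
    for (b in seq_len(cfg$bin_count)) {
      counts[, paste0("rep", r, "_bin", b)] <-
        sample_reads(cell_tab[, b], cfg$reads_per_sample)
    }
  }
  list(counts = counts, sample_info = info)
}

#' Simulate a depletion (cell-fitness) time course
#'
#' Each barcode's expected frequency at day t is proportional to its
#' baseline abundance times `exp(-growth_coupling * phi * t)`: fully active
#' variants (`phi` = 1) are selected against and deplete, inactive variants
#' persist. Reads are drawn multinomially per sample.
#'
#' @inheritParams simulate_sortseq
#' @return A list with `counts` (barcodes x samples) and `sample_info`
#'   (data frame: `sample`, `replicate`, `day`).
#' @export
simulate_depletion <- function(lib, cfg = lib$config) {
  nb <- nrow(lib$barcode_map)
  phi <- lib$truth$phi[lib$barcode_map$variant]
  nd <- length(cfg$days)
  counts <- matrix(0L, nb, cfg$n_replicates * nd,
                   dimnames = list(lib$barcode_map$barcode, NULL))
  info <- expand.grid(day = cfg$days, replicate = seq_len(cfg$n_replicates))[, 2:1]
  colnames(counts) <- paste0("rep", info$replicate, "_day", info$day)
  info <- data.frame(sample = colnames(counts), replicate = info$replicate,
                     day = info$day)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(cfg$seed + 2000L + r)
    f0 <- barcode_abundance(nb)
    for (d in cfg$days) {
      w <- f0 * exp(-cfg$growth_coupling * phi * d)
      counts[, paste0("rep", r, "_day", d)] <-
        sample_reads(w, cfg$reads_per_sample)
    }
  }
  list(counts = counts, sample_info = info)
}
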