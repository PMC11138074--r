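# Synthetic-data generator: primer design helper, library, sort-seq and
# depletion simulations.

test_that("Wallace-rule primer Tm is exact", {
  expect_equal(primer_tm("ATGC"), 12)
  expect_equal(primer_tm(""), 0)
  expect_equal(primer_tm("GGCC"), 16)
  expect_equal(primer_tm("atat"), 8) # case-insensitive
  # 58-degree design target is reachable: e.g. 9 GC + 11 AT
  expect_equal(primer_tm(paste0(strrep("G", 9), strrep("A", 11))), 58)
  expect_error(primer_tm("ATGX"), "non-ACGT")
})

test_that("simulated library matches its configuration", {
  s <- small_sim()
  lib <- s$lib
  expect_equal(nrow(lib$truth), 20 * 21)
  expect_false(any(duplicated(lib$barcode_map$barcode)))
  expect_true(all(nchar(lib$barcode_map$barcode) == 18))
  expect_true(all(lib$barcode_map$variant %in% seq_len(nrow(lib$truth))))
  # every variant owns at least one barcode (zero-truncation)
  expect_setequal(unique(lib$barcode_map$variant), seq_len(nrow(lib$truth)))
  expect_true(all(lib$truth$tau >= 0), all(lib$truth$phi >= 0))
})

test_that("mean barcodes per variant is anchored to the configured 30.7", {
  cfg <- sim_config(protein_length = 40, reads_per_sample = 10,
                    cells_per_replicate = 10, seed = 21)
  lib <- simulate_library(cfg)
  mean_bc <- nrow(lib$barcode_map) / nrow(lib$truth)
  expect_lt(abs(mean_bc - 30.7) / 30.7, 0.05)
})

test_that("simulations are deterministic given the seed", {
  cfg <- sim_config(protein_length = 5, n_barcodes_mean = 5,
                    reads_per_sample = 1e4, cells_per_replicate = 1e4,
                    seed = 99)
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1$barcode_map, lib2$barcode_map)
  expect_identical(lib1$truth, lib2$truth)
  expect_identical(simulate_sortseq(lib1)$counts, simulate_sortseq(lib2)$counts)
  expect_identical(simulate_depletion(lib1)$counts,
                   simulate_depletion(lib2)$counts)
})

test_that("column sums equal the configured read depth exactly", {
  s <- small_sim()
  expect_true(all(colSums(s$sortseq$counts) == s$cfg$reads_per_sample))
  expect_true(all(colSums(s$depletion$counts) == s$cfg$reads_per_sample))
})

test_that("an all-identical effect model gives constant latents", {
  cfg <- sim_config(protein_length = 4, n_barcodes_mean = 3,
                    reads_per_sample = 100, cells_per_replicate = 100,
                    effect_model = flat_effect_model(tau = 1, phi = 1),
                    seed = 5)
  lib <- simulate_library(cfg)
  expect_true(all(lib$truth$phi == 1))
  expect_true(all(lib$truth$tau == 1))
})

test_that("homogeneous fluorescence spreads barcodes evenly over bins", {
  cfg <- sim_config(protein_length = 4, n_barcodes_mean = 20,
                    reads_per_sample = 4e5, cells_per_replicate = 2e5,
                    effect_model = flat_effect_model(), seed = 13)
  lib <- simulate_library(cfg)
  ss <- simulate_sortseq(lib)
  cols <- paste0("rep1_bin", 1:4)
  shares <- prop.table(ss$counts[, cols] + 0, margin = 1)
  # per-barcode bin occupancy concentrates near 25% each
  expect_lt(max(abs(colMeans(shares, na.rm = TRUE) - 0.25)), 0.02)
})

test_that("a zero-tau variant sorts entirely into the dimmest bin", {
  cfg <- sim_config(protein_length = 2, reads_per_sample = 1e5,
                    cells_per_replicate = 1e5, fluorescence_sd = 1e-6,
                    seed = 3)
  # null variant holds well under a quarter of the pool, so it cannot
  # overflow the dimmest bin
  lib <- two_variant_library(tau = c(0, 1), phi = c(1, 1),
                             n_barcodes = c(20, 100), cfg = cfg)
  ss <- simulate_sortseq(lib)
  null_bc <- lib$barcode_map$barcode[lib$barcode_map$name == "A1V"]
  for (r in 1:3) {
    upper <- ss$counts[null_bc, paste0("rep", r, "_bin", 2:4)]
    expect_true(all(upper == 0))
  }
})

test_that("no selection leaves day-20 frequencies at day-0 levels", {
  cfg <- sim_config(protein_length = 2, reads_per_sample = 1e6,
                    cells_per_replicate = 100, seed = 17)
  lib <- two_variant_library(tau = c(1, 1), phi = c(0, 0),
                             n_barcodes = 200, cfg = cfg)
  dp <- simulate_depletion(lib)
  f0 <- dp$counts[, "rep1_day0"] / sum(dp$counts[, "rep1_day0"])
  f20 <- dp$counts[, "rep1_day20"] / sum(dp$counts[, "rep1_day20"])
  expect_gt(cor(f0, f20), 0.99)
  expect_lt(mean(abs(f20 - f0)) / mean(f0), 0.05)
})

test_that("a functional genotype depletes against a null competitor", {
  cfg <- sim_config(protein_length = 2, reads_per_sample = 1e6,
                    cells_per_replicate = 100, seed = 19)
  lib <- two_variant_library(tau = c(1, 1), phi = c(1, 0),
                             n_barcodes = 100, cfg = cfg)
  dp <- simulate_depletion(lib)
  fun_bc <- lib$barcode_map$name == "A1V"
  for (r in 1:3) {
    share <- vapply(c(0, 8, 20), function(d) {
      col <- dp$counts[, paste0("rep", r, "_day", d)]
      sum(col[fun_bc]) / sum(col)
    }, numeric(1))
    expect_true(all(diff(share) < 0))
    # 10-fold depletion of the active genotype by day 20 (odds scale)
    odds <- share / (1 - share)
    expect_equal(odds[3] / odds[1], 0.1, tolerance = 0.05)
  }
})
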