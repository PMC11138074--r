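# Control curation, assay readouts, OddsPath, evidence strength.

test_that("penetrance is cases over total carriers", {
  expect_equal(estimate_penetrance(2, 5, 45), 0.04)
  expect_equal(estimate_penetrance(0, 12, 100), 0)
  expect_error(estimate_penetrance(1, 0, 0), "positive")
})

test_that("control curation applies ClinVar-first rules", {
  controls <- data.frame(
    name = c("A1V", "B2C", "C3D", "D4E", "E5F"),
    clinvar = c("B/LB", "none", "none", "none", "P/LP"),
    n_cases = c(3, 1, 6, 0, 0),
    n_carriers_literature = c(4, 0, 10, 2, 0),
    gnomad_ac = c(500, 2, 10, 400, 1),
    gnomad_af = c(2e-3, 1e-6, 1e-4, 8e-5, 1e-6))
  got <- curate_controls(controls)
  lab <- setNames(got$presumed_label, got$name)
  # ClinVar classifications win regardless of frequency or case counts
  expect_equal(unname(lab["A1V"]), "benign")
  expect_equal(unname(lab["E5F"]), "pathogenic")
  # one literature case at AF 1e-6 is a presumed pathogenic control
  expect_equal(unname(lab["B2C"]), "pathogenic")
  # common and high penetrance (6/20 = 30%) is excluded
  expect_equal(unname(lab["C3D"]), "excluded")
  # common and low penetrance is presumed benign
  expect_equal(unname(lab["D4E"]), "benign")
  expect_equal(got$penetrance[got$name == "C3D"], 0.3)
  expect_error(curate_controls(transform(controls, gnomad_af = "oops")),
               "allele frequency")
})

test_that("assay readouts compare the whole CI to the calibration cutoffs", {
  expect_equal(assay_readout(0.2, 0.1, 0.3), "abnormal_low")
  expect_equal(assay_readout(1.0, 0.8, 1.2), "normal")
  expect_equal(assay_readout(0.5, 0.40, 0.60), "indeterminate")
  expect_equal(assay_readout(1.6, 1.5, 1.7), "abnormal_high")
  expect_equal(assay_readout(1.4, 1.2, 1.6), "indeterminate")
  expect_error(assay_readout(0.5, 0.6, 0.7), "malformed")
})

test_that("OddsPath reproduces the printed calibration worked examples", {
  # 7 benign controls all normal; 4 pathogenic: 3 abnormal, 1 normal
  labels <- c(rep("benign", 7), rep("pathogenic", 4))
  readouts <- c(rep("normal", 7), rep("abnormal_low", 3), "normal")
  rep1 <- oddspath(labels, readouts)
  expect_equal(rep1$P1, 4 / 11)
  expect_equal(rep1$oddspath_pathogenic, 5.25)
  expect_equal(rep1$oddspath_benign, 0.25)
  expect_equal(unname(rep1$strengths["PS3"]), "PS3_moderate")
  expect_equal(unname(rep1$strengths["BS3"]), "BS3_supporting")
  expect_equal(rep1$corrections_applied, "abnormal")

  # expanded control set: pathogenic 14 abnormal / 3 normal,
  # benign 1 abnormal / 16 normal
  labels2 <- c(rep("pathogenic", 17), rep("benign", 17))
  readouts2 <- c(rep("abnormal_low", 14), rep("normal", 3),
                 "abnormal_low", rep("normal", 16))
  rep2 <- oddspath(labels2, readouts2)
  expect_equal(rep2$oddspath_pathogenic, 14.0)
  expect_equal(rep2$oddspath_benign, 0.1875)
  expect_equal(unname(rep2$strengths["PS3"]), "PS3_moderate")
  expect_equal(unname(rep2$strengths["BS3"]), "BS3_moderate")
  expect_length(rep2$corrections_applied, 0)

  # an uninformative assay has odds 1
  labels3 <- c(rep("pathogenic", 4), rep("benign", 4))
  readouts3 <- rep(c("abnormal_low", "normal"), 4)
  expect_equal(oddspath(labels3, readouts3)$oddspath_pathogenic, 1.0)

  # indeterminate readouts are excluded from every denominator
  rep4 <- oddspath(c(labels, "benign"), c(readouts, "indeterminate"))
  expect_equal(rep4$P1, rep1$P1)
  expect_equal(rep4$oddspath_pathogenic, rep1$oddspath_pathogenic)

  expect_error(oddspath(rep("benign", 3), rep("normal", 3)), "each side")
})

test_that("OddsPath equals a brute-force posterior-odds computation", {
  # independent oracle: posterior odds of pathogenicity given the readout,
  # divided by prior odds, on the (possibly zero-corrected) counts
  oracle <- function(pa, ba, pn, bn) {
    p1 <- (pa + pn) / (pa + ba + pn + bn)
    prior_odds <- p1 / (1 - p1)
    ba_c <- if (ba == 0) 1 else ba
    pn_c <- if (pn == 0) 1 else pn
    c(path = (pa / ba_c) / prior_odds,
      benign = (pn_c / bn) / prior_odds)
  }
  set.seed(55)
  for (i in 1:40) {
    pa <- sample(0:20, 1)
    ba <- sample(0:20, 1)
    pn <- sample(0:20, 1)
    bn <- sample(1:20, 1)
    if (pa + pn == 0) next
    labels <- c(rep("pathogenic", pa + pn), rep("benign", ba + bn))
    readouts <- c(rep("abnormal_low", pa), rep("normal", pn),
                  rep("abnormal_high", ba), rep("normal", bn))
    got <- oddspath(labels, readouts)
    want <- oracle(pa, ba, pn, bn)
    expect_equal(got$oddspath_pathogenic, unname(want["path"]),
                 info = paste(pa, ba, pn, bn))
    expect_equal(got$oddspath_benign, unname(want["benign"]),
                 info = paste(pa, ba, pn, bn))
  }
})

test_that("adding a pathogenic-abnormal control never weakens PS3 odds", {
  base_labels <- c(rep("benign", 6), rep("pathogenic", 4))
  base_reads <- c(rep("normal", 5), "abnormal_low",
                  rep("abnormal_low", 3), "normal")
  prev <- oddspath(base_labels, base_reads)$oddspath_pathogenic
  for (extra in 1:5) {
    cur <- oddspath(c(base_labels, rep("pathogenic", extra)),
                    c(base_reads, rep("abnormal_low", extra)))$oddspath_pathogenic
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("evidence strength mapping covers the SVI scale", {
  grades <- function(p, b) {
    unname(evidence_strength(list(oddspath_pathogenic = p,
                                  oddspath_benign = b)))
  }
  expect_equal(grades(5.25, 0.25), c("PS3_moderate", "BS3_supporting"))
  expect_equal(grades(14.0, 0.188), c("PS3_moderate", "BS3_moderate"))
  expect_equal(grades(400, 0.001), c("PS3_very_strong", "BS3_very_strong"))
  expect_equal(grades(20, 0.04), c("PS3_strong", "BS3_strong"))
  expect_equal(grades(2.5, 0.4), c("PS3_supporting", "BS3_supporting"))
  expect_equal(grades(1.0, 1.0), c("none", "none"))
})

test_that("calibrate_assay joins controls to scores and reports", {
  scores <- data.frame(hgvs_pro = c("A1V", "B2C", "C3D"),
                       score = c(1.0, 0.2, 0.5),
                       ci_lower = c(0.9, 0.1, 0.4),
                       ci_upper = c(1.1, 0.3, 0.6))
  controls <- data.frame(name = c("A1V", "B2C"),
                         presumed_label = c("benign", "pathogenic"))
  got <- calibrate_assay(controls, scores)
  expect_equal(got$controls$readout, c("normal", "abnormal_low"))
  expect_s3_class(got$report, "oddspath_report")
})
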