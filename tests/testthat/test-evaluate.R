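# Downstream statistics: correlations, ROC, contrasts, intolerance, splice.

test_that("rank correlation matches the classical rank formula", {
  expect_equal(rank_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  set.seed(61)
  x <- runif(10)
  y <- runif(10)
  got <- rank_correlation(x, y)
  d <- rank(x) - rank(y)
  expect_equal(got$rho, 1 - 6 * sum(d^2) / (10 * (10^2 - 1)))
  expect_equal(got$n, 10)
  expect_true(got$p >= 0 && got$p <= 1)
  expect_error(rank_correlation(1:2, 2:1), "at least 3")
})

test_that("ROC separates classes and the AUC matches an external check", {
  # perfectly separated: pathogenic (low scores) vs benign
  labels <- c(rep(TRUE, 3), rep(FALSE, 3))
  scores <- c(0.1, 0.2, 0.3, 0.9, 1.0, 1.1)
  expect_equal(roc_curve(labels, scores)$auc, 1)

  # label-independent scores give a chance-level AUC
  set.seed(62)
  labs <- rep(c(TRUE, FALSE), each = 250)
  rand <- runif(500)
  expect_lt(abs(roc_curve(labs, rand)$auc - 0.5), 0.08)

  # AUC is invariant under strictly monotone transforms
  expect_equal(roc_curve(labs, rand)$auc, roc_curve(labs, rand^3)$auc)

  # cross-check against an independent implementation
  got <- roc_curve(labs, rand)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labs, rand, direction = ">",
                                        quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-9)
  expect_error(roc_curve(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("operating point equals direct confusion-matrix counts", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  scores <- c(0.1, 0.2, 0.5, 0.9, 1.0, 1.1)
  op <- operating_point(labels, scores, cutoff = 0.44)
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 1)
  expect_equal(c(op$tp, op$fn, op$tn, op$fp), c(2, 1, 3, 0))
})

test_that("group contrast agrees with exhaustive rank-sum enumeration", {
  x <- c(1.1, 2.3, 3.1, 4.7, 5.2)
  y <- c(6.4, 7.1, 8.8, 9.9, 10.5)
  got <- group_contrast(x, y)
  expect_equal(got$statistic, 0) # full separation, x below y
  # exact two-sided p by enumerating all C(10,5) group assignments
  pooled <- c(x, y)
  combos <- utils::combn(10, 5)
  w_obs <- sum(rank(pooled)[1:5]) - 5 * 6 / 2
  w_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - 5 * 6 / 2
  })
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu))
  expect_equal(got$p, p_exact)

  # identical groups are not significant
  same <- group_contrast(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))
  expect_gt(same$p, 0.9)
  expect_error(group_contrast(numeric(0), 1:3), "non-empty")
})

test_that("chi-square independence matches the analytic value", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  got <- crosstab_independence(tab)
  expect_equal(got$statistic, 20)
  expect_equal(got$df, 1)

  diag3 <- diag(c(6, 6, 6))
  # all off-diagonal expected counts are 2, diagonal 2: chi-square by hand
  exp_counts <- outer(rowSums(diag3), colSums(diag3)) / sum(diag3)
  want <- sum((diag3 - exp_counts)^2 / exp_counts)
  expect_equal(crosstab_independence(diag3)$statistic, want)

  # near-uniform fill carries no signal
  unif <- matrix(50, 2, 2)
  expect_equal(crosstab_independence(unif)$statistic, 0)
  expect_error(crosstab_independence(matrix(c(5, 5, 0, 0), 2, 2)),
               "degenerate")
})

test_that("residue intolerance uses strict fraction thresholds", {
  mk <- function(pos, cats) {
    data.frame(position = pos, vclass = "missense",
               category = factor(cats, levels = c("loss", "partial_loss",
                                                  "possible_loss", "normal",
                                                  "possible_gain", "gain"),
                                 ordered = TRUE))
  }
  tab <- rbind(
    mk(1, c(rep("loss", 10), rep("partial_loss", 5), rep("normal", 5))),
    mk(2, c(rep("loss", 14), rep("normal", 6))),
    mk(3, rep("normal", 19)))
  ri <- residue_intolerance(tab)
  expect_true(ri$intolerant[ri$position == 1])   # 15/20 = 75%
  expect_false(ri$intolerant[ri$position == 2])  # 14/20 = 70%, strict
  expect_true(ri$tolerant[ri$position == 3])
  expect_false(ri$tolerant[ri$position == 1])
  expect_equal(ri$frac_lof[ri$position == 1], 0.75)
  # flags are mutually exclusive everywhere
  expect_false(any(ri$intolerant & ri$tolerant))
  # a residue with no scored missense variants is unscorable
  tab2 <- rbind(tab, data.frame(position = 4, vclass = "synonymous",
                                category = factor("normal",
                                                  levels = levels(tab$category),
                                                  ordered = TRUE)))
  ri2 <- residue_intolerance(tab2)
  expect_true(ri2$unscorable[ri2$position == 4])
})

test_that("splice flags bracket the recommended and high-recall thresholds", {
  expect_equal(splice_flags(c(0.55, 0.30, 0.10)),
               c("recommended", "high_recall", "none"))
  expect_equal(splice_flags(0.2), "none") # strict inequality at 0.2
  expect_error(splice_flags(1.2), "\\[0, 1\\]")
})
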