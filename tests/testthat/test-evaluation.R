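test_that("Cohen's kappa matches hand computations", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # TP 40, FN 10, FP 10, TN 40: p_o 0.8, p_e 0.5, kappa 0.6
  a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(cohens_kappa(a, b), 0.6)
  # independent raters
  set.seed(70)
  expect_lt(abs(cohens_kappa(
    sample(0:1, 1e4, replace = TRUE),
    sample(0:1, 1e4, replace = TRUE)
  )), 0.05)
  # both raters constant and identical
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5)), 1)
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
  # cross-check against an independent implementation
  set.seed(71)
  a <- sample(letters[1:4], 500, replace = TRUE)
  b <- ifelse(runif(500) < 0.6, a, sample(letters[1:4], 500, replace = TRUE))
  expect_equal(
    cohens_kappa(a, b),
    unname(e1071::classAgreement(table(a, b))$kappa),
    tolerance = 1e-12
  )
})

test_that("agreement report reproduces Bland-Altman hand values", {
  ref <- c(10, 20, 30)
  pred <- ref - c(-2, 0, 2)
  rep_ <- agreement_report(ref, pred)
  expect_equal(rep_$bland_altman_bias, 0)
  expect_equal(unname(rep_$limits_of_agreement), c(-3.92, 3.92)) # 1.96 * sample SD 2
  expect_true(all(rep_$flags == "ok"))

  perfect <- agreement_report(ref, ref)
  expect_equal(perfect$spearman_rho, 1)
  expect_equal(perfect$bland_altman_bias, 0)
  expect_equal(unname(perfect$limits_of_agreement), c(0, 0))

  # a +31 difference flags considerable underestimation
  pred2 <- c(10, 20, 61, 40)
  ref2 <- c(10, 20, 30, 71)
  rep2 <- agreement_report(ref2, pred2)
  expect_equal(rep2$flags, c("ok", "ok", "considerably_over", "considerably_under"))

  expect_warning(agreement_report(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(agreement_report(1:2, 1:2), "at least 3")
})

test_that("per-severity errors and the heteroscedasticity test are reported", {
  set.seed(72)
  ref <- runif(60, 0, 50)
  pred <- pmax(0, ref + rnorm(60, 0, 2 + ref / 5)) # spread grows with AHI
  rep_ <- agreement_report(ref, pred)
  expect_true(all(c("severity", "mean_error", "n") %in% names(rep_$per_severity_error)))
  expect_lt(rep_$breusch_pagan_p, 0.05)
})

test_that("screening metrics and ROC behave across calibration regimes", {
  set.seed(73)
  ref <- runif(80, 0, 50)
  scr <- screening_report(ref, ref)
  expect_true(all(scr$per_threshold$roc_auc == 1))
  expect_true(all(scr$per_threshold$sensitivity == 1))
  expect_true(all(scr$per_threshold$specificity == 1))
  expect_equal(scr$severity_accuracy, 1)
  # the optimal cut achieves zero distance to (1, 1)
  for (t in c("5", "15", "30")) {
    cut <- scr$per_threshold$optimal_cut[scr$per_threshold$threshold == as.numeric(t)]
    pos <- ref >= as.numeric(t)
    expect_true(all((ref >= cut) == pos))
  }
  # rank-preserving shift: AUC stays 1 but canonical specificity collapses
  shifted <- screening_report(ref, ref + 100)
  expect_true(all(shifted$per_threshold$roc_auc == 1))
  expect_true(all(shifted$per_threshold$specificity == 0))
  # random predictor: AUC near one half
  big_ref <- runif(1000, 0, 50)
  rnd <- screening_report(big_ref, runif(1000, 0, 50))
  expect_true(all(abs(rnd$per_threshold$roc_auc - 0.5) < 0.05))
})

test_that("ROC AUC is invariant under monotone transforms and matches pROC", {
  set.seed(74)
  ref <- runif(120, 0, 60)
  pred <- pmax(0, ref + rnorm(120, 0, 10))
  a1 <- screening_report(ref, pred)$per_threshold$roc_auc
  a2 <- screening_report(ref, log1p(pred))$per_threshold$roc_auc
  expect_equal(a1, a2, tolerance = 1e-12)
  for (t in c(5, 15, 30)) {
    oracle <- suppressMessages(as.numeric(pROC::auc(ref >= t, pred)))
    expect_equal(a1[c(5, 15, 30) == t], oracle, tolerance = 1e-10)
  }
})

test_that("confusion matrices are internally consistent", {
  set.seed(75)
  ref <- runif(100, 0, 45)
  pred <- pmax(0, ref + rnorm(100, 0, 8))
  scr <- screening_report(ref, pred)
  expect_equal(sum(scr$confusion), 100)
  expect_equal(
    scr$severity_accuracy,
    sum(diag(scr$confusion)) / 100
  )
  expect_equal(unname(rowSums(scr$confusion_pct)), rep(100, 4), tolerance = 1e-10)
  # binary metrics recomputable from the reported counts
  t5 <- scr$per_threshold[scr$per_threshold$threshold == 5, ]
  pos <- ref >= 5
  det <- pred >= 5
  expect_equal(t5$sensitivity, sum(det & pos) / sum(pos))
  expect_equal(t5$specificity, sum(!det & !pos) / sum(!pos))
})

test_that("single-class thresholds degrade gracefully", {
  ref <- c(1, 2, 8, 20) # nobody reaches AHI 30
  expect_warning(scr <- screening_report(ref, ref), "single-class")
  expect_true(is.na(scr$per_threshold$kappa[scr$per_threshold$threshold == 30]))
  expect_false(is.na(scr$per_threshold$kappa[scr$per_threshold$threshold == 5]))
})

test_that("Fisher-z correlation comparison has the right nulls and symmetry", {
  expect_equal(compare_correlations(0.6, 50, 0.6, 80), 1)
  expect_lt(compare_correlations(0.9, 100, 0.0, 100), 0.001)
  expect_equal(
    compare_correlations(0.3, 40, 0.7, 60),
    compare_correlations(0.7, 60, 0.3, 40)
  )
  expect_warning(p <- compare_correlations(1, 50, 0.5, 50), "infinite|magnitude 1")
  expect_equal(p, 0)
  # closed-form z oracle
  z <- (atanh(0.9) - atanh(0)) / sqrt(1 / 97 + 1 / 97)
  expect_equal(compare_correlations(0.9, 100, 0, 100), 2 * pnorm(-abs(z)))
})

test_that("plot builders return ggplot objects", {
  set.seed(76)
  ref <- runif(40, 0, 50)
  pred <- pmax(0, ref + rnorm(40, 0, 6))
  expect_s3_class(autoplot(agreement_report(ref, pred)), "ggplot")
  expect_s3_class(autoplot(screening_report(ref, pred)), "ggplot")
})
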