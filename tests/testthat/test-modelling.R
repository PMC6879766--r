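test_that("SMOTE reaches parity and ENN leaves separated classes alone", {
  set.seed(60)
  x <- rbind(
    matrix(rnorm(900 * 2, 0, 0.5), ncol = 2),
    matrix(rnorm(100 * 2, 8, 0.5), ncol = 2) # far-away minority
  )
  lab <- rep(c(FALSE, TRUE), c(900, 100))
  bal <- balance_epochs(x, lab, k = 5)
  # parity up to the (near-zero) ENN cleaning on well-separated classes
  expect_gt(sum(bal$labels), 0.97 * 900)
  expect_gt(sum(!bal$labels), 0.97 * 900)
  expect_lte(abs(sum(bal$labels) - sum(!bal$labels)), 0.03 * 900)
  # synthetic points interpolate the minority cloud
  expect_true(all(bal$x[bal$labels, 1] > 5))
})

test_that("balanced input gets no synthetic samples, small minorities error", {
  set.seed(61)
  x <- matrix(rnorm(80), ncol = 2)
  lab <- rep(c(TRUE, FALSE), each = 20)
  bal <- balance_epochs(x, lab)
  expect_lte(nrow(bal$x), 40) # only ENN removal possible
  expect_error(
    balance_epochs(matrix(rnorm(40), ncol = 2), rep(c(TRUE, FALSE), c(3, 17)), k = 5),
    "at least 6"
  )
})

test_that("balancing is bit-reproducible under a fixed seed", {
  x <- matrix(rnorm(600), ncol = 3)
  lab <- rep(c(TRUE, FALSE), c(40, 160))
  set.seed(7)
  a <- balance_epochs(x, lab)
  set.seed(7)
  b <- balance_epochs(x, lab)
  expect_identical(a, b)
})

test_that("model selection grades candidates by inner-CV PR-AUC", {
  set.seed(62)
  # quadratic boundary: minority inside a ring, linear models fail
  n_rec <- 8
  x <- NULL
  lab <- logical(0)
  rid <- character(0)
  for (r in 1:n_rec) {
    xr <- matrix(rnorm(400), ncol = 2)
    d <- sqrt(rowSums(xr^2))
    lr <- d < 0.8
    x <- rbind(x, xr)
    lab <- c(lab, lr)
    rid <- c(rid, rep(paste0("r", r), 200))
  }
  winner <- suppressWarnings(select_model(x, lab, rid, seed = 3))
  expect_equal(as.character(winner), "qda")
  # pure-noise labels: every candidate's PR-AUC is near the prevalence
  set.seed(63)
  lab_noise <- runif(length(lab)) < 0.3
  w2 <- suppressWarnings(select_model(x, lab_noise, rid, seed = 3))
  expect_true(all(abs(attr(w2, "scores") - 0.3) < 0.08, na.rm = TRUE))
})

test_that("PR-AUC of a random scorer approaches the prevalence", {
  set.seed(64)
  lab <- runif(5000) < 0.2
  expect_equal(pr_auc(runif(5000), lab), 0.2, tolerance = 0.04)
  expect_equal(pr_auc(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)
})

test_that("Theil-Sen slope matches enumeration and resists outliers", {
  expect_equal(theil_sen_slope(c(0.1, 0.2, 0.3), c(5, 10, 15)), 50)
  # with the outlier (0.2, 100): slopes {50, 50, 950, 50, -850}, median 50
  expect_equal(theil_sen_slope(c(0.1, 0.2, 0.3, 0.2), c(5, 10, 15, 100)), 50)
  # an off-centre outlier drags least squares away but not Theil-Sen
  expect_equal(theil_sen_slope(c(0.1, 0.2, 0.3, 0.3), c(5, 10, 15, 100)), 50)
  ls <- unname(coef(lm(y ~ x, data.frame(
    x = c(0.1, 0.2, 0.3, 0.3),
    y = c(5, 10, 15, 100)
  )))[2])
  expect_gt(abs(ls - 50), 10)
  # brute-force double-loop oracle on random data
  set.seed(65)
  for (i in 1:5) {
    n <- sample(5:60, 1)
    x <- round(runif(n), 2)
    y <- 3 * x + rnorm(n)
    slopes <- c()
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        if (x[b] != x[a]) slopes <- c(slopes, (y[b] - y[a]) / (x[b] - x[a]))
      }
    }
    expect_equal(theil_sen_slope(x, y), median(slopes))
  }
  expect_error(theil_sen_slope(c(1, 1), c(0, 5)), "equal")
})

test_that("estimate_beta pairs sleep-only epoch fractions with the AHI", {
  labels <- list(
    rep(c(TRUE, FALSE), c(10, 90)),
    rep(c(TRUE, FALSE), c(20, 80)),
    rep(c(TRUE, FALSE), c(30, 70))
  )
  masks <- list(rep(TRUE, 100), rep(TRUE, 100), rep(TRUE, 100))
  expect_equal(estimate_beta(c(5, 10, 15), labels, masks), 50)
  # wake epochs are excluded from the fraction
  masks2 <- list(
    rep(c(TRUE, FALSE), c(50, 50)),
    rep(TRUE, 100), rep(TRUE, 100)
  )
  # first recording: 10 RE among 50 sleep -> 0.2
  expect_equal(
    estimate_beta(c(10, 10, 15), labels, masks2),
    theil_sen_slope(c(0.2, 0.2, 0.3), c(10, 10, 15))
  )
})

test_that("probability threshold selection follows the highest-tie rule", {
  # perfect 0/1 probabilities: kappa plateaus at 1, highest grid point wins
  probs <- list(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(10, 90)), rep(0, 100))
  refs <- c(50 * 0.3, 50 * 0.1, 0) # beta 50 reproduces them exactly
  expect_equal(select_probability_threshold(probs, refs, beta = 50), 0.99)
  # uninformative probabilities: constant kappa, returns 0.99
  flat <- list(rep(0.5, 50), rep(0.5, 50), rep(0.5, 50))
  expect_equal(select_probability_threshold(flat, c(2, 10, 40), beta = 50), 0.99)
  # constructed window: only thresholds in (0.6, 0.7] are fully correct
  p1 <- c(rep(0.9, 24), rep(0.6, 30), rep(0.05, 66)) # ref mild (10)
  p2 <- c(rep(0.7, 48), rep(0.05, 72)) # ref moderate (20)
  p3 <- rep(0.3, 120) # ref normal (2)
  got <- select_probability_threshold(
    list(p1, p2, p3), c(10, 20, 2),
    beta = 50
  )
  expect_equal(got, 0.70)
  # brute-force grid oracle agrees
  grid <- seq_len(99) / 100
  kap <- vapply(grid, function(t) {
    pred <- 50 * vapply(list(p1, p2, p3), function(p) mean(p >= t), 1)
    cohens_kappa(ahi_severity(pred), ahi_severity(c(10, 20, 2)))
  }, 1)
  expect_equal(got, grid[max(which(kap == max(kap)))])
})

test_that("estimate_ahi applies beta, threshold and severity bounds", {
  est <- list(probability_threshold = 0.5, beta = 50)
  out <- estimate_ahi(
    c(rep(0.9, 20), rep(0.1, 80)), est, rep(TRUE, 100), "r1"
  )
  expect_equal(out$ahi_pred, 10)
  expect_equal(out$severity, "mild")
  out0 <- estimate_ahi(rep(0.1, 50), est, rep(TRUE, 50))
  expect_equal(out0$ahi_pred, 0)
  expect_equal(out0$severity, "normal")
  est2 <- list(probability_threshold = 0.5, beta = 60)
  out2 <- estimate_ahi(
    rep(c(0.9, 0.1), c(60, 60)), est2, rep(TRUE, 120)
  )
  expect_equal(out2$ahi_pred, 30)
  expect_equal(out2$severity, "severe") # inclusive lower edge
  expect_error(
    estimate_ahi(c(0.5, 0.5), est, c(FALSE, FALSE)),
    "undefined"
  )
  # monotonicity in the threshold
  p <- runif(200)
  a1 <- estimate_ahi(p, list(probability_threshold = 0.3, beta = 50), rep(TRUE, 200))
  a2 <- estimate_ahi(p, list(probability_threshold = 0.7, beta = 50), rep(TRUE, 200))
  expect_gte(a1$ahi_pred, a2$ahi_pred)
})

test_that("classifier training is deterministic and monotone in its feature", {
  set.seed(66)
  x <- matrix(rnorm(400), ncol = 2)
  y <- x[, 1] + 0.2 * rnorm(200) > 0
  f1 <- fit_candidate(x, y, "logistic_elastic_net")
  f2 <- fit_candidate(x, y, "logistic_elastic_net")
  expect_identical(coef(f1), coef(f2))
  p <- predict_candidate(f1, x, "logistic_elastic_net")
  ord <- order(x[, 1])
  # probabilities rise with the separating feature
  expect_gt(cor(x[, 1], p, method = "spearman"), 0.95)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("duplicating a feature column leaves predictions almost unchanged", {
  set.seed(67)
  x <- matrix(rnorm(600), ncol = 3)
  y <- x[, 1] - x[, 2] + 0.3 * rnorm(200) > 0
  f1 <- fit_candidate(x, y, "logistic_elastic_net")
  p1 <- predict_candidate(f1, x, "logistic_elastic_net")
  xd <- cbind(x, x[, 1])
  f2 <- fit_candidate(xd, y, "logistic_elastic_net")
  p2 <- predict_candidate(f2, xd, "logistic_elastic_net")
  expect_equal(p1, p2, tolerance = 1e-2)
})
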