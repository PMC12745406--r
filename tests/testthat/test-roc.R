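test_that("AUC equals the brute-force pair count, including the toy example", {
  d <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- c(3, 4, 2, 1, 2, 3)
  r <- empirical_roc(s, d)
  expect_equal(r$auc, 7 / 9)              # (favorable + ties/2) / 9
  expect_equal(r$auc, brute_auc(s, d))
  set.seed(14)
  for (i in 1:40) {
    n <- sample(8:60, 1)
    d <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(0:6, n, replace = TRUE)
    expect_equal(empirical_roc(s, d)$auc, brute_auc(s, d))
  }
})

test_that("degenerate scores give the expected extremes", {
  d <- rep(c(TRUE, FALSE), each = 10)
  perfect <- rep(c(5, 1), each = 10)
  r <- empirical_roc(perfect, d)
  expect_equal(r$auc, 1)
  expect_equal(delong_variance(perfect, d), 0)
  expect_equal(empirical_roc(rep(2, 20), d)$auc, 0.5)
  expect_error(empirical_roc(1:5, rep(TRUE, 5)), "both")
})

test_that("the ROC staircase is monotone with trivial endpoints", {
  set.seed(15)
  s <- sample(0:10, 80, replace = TRUE)
  d <- runif(80) < plogis(s - 5)
  d[1:2] <- c(TRUE, FALSE)
  r <- empirical_roc(s, d)
  expect_true(all(diff(r$sens_at) <= 1e-12))
  expect_true(all(diff(r$spec_at) >= -1e-12))
  expect_equal(c(r$sens_at[1], r$spec_at[1]), c(1, 0))
  n <- length(r$cutoffs)
  expect_equal(c(r$sens_at[n], r$spec_at[n]), c(0, 1))
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(16)
  s <- sample(0:6, 100, replace = TRUE)
  d <- runif(100) < plogis(s - 3)
  d[1:2] <- c(TRUE, FALSE)
  a0 <- empirical_roc(s, d)$auc
  expect_equal(empirical_roc(s^3, d)$auc, a0)
  expect_equal(empirical_roc(exp(s / 2), d)$auc, a0)
})

test_that("DeLong variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    n <- 80
    d <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    a <- sample(0:6, n, replace = TRUE) + d * sample(0:2, n, replace = TRUE)
    b <- sample(0:10, n, replace = TRUE) + d * sample(0:2, n, replace = TRUE)
    ra <- suppressMessages(pROC::roc(d, a, direction = "<"))
    expect_equal(empirical_roc(a, d)$auc, as.numeric(pROC::auc(ra)))
    expect_equal(delong_variance(a, d), as.numeric(pROC::var(ra)),
                 tolerance = 1e-10)
    cmp <- delong_paired_test(a, b, d)
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(d, a, direction = "<"), pROC::roc(d, b, direction = "<"),
      method = "delong", paired = TRUE))
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(abs(cmp$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  }
})

test_that("paired test is antisymmetric and null on identical scores", {
  set.seed(18)
  d <- c(TRUE, FALSE, runif(58) < 0.5)
  a <- sample(0:6, 60, replace = TRUE) + d
  b <- sample(0:10, 60, replace = TRUE)
  ab <- delong_paired_test(a, b, d)
  ba <- delong_paired_test(b, a, d)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$delta, ab$auc_a - ab$auc_b)
  same <- delong_paired_test(a, a, d)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
})

test_that("placement covariance vanishes for independent scores", {
  set.seed(19)
  covs <- replicate(200, {
    d <- rep(c(TRUE, FALSE), each = 50)
    a <- sample(0:6, 100, replace = TRUE)
    b <- sample(0:10, 100, replace = TRUE)
    delong_paired_test(a, b, d)$covariance
  })
  expect_lt(abs(mean(covs)), 3 * sd(covs) / sqrt(length(covs)))
})

test_that("Youden cutoff maximizes J with ties broken toward sensitivity", {
  d <- rep(c(TRUE, FALSE), each = 10)
  r <- empirical_roc(rep(c(5, 1), each = 10), d)
  y <- youden_cutoff(r)
  expect_equal(y$j, 1)
  expect_equal(y$cutoff, 2)            # lowest separating cutoff
  expect_equal(youden_cutoff(empirical_roc(rep(3, 20), d))$j, 0)
  # exact tie between two cutoffs: the lower one wins
  s <- c(4, 4, 2, 2, 3, 1, 1, 3)
  d <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- empirical_roc(s, d)
  j <- r$sens_at + r$spec_at - 1
  ties <- r$cutoffs[j >= max(j) - 1e-12]
  expect_gt(length(ties), 1)
  expect_equal(youden_cutoff(r)$cutoff, min(ties))
})

test_that("threshold_table hits the trivial rows and composes with classify", {
  set.seed(20)
  s <- sample(2:5, 60, replace = TRUE)
  d <- c(TRUE, FALSE, runif(58) < 0.5)
  tt <- threshold_table(s, d, c(0, 4, 9))
  expect_equal(c(tt$sens[1], tt$spec[1]), c(1, 0))   # cutoff below range
  expect_equal(c(tt$sens[3], tt$spec[3]), c(0, 1))   # cutoff above range
  direct <- compute_metrics(two_by_two(classify(s, 4), d))
  expect_equal(tt[2, names(direct)], as.data.frame(direct),
               ignore_attr = TRUE)
})
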