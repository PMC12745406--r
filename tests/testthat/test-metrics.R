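test_that("two_by_two cross-counts, drops missing pairs, and checks lengths", {
  t <- two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 0L, tn = 1L))
  t <- two_by_two(rep(TRUE, 8), rep(TRUE, 8))
  expect_equal(t$tp, 8L)
  expect_equal(t$fp + t$fn + t$tn, 0L)
  t <- two_by_two(c(TRUE, NA, FALSE, TRUE), c(TRUE, TRUE, NA, FALSE))
  expect_equal(t$n_used, 2L)
  expect_equal(t$n_missing, 2L)
  expect_error(two_by_two(c(TRUE, FALSE), TRUE))
})

test_that("heel-drop metrics reproduce the published row", {
  t <- as_two_by_two(tp = 66, fp = 35, fn = 18, tn = 23)
  m <- compute_metrics(t)
  expect_equal(m$sens, 66 / 84)
  expect_equal(m$spec, 23 / 58)
  expect_equal(round(c(m$sens, m$spec), 2), c(0.79, 0.40))
  expect_equal(round(c(m$sens_lo, m$sens_hi), 2), c(0.68, 0.87))
  expect_equal(round(c(m$spec_lo, m$spec_hi), 2), c(0.27, 0.53))
  expect_equal(round(m$or, 3), 2.410)
})

test_that("nausea/vomiting metrics reproduce the published row", {
  m <- compute_metrics(as_two_by_two(tp = 47, fp = 8, fn = 37, tn = 50))
  expect_equal(round(m$plr, 2), 4.06)
  expect_equal(round(m$npv, 2), 0.57)
  expect_equal(round(c(m$plr_lo, m$plr_hi), 2), c(2.07, 7.93))
  o <- odds_ratio(as_two_by_two(tp = 47, fp = 8, fn = 37, tn = 50))
  expect_equal(round(o$estimate, 3), 7.939)
  expect_equal(round(o$lower, 3), 3.354)
  expect_equal(round(o$upper, 3), 18.794)
})

test_that("a perfect test has sens 1, spec 1, NLR 0 and undefined PLR", {
  m <- compute_metrics(as_two_by_two(tp = 12, fp = 0, fn = 0, tn = 12))
  expect_equal(c(m$sens, m$spec, m$ppv, m$npv), c(1, 1, 1, 1))
  expect_equal(m$nlr, 0)
  expect_true(is.na(m$plr))          # zero denominator: undefined, not faked
})

test_that("metric identities hold on random tables", {
  set.seed(5)
  for (i in 1:50) {
    cts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, .05, 1))
    t <- as_two_by_two(cts[1], cts[2], cts[3], cts[4])
    if (t$tp + t$fn == 0 || t$fp + t$tn == 0) next
    m <- compute_metrics(t)
    if (!is.na(m$plr)) expect_equal(m$plr, m$sens / (1 - m$spec))
    if (!is.na(m$nlr)) expect_equal(m$nlr, (1 - m$sens) / m$spec)
    # each point estimate sits inside its interval
    for (q in c("sens", "spec", "ppv", "npv", "plr", "nlr")) {
      lo <- m[[paste0(q, "_lo")]]; hi <- m[[paste0(q, "_hi")]]
      if (!anyNA(c(m[[q]], lo, hi))) {
        expect_true(lo <= m[[q]] && m[[q]] <= hi, label = q)
      }
    }
    # PLR > 1 <=> sens + spec > 1 <=> NLR < 1
    if (!anyNA(c(m$plr, m$nlr)) && abs(m$sens + m$spec - 1) > 1e-9) {
      expect_equal(m$plr > 1, m$sens + m$spec > 1)
      expect_equal(m$plr > 1, m$nlr < 1)
    }
  }
})

test_that("odds ratio is symmetric, reciprocal under relabeling, corrected at zero", {
  t <- as_two_by_two(tp = 12, fp = 5, fn = 7, tn = 21)
  o <- odds_ratio(t)
  swapped <- as_two_by_two(tp = 12, fp = 7, fn = 5, tn = 21)  # transpose axes
  expect_equal(odds_ratio(swapped)$estimate, o$estimate)
  # relabeling one axis (test positive <-> negative) inverts the OR;
  # relabeling both axes restores it
  one_axis <- as_two_by_two(tp = 7, fp = 21, fn = 12, tn = 5)
  expect_equal(odds_ratio(one_axis)$estimate, 1 / o$estimate)
  both_axes <- as_two_by_two(tp = 21, fp = 7, fn = 5, tn = 12)
  expect_equal(odds_ratio(both_axes)$estimate, o$estimate)
  sym <- as_two_by_two(tp = 9, fp = 9, fn = 4, tn = 4)
  expect_equal(odds_ratio(sym)$estimate, 1)
  zc <- odds_ratio(as_two_by_two(tp = 10, fp = 0, fn = 3, tn = 12))
  expect_true(zc$corrected)
  expect_true(is.finite(zc$estimate) && is.finite(zc$upper))
})

test_that("proportion_ci is the exact interval, pinned at 0 and 1", {
  expect_equal(unname(proportion_ci(0, 10)[1, "lower"]), 0)
  expect_equal(unname(proportion_ci(10, 10)[1, "upper"]), 1)
  set.seed(8)
  for (i in 1:25) {   # binom.test as independent oracle
    n <- sample(5:120, 1); k <- sample(0:n, 1)
    ours <- proportion_ci(k, n)
    ref <- binom.test(k, n)$conf.int
    expect_equal(unname(ours[1, ]), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("univariate male-sex comparison is significant as published", {
  co <- generate_cohort(cohort_spec(), seed = 2)
  # replace generated sex with the exact published counts: 52/84 vs 24/58
  sex <- rep("female", 142)
  disease <- co$outcome != "none"
  sex[which(disease)[1:52]] <- "male"
  sex[which(!disease)[1:24]] <- "male"
  co$sex <- sex
  u <- univariate_compare(co, "male_sex")
  expect_equal(u$type, "binary")
  expect_equal(u$summary$positive, c(52, 24))
  expect_lt(u$p_value, 0.05)
  expect_equal(round(u$odds_ratio$estimate, 3), 2.302)
})

test_that("Fisher branch p-value matches a Monte-Carlo permutation oracle", {
  # small table forces the expected-cell-5 switch to Fisher's exact test
  v <- c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 8))
  d <- c(rep(TRUE, 10), rep(FALSE, 10))
  t22 <- two_by_two(v, d)
  m <- compute_metrics(t22)
  expect_equal(m$test, "fisher")
  # permuting labels at fixed margins makes tp hypergeometric; the two-sided
  # exact p sums the probabilities of tables at most as probable as observed
  set.seed(9)
  k_obs <- t22$tp
  k_perm <- rhyper(100000, m = 10, n = 10, k = sum(v))
  p_perm <- mean(dhyper(k_perm, 10, 10, sum(v)) <=
                   dhyper(k_obs, 10, 10, sum(v)) + 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 100000)
  expect_lt(abs(p_perm - m$p_value), 4 * se)
})

test_that("chi-square branch approximates the permutation null at moderate n", {
  set.seed(10)
  v <- rep(c(TRUE, FALSE), times = c(90, 110))
  d <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(55, 35, 45, 65))
  t22 <- two_by_two(v, d)
  m <- compute_metrics(t22)
  expect_equal(m$test, "chisq")
  k_perm <- rhyper(100000, m = 100, n = 100, k = 90)
  chi <- function(k) {    # Pearson statistic as a function of the tp cell
    e <- outer(c(90, 110), c(100, 100)) / 200
    o <- rbind(c(k, 90 - k), c(100 - k, 10 + k))
    sum((o - e)^2 / e)
  }
  stat_obs <- chi(t22$tp)
  p_perm <- mean(vapply(k_perm, chi, numeric(1)) >= stat_obs - 1e-12)
  expect_lt(abs(p_perm - m$p_value), 0.02)
})

test_that("continuous variables get Welch summaries; constants are degenerate", {
  df <- manual_cohort_df()
  extra <- df[c(2, 2), ]                 # second non-diseased patient
  extra$patient_id <- c("B1", "B2")
  extra$wbc_per_ul <- c(7200, 9100)
  co <- cohort(rbind(df, extra))
  u <- univariate_compare(co, "wbc_per_ul")
  expect_equal(u$type, "continuous")
  expect_equal(u$test, "welch")
  expect_equal(u$summary$mean[1], mean(c(14200, 10000)))
  expect_equal(u$summary$mean[2], mean(c(8300, 7200, 9100)))
  co$diarrhea <- FALSE
  expect_equal(univariate_compare(co, "diarrhea")$test, "degenerate")
  expect_true(is.na(univariate_compare(co, "diarrhea")$p_value))
  expect_error(univariate_compare(co, "no_such_column"), "unknown variable")
})
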