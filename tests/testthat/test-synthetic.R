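test_that("generation is reproducible from the seed and seeds differ", {
  spec <- cohort_spec()
  a <- generate_cohort(spec, seed = 5)
  b <- generate_cohort(spec, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(spec, seed = 6)
  expect_false(identical(a$wbc_per_ul, c$wbc_per_ul))
  expect_equal(sum(a$outcome != "none"), 84)
  expect_equal(sum(a$outcome == "complicated"), 32)
  expect_equal(nrow(a), 142)
})

test_that("generated labs are consistent with the drawn binary flags", {
  co <- generate_cohort(cohort_spec(), seed = 12)
  f <- derive_features(co)
  # in match_flag_prevalence mode the labs are drawn conditional on the
  # flags, so thresholding the labs must recover the flags exactly
  expect_true(all(f$crp_elevated_5 <= f$crp_elevated_1))
  expect_true(all(co$neutrophil_pct >= 0 & co$neutrophil_pct <= 100))
  expect_true(all(co$wbc_per_ul >= 0 & co$crp_mg_dl >= 0))
  # derived mode: flags follow from the labs by construction as well
  co2 <- generate_cohort(cohort_spec(match_flag_prevalence = FALSE), seed = 12)
  expect_s3_class(co2, "chanse_cohort")
})

test_that("group-conditional prevalences are recovered at large n", {
  spec <- cohort_spec(n_disease = 10000, n_no_disease = 2000,
                      n_complicated = 3810)
  co <- generate_cohort(spec, seed = 13)
  dis <- co$outcome != "none"
  f <- derive_features(co)
  # each empirical prevalence within 3.5 Monte-Carlo SEs of its target
  near <- function(emp, p, n) expect_lt(abs(emp - p),
                                        3.5 * sqrt(p * (1 - p) / n))
  near(mean(co$heel_drop[dis]), 66 / 84, 10000)
  near(mean(f$leukocytosis[dis]), 61 / 84, 10000)
  near(mean(f$crp_elevated_1[!dis]), 22 / 58, 2000)
  near(mean(co$sex[dis] == "male"), 52 / 84, 10000)
})

test_that("the copula couples features: high rho gives high phi", {
  bp <- data.frame(
    variable = c("male_sex", "anorexia", "nausea_or_vomiting", "diarrhea",
                 "migration", "rlq_tenderness", "cough_percussion_hopping",
                 "psoas", "rovsing", "obturator", "heel_drop", "fever",
                 "leukocytosis", "left_shift", "crp_elevated_1",
                 "crp_elevated_5"),
    p_disease = 0.5, p_no_disease = 0.5)
  bp$p_disease[bp$variable == "crp_elevated_5"] <- 0.2
  bp$p_no_disease[bp$variable == "crp_elevated_5"] <- 0.2
  spec <- cohort_spec(n_disease = 4000, n_no_disease = 100,
                      n_complicated = 0, binary_prevalence = bp,
                      correlation = 0.99)
  co <- generate_cohort(spec, seed = 14)
  dis <- co$outcome != "none"
  phi <- cor(co$anorexia[dis], co$heel_drop[dis])
  expect_gt(phi, 0.8)
  # and rho = 0 leaves them uncorrelated
  spec0 <- cohort_spec(n_disease = 4000, n_no_disease = 100,
                       n_complicated = 0, binary_prevalence = bp,
                       correlation = 0)
  co0 <- generate_cohort(spec0, seed = 14)
  expect_lt(abs(cor(co0$anorexia[co0$outcome != "none"],
                    co0$heel_drop[co0$outcome != "none"])), 0.05)
})

test_that("invalid specifications are rejected with clear errors", {
  expect_error(cohort_spec(n_complicated = 100), "n_complicated")
  expect_error(cohort_spec(correlation = 1.2), "correlation")
  expect_error(cohort_spec(correlation = matrix(1, 2, 2)), "matrix")
  bad <- matrix(0.9, 15, 15); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.9
  expect_error(cohort_spec(correlation = bad), "positive semi-definite")
  bp <- cohort_spec()$binary_prevalence
  bp$p_disease[1] <- 1.4
  expect_error(cohort_spec(binary_prevalence = bp), "\\[0, 1\\]")
})

test_that("a full correlation matrix is accepted and generates", {
  rho <- diag(15)
  rho[rho == 0] <- 0.3
  co <- generate_cohort(cohort_spec(correlation = rho), seed = 15)
  expect_equal(nrow(co), 142)
})

test_that("severity calibration hits targets and is monotone", {
  spec <- cohort_spec()
  base_mean <- expected_chanse_mean(spec, "uncomplicated")  # unshifted
  ident <- calibrate_severity_shift(spec, c(base_mean, base_mean))
  expect_equal(unname(ident$severity_shift), c(0, 0))
  cal <- calibrate_severity_shift(spec, c(3.0, 4.6))
  expect_equal(expected_chanse_mean(cal, "uncomplicated"), 3.0,
               tolerance = 1e-6)
  expect_equal(expected_chanse_mean(cal, "complicated"), 4.6,
               tolerance = 1e-6)
  # larger target gap -> larger shift difference
  gaps <- c(0.5, 1.0, 2.0)
  diffs <- vapply(gaps, function(g) {
    s <- calibrate_severity_shift(spec, c(3.5 - g / 2, 3.5 + g / 2))
    s$severity_shift[["complicated"]] - s$severity_shift[["uncomplicated"]]
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
  expect_error(calibrate_severity_shift(spec, c(3, 6.5)), "unreachable")
})
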