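# 2x2 diagnostic-accuracy statistics: tables, metrics with CIs, odds ratios,
# exact proportion intervals, and univariate group comparisons.

#' Cross-classify a binary test against disease status
#'
#' Builds the 2x2 table of test result versus disease. Pairs with a missing
#' value in either vector are dropped (complete-case per variable) and
#' counted in `n_missing`.
#'
#' @param test_positive logical vector of test results.
#' @param diseased logical vector of true disease status, same length.
#' @return Object of class `two_by_two`: list with counts `tp`, `fp`, `fn`,
#'   `tn`, plus `n_used` and `n_missing`.
#' @export
two_by_two <- function(test_positive, diseased) {
  test_positive <- as.logical(test_positive)
  diseased <- as.logical(diseased)
  stopifnot(length(test_positive) == length(diseased),
            length(diseased) >= 1L)
  keep <- !is.na(test_positive) & !is.na(diseased)
  t <- test_positive[keep]; d <- diseased[keep]
  as_two_by_two(tp = sum(t & d), fp = sum(t & !d),
                fn = sum(!t & d), tn = sum(!t & !d),
                n_missing = sum(!keep))
}

#' Build a 2x2 table directly from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (true/false positives,
#'   false/true negatives).
#' @param n_missing number of records excluded for missingness, if known.
#' @return Object of class `two_by_two`.
#' @export
as_two_by_two <- function(tp, fp, fn, tn, n_missing = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_used = as.integer(tp + fp + fn + tn),
                 n_missing = as.integer(n_missing)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              disease = c("yes", "no")))
  cat(sprintf("<two_by_two> n = %d (%d excluded missing)\n",
              x$n_used, x$n_missing))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (beta-quantile) interval for a proportion; guarantees coverage at
#' least the nominal level. `k = 0` pins the lower bound at 0 and `k = n`
#' the upper bound at 1.
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param level confidence level, default 0.95.
#' @return Matrix with columns `lower` and `upper`, one row per input.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(all(k >= 0), all(k <= n), all(n > 0), level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  cbind(lower = lower, upper = upper)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (tp*tn)/(fp*fn); CI on the log scale with standard error
#' sqrt(1/tp + 1/fp + 1/fn + 1/tn). When any cell is zero, the Haldane
#' 0.5 continuity correction is added to all four cells and the result is
#' flagged `corrected`.
#'
#' @param x a [two_by_two()] table.
#' @param level confidence level.
#' @return List with `estimate`, `lower`, `upper`, `corrected`, `level`.
#' @export
odds_ratio <- function(x, level = 0.95) {
  stopifnot(inherits(x, "two_by_two"))
  cells <- c(x$tp, x$fp, x$fn, x$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = or,
       lower = exp(log(or) - z * se),
       upper = exp(log(or) + z * se),
       corrected = corrected, level = level)
}

# Association p-value for a 2x2 table: Pearson chi-square without continuity
# correction, switching to Fisher's exact test when any expected cell < 5.
.assoc_test <- function(x) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = NA_real_, test = "degenerate"))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(p_value = stats::fisher.test(m)$p.value, test = "fisher")
  } else {
    list(p_value = suppressWarnings(
      stats::chisq.test(m, correct = FALSE)$p.value), test = "chisq")
  }
}

#' Full diagnostic-accuracy metrics for a 2x2 table
#'
#' Computes sensitivity, specificity, PPV, NPV, the positive and negative
#' likelihood ratios, the odds ratio, and an association p-value, each with
#' a 95% (by default) confidence interval:
#' \itemize{
#'   \item sensitivity/specificity: Clopper-Pearson exact intervals;
#'   \item PLR/NLR: log-method intervals (Simel et al.);
#'   \item PPV/NPV: point estimates `tp/(tp+fp)` and `tn/(tn+fn)`; intervals
#'     obtained by propagating the likelihood-ratio interval through Bayes'
#'     theorem at the observed prevalence (the convention used by standard
#'     diagnostic-test calculators, which the reference tables follow);
#'     when the LR interval is undefined, Clopper-Pearson is used instead;
#'   \item odds ratio: Woolf interval ([odds_ratio()]);
#'   \item p-value: Pearson chi-square, or Fisher's exact test when any
#'     expected cell is below 5.
#' }
#' Metrics with a zero denominator are returned as `NA` (undefined), never
#' fabricated.
#'
#' @param x a [two_by_two()] table; requires diseased and non-diseased both
#'   represented (`tp + fn > 0` and `fp + tn > 0`).
#' @param level confidence level.
#' @return A one-row data frame of class `diag_metrics` with the counts and,
#'   for each metric `m`, columns `m`, `m_lo`, `m_hi`; plus `or`, `or_lo`,
#'   `or_hi`, `or_corrected`, `p_value`, `test`, `n_used`.
#' @export
compute_metrics <- function(x, level = 0.95) {
  stopifnot(inherits(x, "two_by_two"))
  tp <- x$tp; fp <- x$fp; fn <- x$fn; tn <- x$tn
  n_dis <- tp + fn; n_non <- fp + tn
  if (n_dis == 0 || n_non == 0) {
    stop("compute_metrics needs both diseased and non-diseased records")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  sens <- tp / n_dis
  spec <- tn / n_non
  sens_ci <- proportion_ci(tp, n_dis, level)
  spec_ci <- proportion_ci(tn, n_non, level)

  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_

  # likelihood ratios with Simel log-method intervals
  plr <- if (spec < 1) sens / (1 - spec) else NA_real_
  nlr <- if (spec > 0) (1 - sens) / spec else NA_real_
  plr_ci <- c(NA_real_, NA_real_)
  if (!is.na(plr) && plr > 0 && tp > 0 && fp > 0) {
    se <- sqrt(1 / tp - 1 / n_dis + 1 / fp - 1 / n_non)
    plr_ci <- exp(log(plr) + c(-1, 1) * z * se)
  }
  nlr_ci <- c(NA_real_, NA_real_)
  if (!is.na(nlr) && nlr > 0 && fn > 0 && tn > 0) {
    se <- sqrt(1 / fn - 1 / n_dis + 1 / tn - 1 / n_non)
    nlr_ci <- exp(log(nlr) + c(-1, 1) * z * se)
  }

  # predictive-value intervals via Bayes at observed prevalence
  prev <- n_dis / (n_dis + n_non)
  podds <- prev / (1 - prev)
  ppv_ci <- if (all(is.finite(plr_ci))) {
    podds * plr_ci / (podds * plr_ci + 1)
  } else if (!is.na(ppv)) proportion_ci(tp, tp + fp, level)[1, ] else c(NA, NA)
  npv_ci <- if (all(is.finite(nlr_ci))) {
    rev(1 / (1 + podds * nlr_ci))
  } else if (!is.na(npv)) proportion_ci(tn, tn + fn, level)[1, ] else c(NA, NA)

  or <- odds_ratio(x, level)
  assoc <- .assoc_test(x)
  out <- data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn, n_used = x$n_used,
    sens = sens, sens_lo = sens_ci[1, 1], sens_hi = sens_ci[1, 2],
    spec = spec, spec_lo = spec_ci[1, 1], spec_hi = spec_ci[1, 2],
    ppv = ppv, ppv_lo = unname(ppv_ci[1]), ppv_hi = unname(ppv_ci[2]),
    npv = npv, npv_lo = unname(npv_ci[1]), npv_hi = unname(npv_ci[2]),
    plr = plr, plr_lo = unname(plr_ci[1]), plr_hi = unname(plr_ci[2]),
    nlr = nlr, nlr_lo = unname(nlr_ci[1]), nlr_hi = unname(nlr_ci[2]),
    or = or$estimate, or_lo = or$lower, or_hi = or$upper,
    or_corrected = or$corrected,
    p_value = assoc$p_value, test = assoc$test,
    stringsAsFactors = FALSE
  )
  class(out) <- c("diag_metrics", "data.frame")
  out
}

#' Univariate comparison of one variable between disease groups
#'
#' Reproduces a demographics-table row: binary variables are cross-tabulated
#' against disease and tested with Pearson's chi-square (without continuity
#' correction), switching to Fisher's exact test when any expected cell is
#' below 5, and summarized as n (%) per group with a Woolf odds ratio;
#' continuous variables are tested with Welch's t-test and summarized as
#' mean +/- SD. Complete-case per variable; a constant variable is flagged
#' degenerate with `NA` p-value.
#'
#' @param x a [cohort()].
#' @param variable name of a raw cohort column or a derived feature
#'   (see [derive_features()]); `"male_sex"` compares sex.
#' @param thresholds output of [feature_thresholds()], used when `variable`
#'   is a derived feature.
#' @return List of class `univariate_result`: `variable`, `type`
#'   (binary/continuous), per-group `summary` data frame, `p_value`, `test`,
#'   and for binary variables the [odds_ratio()] list.
#' @export
univariate_compare <- function(x, variable,
                               thresholds = feature_thresholds()) {
  validate_cohort(x)
  disease <- x$outcome != "none"
  v <- if (variable == "male_sex") {
    x$sex == "male"
  } else if (variable %in% names(x)) {
    x[[variable]]
  } else {
    f <- derive_features(x, thresholds)
    if (!variable %in% names(f)) stop("unknown variable: ", variable)
    f[[variable]]
  }
  keep <- !is.na(v) & !is.na(disease)
  v <- v[keep]; d <- disease[keep]
  res <- list(variable = variable,
              n_used = c(disease = sum(d), no_disease = sum(!d)))

  if (is.logical(v)) {
    res$type <- "binary"
    res$summary <- data.frame(
      group = c("disease", "no_disease"),
      n = c(sum(d), sum(!d)),
      positive = c(sum(v[d]), sum(v[!d])),
      pct = 100 * c(mean(v[d]), mean(v[!d]))
    )
    if (length(unique(v)) < 2L || length(unique(d)) < 2L) {
      res$test <- "degenerate"; res$p_value <- NA_real_
    } else {
      t22 <- two_by_two(v, d)
      assoc <- .assoc_test(t22)
      res$test <- assoc$test
      res$p_value <- assoc$p_value
      res$odds_ratio <- odds_ratio(t22)
    }
  } else {
    res$type <- "continuous"
    res$summary <- data.frame(
      group = c("disease", "no_disease"),
      n = c(sum(d), sum(!d)),
      mean = c(mean(v[d]), mean(v[!d])),
      sd = c(stats::sd(v[d]), stats::sd(v[!d]))
    )
    if (stats::sd(v) == 0 || sum(d) < 2L || sum(!d) < 2L) {
      res$test <- "degenerate"; res$p_value <- NA_real_
    } else {
      tt <- stats::t.test(v[d], v[!d])  # Welch by default
      res$test <- "welch"
      res$p_value <- tt$p.value
      res$statistic <- unname(tt$statistic)
    }
  }
  class(res) <- "univariate_result"
  res
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("<univariate_result> %s (%s, %s test): p = %s\n",
              x$variable, x$type, x$test,
              format.pval(x$p_value, digits = 3)))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  OR %.3f (%.3f-%.3f)%s\n", x$odds_ratio$estimate,
                x$odds_ratio$lower, x$odds_ratio$upper,
                if (x$odds_ratio$corrected) " [continuity-corrected]" else ""))
  }
  invisible(x)
}
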