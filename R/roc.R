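# Empirical ROC analysis for integer-valued scores: AUC (Mann-Whitney, ties
# at 1/2), DeLong placement-value variance and paired correlated-ROC Z-test,
# Youden cutoff selection, and threshold operating tables.

.roc_clean <- function(scores, diseased) {
  diseased <- as.logical(diseased)
  stopifnot(length(scores) == length(diseased))
  keep <- !is.na(scores) & !is.na(diseased)
  scores <- scores[keep]; diseased <- diseased[keep]
  if (!any(diseased) || all(diseased)) {
    stop("ROC analysis needs both diseased and non-diseased records")
  }
  list(s = scores, d = diseased)
}

# DeLong structural components (placement values), computed with midranks.
# v10[i] = P-hat(score_pos_i > score_neg + 1/2 ties); mean(v10) = AUC.
.placements <- function(s, d) {
  n1 <- sum(d); n0 <- sum(!d)
  r_all <- rank(s)
  v10 <- (r_all[d] - rank(s[d])) / n0
  v01 <- 1 - (r_all[!d] - rank(s[!d])) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' Empirical ROC curve and AUC for an integer-valued score
#'
#' One operating point per threshold "score >= c", with c spanning the
#' observed score range plus a sentinel above the maximum, so the curve
#' includes the trivial (sens 1, spec 0) and (sens 0, spec 1) points. The
#' AUC is the Mann-Whitney statistic with tied score pairs credited 1/2,
#' identical to the trapezoidal area under the empirical staircase. The AUC
#' confidence interval is normal-approximation, using the DeLong variance.
#'
#' @param scores numeric (typically integer) score vector.
#' @param diseased logical disease-status vector, same length.
#' @param level confidence level for the AUC interval.
#' @return Object of class `roc_result`: `cutoffs`, `sens_at`, `spec_at`,
#'   `auc`, `auc_var`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, diseased, level = 0.95) {
  cl <- .roc_clean(scores, diseased)
  s <- cl$s; d <- cl$d
  cutoffs <- if (all(s == round(s))) {
    seq(min(s), max(s) + 1)
  } else {
    c(sort(unique(s)), max(s) + 1)
  }
  sens_at <- vapply(cutoffs, function(cc) mean(s[d] >= cc), numeric(1))
  spec_at <- vapply(cutoffs, function(cc) mean(s[!d] < cc), numeric(1))
  pl <- .placements(s, d)
  v <- .delong_var(pl)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(v)))
  structure(list(cutoffs = cutoffs, sens_at = sens_at, spec_at = spec_at,
                 auc = pl$auc, auc_var = v, auc_ci = ci,
                 n_pos = pl$n1, n_neg = pl$n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%.3f-%.3f), %d positive / %d negative\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

.delong_var <- function(pl) {
  s10 <- if (pl$n1 > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n0 > 1) stats::var(pl$v01) else 0
  s10 / pl$n1 + s01 / pl$n0
}

#' DeLong variance of the empirical AUC
#'
#' Nonparametric variance from the placement-value (structural-component)
#' decomposition: var = S10/n1 + S01/n0, where S10 and S01 are the sample
#' variances of the positive and negative placement values. Zero for a
#' perfectly separating score.
#'
#' @inheritParams empirical_roc
#' @return Non-negative scalar variance.
#' @export
delong_variance <- function(scores, diseased) {
  cl <- .roc_clean(scores, diseased)
  .delong_var(.placements(cl$s, cl$d))
}

#' Paired DeLong test for two correlated ROC AUCs
#'
#' Compares the AUCs of two scores measured on the same patients with the
#' nonparametric Z-test for correlated ROC curves: the variance of the AUC
#' difference subtracts twice the covariance of the shared placement values,
#' z = (auc_a - auc_b) / se(difference), two-sided normal p-value.
#'
#' @param scores_a,scores_b score vectors on the same patients.
#' @param diseased logical disease-status vector.
#' @return Object of class `auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `covariance`, `var_delta`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, diseased) {
  stopifnot(length(scores_a) == length(scores_b))
  diseased <- as.logical(diseased)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(diseased)
  a <- scores_a[keep]; b <- scores_b[keep]; d <- diseased[keep]
  if (!any(d) || all(d)) {
    stop("ROC analysis needs both diseased and non-diseased records")
  }
  pa <- .placements(a, d); pb <- .placements(b, d)
  var_a <- .delong_var(pa); var_b <- .delong_var(pb)
  cov_ab <- (if (pa$n1 > 1) stats::cov(pa$v10, pb$v10) else 0) / pa$n1 +
            (if (pa$n0 > 1) stats::cov(pa$v01, pb$v01) else 0) / pa$n0
  delta <- pa$auc - pb$auc
  var_delta <- max(0, var_a + var_b - 2 * cov_ab)
  if (var_delta < .Machine$double.eps) {
    if (abs(delta) < sqrt(.Machine$double.eps)) {
      z <- 0; p <- 1
    } else {
      stop("degenerate comparison: zero variance of the AUC difference ",
           "with unequal AUCs")
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 covariance = cov_ab, var_delta = var_delta,
                 z = z, p_value = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "<auc_comparison> AUC %.3f vs %.3f (delta %+.3f), z = %.2f, p = %s\n",
    x$auc_a, x$auc_b, x$delta, x$z, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Selects the cutoff maximizing J = sensitivity + specificity - 1 on an
#' empirical ROC curve. Ties are broken toward the lowest cutoff (the more
#' sensitive operating point, the usual screening preference).
#'
#' @param roc a [empirical_roc()] result.
#' @return List with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sens_at + roc$spec_at - 1
  idx <- which(j >= max(j) - 1e-12)[1]  # cutoffs ascending: first = lowest
  list(cutoff = roc$cutoffs[idx], j = j[idx],
       sensitivity = roc$sens_at[idx], specificity = roc$spec_at[idx])
}

#' Operating characteristics of a score at several cutoffs
#'
#' Dichotomizes the score at each cutoff ("score >= c") and computes the
#' full [compute_metrics()] row, reproducing a score-threshold table.
#'
#' @inheritParams empirical_roc
#' @param cutoffs integer vector of cutoffs.
#' @param level confidence level.
#' @return Data frame with a `cutoff` column followed by the
#'   `diag_metrics` columns, one row per cutoff.
#' @export
threshold_table <- function(scores, diseased, cutoffs, level = 0.95) {
  rows <- lapply(cutoffs, function(cc) {
    m <- compute_metrics(two_by_two(classify(scores, cc), diseased), level)
    cbind(cutoff = cc, as.data.frame(m))
  })
  do.call(rbind, rows)
}
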