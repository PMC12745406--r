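# End-to-end analysis pipeline (cohort -> features -> scores -> univariate,
# per-parameter and per-cutoff tables -> paired ROC comparison -> severity
# summary) and the reproduction ledger against the published tables.

.table1_variables <- list(
  continuous = c("age_years", "body_temp_c", "pain_duration_h",
                 "wbc_per_ul", "neutrophil_pct", "crp_mg_dl"),
  binary = c("male_sex", "fever", "anorexia", "nausea_or_vomiting",
             "diarrhea", "migration", "leukocytosis", "left_shift",
             "crp_elevated_5", "rlq_tenderness", "cough_percussion_hopping",
             "psoas", "rovsing", "obturator", "heel_drop")
)
.table3_parameters <- c("migration", "anorexia", "nausea_or_vomiting",
                        "rlq_tenderness", "cough_percussion_hopping",
                        "fever", "leukocytosis", "left_shift",
                        "crp_elevated_1", "heel_drop")

#' Default analysis configuration
#'
#' @param thresholds lab/vital cutpoints, see [feature_thresholds()].
#' @param chanse_cutoffs,pas_cutoffs cutoffs for the score-threshold table
#'   (defaults 2:4 and 6:8, the published operating points).
#' @param level confidence level for every interval.
#' @return Named list of settings.
#' @export
analysis_config <- function(thresholds = feature_thresholds(),
                            chanse_cutoffs = 2:4, pas_cutoffs = 6:8,
                            level = 0.95) {
  list(thresholds = thresholds, chanse_cutoffs = chanse_cutoffs,
       pas_cutoffs = pas_cutoffs, level = level)
}

.univariate_row <- function(u) {
  s <- u$summary
  fmt <- if (u$type == "binary") {
    sprintf("%d (%.1f)", s$positive, s$pct)
  } else {
    sprintf("%.1f +/- %.1f", s$mean, s$sd)
  }
  data.frame(
    variable = u$variable, type = u$type,
    disease = fmt[1], no_disease = fmt[2],
    n_disease = s$n[1], n_no_disease = s$n[2],
    p_value = u$p_value, test = u$test,
    or = if (!is.null(u$odds_ratio)) u$odds_ratio$estimate else NA_real_,
    or_lo = if (!is.null(u$odds_ratio)) u$odds_ratio$lower else NA_real_,
    or_hi = if (!is.null(u$odds_ratio)) u$odds_ratio$upper else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run the complete diagnostic-accuracy analysis
#'
#' Validates and scores the cohort, then computes: the univariate
#' demographics comparison (binary and continuous variables, with odds
#' ratios), the per-parameter diagnostic metrics table, the score-threshold
#' operating table for both scores, the paired ROC comparison (AUCs with
#' DeLong variance, correlated-ROC Z-test, Youden cutoffs, curve
#' coordinates), and the score-by-severity summary. Every number in the
#' report is regenerable from the cohort and configuration alone.
#'
#' @param x a [cohort()] or a path to a cohort CSV.
#' @param config output of [analysis_config()].
#' @return Object of class `chanse_report`: list with elements `table1`,
#'   `table3`, `table4`, `roc`, `severity`, `metadata`.
#' @export
run_analysis <- function(x, config = analysis_config()) {
  if (is.character(x)) x <- read_cohort(x)
  validate_cohort(x)
  feats <- derive_features(x, config$thresholds)
  scored <- score_cohort(x, config$thresholds)
  disease <- scored$disease

  table1 <- do.call(rbind, lapply(
    c(.table1_variables$binary, .table1_variables$continuous),
    function(v) .univariate_row(
      univariate_compare(x, v, config$thresholds))))

  table3 <- do.call(rbind, lapply(.table3_parameters, function(v) {
    m <- compute_metrics(two_by_two(feats[[v]], disease), config$level)
    cbind(parameter = v, as.data.frame(m))
  }))

  table4 <- rbind(
    cbind(score = "chanse",
          threshold_table(scored$chanse, disease, config$chanse_cutoffs,
                          config$level)),
    cbind(score = "pas",
          threshold_table(scored$pas, disease, config$pas_cutoffs,
                          config$level))
  )

  ok <- !is.na(scored$chanse) & !is.na(scored$pas)
  roc_chanse <- empirical_roc(scored$chanse[ok], disease[ok], config$level)
  roc_pas <- empirical_roc(scored$pas[ok], disease[ok], config$level)
  comparison <- delong_paired_test(scored$chanse[ok], scored$pas[ok],
                                   disease[ok])
  roc <- list(chanse = roc_chanse, pas = roc_pas,
              comparison = comparison,
              youden_chanse = youden_cutoff(roc_chanse),
              youden_pas = youden_cutoff(roc_pas))

  severity <- do.call(rbind, lapply(
    c("none", "uncomplicated", "complicated"), function(g) {
      v <- scored$chanse[scored$outcome == g]
      v <- v[!is.na(v)]
      data.frame(outcome = g, n = length(v),
                 chanse_mean = if (length(v)) mean(v) else NA_real_,
                 chanse_sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))

  structure(list(
    table1 = table1, table3 = table3, table4 = table4,
    roc = roc, severity = severity,
    metadata = list(
      package_version = as.character(utils::packageVersion("chanse")),
      n = nrow(x), n_disease = sum(disease),
      n_score_complete = sum(ok),
      provenance = attr(x, "provenance"),
      config = config,
      methods = c(
        proportion_ci = "Clopper-Pearson exact",
        lr_ci = "Simel log method",
        ppv_npv_ci = "likelihood-ratio interval through Bayes at observed prevalence",
        or_ci = "Woolf log method (Haldane 0.5 correction on zero cells)",
        binary_test = "Pearson chi-square; Fisher exact if any expected cell < 5",
        continuous_test = "Welch t-test",
        auc = "Mann-Whitney with ties at 1/2",
        auc_comparison = "DeLong correlated-ROC Z-test, two-sided"
      ))),
    class = "chanse_report")
}

#' @export
print.chanse_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<chanse_report> %d patients (%d appendicitis), %s\n",
              md$n, md$n_disease, md$provenance))
  cat(sprintf("  AUC: CHANSE %.3f (%.3f-%.3f) vs PAS %.3f (%.3f-%.3f)\n",
              x$roc$chanse$auc, x$roc$chanse$auc_ci[1], x$roc$chanse$auc_ci[2],
              x$roc$pas$auc, x$roc$pas$auc_ci[1], x$roc$pas$auc_ci[2]))
  cat(sprintf("  DeLong z = %.2f, p = %s; Youden cutoffs: CHANSE >= %d, PAS >= %d\n",
              x$roc$comparison$z,
              format.pval(x$roc$comparison$p_value, digits = 3),
              x$roc$youden_chanse$cutoff, x$roc$youden_pas$cutoff))
  cat("  CHANSE by severity:\n")
  print(x$severity, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes the report as machine-readable JSON (unrounded) plus
#' tab-separated tables rendered at publication precision (2 decimals for
#' proportions and likelihood ratios, 3 for odds ratios).
#'
#' @param report a [run_analysis()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "chanse_report"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_report requires the 'jsonlite' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(
    table1 = report$table1, table3 = report$table3, table4 = report$table4,
    roc = list(
      chanse = report$roc$chanse[c("cutoffs", "sens_at", "spec_at",
                                   "auc", "auc_var", "auc_ci")],
      pas = report$roc$pas[c("cutoffs", "sens_at", "spec_at",
                             "auc", "auc_var", "auc_ci")],
      comparison = unclass(report$roc$comparison),
      youden_chanse = report$roc$youden_chanse,
      youden_pas = report$roc$youden_pas),
    severity = report$severity,
    metadata = report$metadata)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  r2 <- function(x) round(x, 2)
  t3 <- report$table3
  for (cc in grep("^(sens|spec|ppv|npv|plr|nlr)", names(t3))) t3[[cc]] <- r2(t3[[cc]])
  for (cc in grep("^or", names(t3), value = TRUE)) {
    if (is.numeric(t3[[cc]])) t3[[cc]] <- round(t3[[cc]], 3)
  }
  utils::write.table(report$table1, file.path(dir, "table1.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(t3, file.path(dir, "table3.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$table4, file.path(dir, "table4.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$severity, file.path(dir, "severity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

# Printed cells that are internally inconsistent with their own row and are
# therefore skipped (with reason) rather than compared.
.printed_cell_exclusions <- data.frame(
  table = "table1", variable = "cough_percussion_hopping", quantity = "or_lo",
  reason = paste("printed lower bound 1.056 is inconsistent with the row's",
                 "printed OR 2.071 and upper bound 4.484, both of which match",
                 "the Woolf computation exactly (computed lower 0.956)"),
  stringsAsFactors = FALSE
)

.ledger_row <- function(table, variable, quantity, printed, computed, tol,
                        status = NULL, reason = "") {
  if (is.null(status)) {
    status <- if (is.na(printed) || is.na(computed)) "skipped"
              else if (abs(computed - printed) <= tol + 1e-9) "match"
              else "mismatch"
  }
  excl <- .printed_cell_exclusions
  hit <- which(excl$table == table & excl$variable == variable &
                 excl$quantity == quantity)
  if (length(hit) == 1L) {
    status <- "skipped"
    reason <- excl$reason[hit]
  }
  data.frame(table = table, variable = variable, quantity = quantity,
             printed = printed, computed = computed, tolerance = tol,
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Recompute the published tables from their printed counts
#'
#' For every count-derivable published quantity - each binary variable's
#' odds ratio and Woolf CI bounds, and each diagnostic parameter's
#' sensitivity, specificity, PPV, NPV, PLR, NLR and their CIs - recomputes
#' the value from the published group-conditional counts ([printed_counts()])
#' and compares it to the printed value at the printed precision (+-1 unit
#' in the last printed digit for point estimates; +-0.015 for 2-decimal CI
#' bounds; +-0.02 for likelihood-ratio CI bounds, whose computation method
#' the source does not state). Known internal inconsistencies of the source
#' (the fever row; the cough/percussion/hopping LR cells) are reported as
#' `skipped` with their reason, never silently passed.
#'
#' @return Data frame of class `reproduction_ledger`, one row per compared
#'   cell: `table`, `variable`, `quantity`, `printed`, `computed`,
#'   `tolerance`, `status` (match/mismatch/skipped), `reason`.
#' @export
reproduce_printed_tables <- function() {
  counts <- printed_counts()
  rows <- list()

  for (i in seq_len(nrow(counts))) {
    v <- counts$variable[i]
    if (is.na(counts$printed_or[i])) next
    t22 <- as_two_by_two(
      tp = counts$pos_disease[i],
      fn = counts$n_disease[i] - counts$pos_disease[i],
      fp = counts$pos_no_disease[i],
      tn = counts$n_no_disease[i] - counts$pos_no_disease[i])
    or <- odds_ratio(t22)
    rows[[length(rows) + 1L]] <- rbind(
      .ledger_row("table1", v, "or", counts$printed_or[i], or$estimate, 0.001),
      .ledger_row("table1", v, "or_lo", counts$printed_or_lo[i], or$lower, 0.01),
      .ledger_row("table1", v, "or_hi", counts$printed_or_hi[i], or$upper, 0.01))
  }

  printed <- printed_metrics()
  prop_q <- c("sens", "spec", "ppv", "npv")
  lr_q <- c("plr", "nlr")
  for (i in seq_len(nrow(printed))) {
    v <- printed$variable[i]
    ci <- counts[match(v, counts$variable), ]
    if (identical(printed$exclude[i], "all")) {
      rows[[length(rows) + 1L]] <- .ledger_row(
        "table3", v, "all", NA_real_, NA_real_, NA_real_,
        status = "skipped", reason = printed$exclude_reason[i])
      next
    }
    m <- compute_metrics(as_two_by_two(
      tp = ci$pos_disease, fn = ci$n_disease - ci$pos_disease,
      fp = ci$pos_no_disease, tn = ci$n_no_disease - ci$pos_no_disease))
    skip_lr <- identical(printed$exclude[i], "lr")
    for (q in prop_q) {
      rows[[length(rows) + 1L]] <- rbind(
        .ledger_row("table3", v, q, printed[[q]][i], m[[q]], 0.01),
        .ledger_row("table3", v, paste0(q, "_lo"),
                    printed[[paste0(q, "_lo")]][i], m[[paste0(q, "_lo")]], 0.015),
        .ledger_row("table3", v, paste0(q, "_hi"),
                    printed[[paste0(q, "_hi")]][i], m[[paste0(q, "_hi")]], 0.015))
    }
    for (q in lr_q) {
      if (skip_lr) {
        rows[[length(rows) + 1L]] <- .ledger_row(
          "table3", v, q, printed[[q]][i], m[[q]], NA_real_,
          status = "skipped", reason = printed$exclude_reason[i])
        next
      }
      rows[[length(rows) + 1L]] <- rbind(
        .ledger_row("table3", v, q, printed[[q]][i], m[[q]], 0.01),
        .ledger_row("table3", v, paste0(q, "_lo"),
                    printed[[paste0(q, "_lo")]][i], m[[paste0(q, "_lo")]], 0.02),
        .ledger_row("table3", v, paste0(q, "_hi"),
                    printed[[paste0(q, "_hi")]][i], m[[paste0(q, "_hi")]], 0.02))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reproduction_ledger", "data.frame")
  out
}

#' @export
print.reproduction_ledger <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("<reproduction_ledger> %d cells: %d match, %d mismatch, %d skipped\n",
              nrow(x), sum(x$status == "match"), sum(x$status == "mismatch"),
              sum(x$status == "skipped")))
  bad <- x[x$status == "mismatch", ]
  if (nrow(bad) > 0L) {
    cat("mismatches:\n")
    print(as.data.frame(bad), row.names = FALSE)
  }
  sk <- unique(x[x$status == "skipped", c("variable", "reason")])
  if (nrow(sk) > 0L) {
    cat("skipped (source inconsistencies):\n")
    for (i in seq_len(nrow(sk)))
      cat(sprintf("  %s: %s\n", sk$variable[i], sk$reason[i]))
  }
  invisible(x)
}
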