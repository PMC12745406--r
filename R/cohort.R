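# Patient-level cohort data model: schema, CSV I/O, validation, feature derivation.

.cohort_char_cols <- c("patient_id", "sex", "outcome")
.cohort_num_cols  <- c("age_years", "body_temp_c", "pain_duration_h",
                       "wbc_per_ul", "neutrophil_pct", "crp_mg_dl")
.cohort_bool_cols <- c("anorexia", "nausea_or_vomiting", "diarrhea", "migration",
                       "rlq_tenderness", "cough_percussion_hopping",
                       "psoas", "obturator", "rovsing", "heel_drop")
.cohort_columns <- c("patient_id", "age_years", "sex", "body_temp_c",
                     "pain_duration_h", "anorexia", "nausea_or_vomiting",
                     "diarrhea", "migration", "wbc_per_ul", "neutrophil_pct",
                     "crp_mg_dl", "rlq_tenderness", "cough_percussion_hopping",
                     "psoas", "obturator", "rovsing", "heel_drop", "outcome")
.outcome_levels <- c("none", "uncomplicated", "complicated")

#' Construct a validated cohort
#'
#' A cohort is a data frame with one row per patient and a fixed clinical
#' schema: identifiers, demographics, symptoms, physical-exam findings
#' (including the heel drop test), laboratory values and a three-class
#' outcome (`none`, `uncomplicated`, `complicated` appendicitis). A patient
#' is "disease positive" when `outcome != "none"`.
#'
#' @param data data frame holding the cohort columns (see Details).
#' @param provenance free-text description of where the rows came from
#'   (a file path, or a generator seed).
#'
#' @details Required columns: `patient_id` (unique), `age_years`, `sex`
#'   (`male`/`female`), `body_temp_c`, `pain_duration_h`, ten logical
#'   symptom/sign columns (`anorexia`, `nausea_or_vomiting`, `diarrhea`,
#'   `migration`, `rlq_tenderness`, `cough_percussion_hopping`, `psoas`,
#'   `obturator`, `rovsing`, `heel_drop`), labs `wbc_per_ul` (cells/uL),
#'   `neutrophil_pct` (0-100), `crp_mg_dl`, and `outcome`. Missing values
#'   are allowed anywhere except `patient_id` and `outcome`; analyses are
#'   complete-case per variable and report the n actually used.
#'
#' @return An object of class `chanse_cohort` (a data frame).
#' @seealso [read_cohort()], [write_cohort()], [derive_features()]
#' @export
cohort <- function(data, provenance = "in-memory") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(data), .cohort_columns)
  if (length(extra) > 0L) {
    stop("schema error: unknown column(s): ", paste(extra, collapse = ", "))
  }
  data <- data[, .cohort_columns]
  for (cc in .cohort_char_cols) data[[cc]] <- as.character(data[[cc]])
  for (nc in .cohort_num_cols)  data[[nc]] <- as.numeric(data[[nc]])
  for (bc in .cohort_bool_cols) data[[bc]] <- as.logical(data[[bc]])
  validate_cohort(data)
  structure(data, provenance = provenance,
            class = c("chanse_cohort", "data.frame"))
}

#' Validate cohort invariants
#'
#' Checks uniqueness of `patient_id`, legal `sex` and `outcome` levels, and
#' physiological ranges (`neutrophil_pct` in \[0,100\], non-negative WBC, CRP,
#' age and pain duration). All violations are collected and reported together,
#' each naming the offending row.
#'
#' @param data a cohort or plain data frame with cohort columns.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(data) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0L)
      sprintf("row %s: %s", paste(rows, collapse = ","), msg)
    else character(0)
  }
  if (nrow(data) == 0L) problems <- c(problems, "cohort is empty")
  id <- data$patient_id
  bad_id <- which(is.na(id) | id == "")
  problems <- c(problems, note(bad_id, "missing patient_id"))
  dup <- which(duplicated(id) & !is.na(id))
  if (length(dup) > 0L) {
    problems <- c(problems, sprintf("duplicate patient_id: %s",
                                    paste(unique(id[dup]), collapse = ", ")))
  }
  bad_sex <- which(!is.na(data$sex) & !data$sex %in% c("male", "female"))
  problems <- c(problems, note(bad_sex, "sex must be 'male' or 'female'"))
  bad_out <- which(is.na(data$outcome) | !data$outcome %in% .outcome_levels)
  problems <- c(problems, note(bad_out,
    "outcome must be one of none/uncomplicated/complicated"))
  rng <- list(
    neutrophil_pct  = c(0, 100),
    wbc_per_ul      = c(0, Inf),
    crp_mg_dl       = c(0, Inf),
    age_years       = c(0, Inf),
    pain_duration_h = c(0, Inf)
  )
  for (v in names(rng)) {
    x <- data[[v]]
    bad <- which(!is.na(x) & (x < rng[[v]][1] | x > rng[[v]][2]))
    problems <- c(problems, note(bad, sprintf(
      "%s out of range [%s, %s]", v, rng[[v]][1], rng[[v]][2])))
  }
  if (length(problems) > 0L) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(data)
}

#' @export
print.chanse_cohort <- function(x, ...) {
  dis <- sum(x$outcome != "none", na.rm = TRUE)
  cat(sprintf("<chanse_cohort> %d patients (%d appendicitis / %d without)\n",
              nrow(x), dis, nrow(x) - dis))
  cat("  provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

.parse_bool_cell <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "t", "y")]  <- TRUE
  out[x %in% c("0", "false", "no", "f", "n")]  <- FALSE
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  list(value = out, bad = which(bad))
}

#' Read a cohort from CSV
#'
#' Reads a patient-level cohort table (UTF-8, RFC-4180, header row required).
#' Column names are matched case-insensitively against the cohort schema.
#' Boolean cells accept `0/1`, `true/false`, `yes/no` in any case; empty cells
#' are missing values. Every parsed row is validated; errors name the row and
#' column.
#'
#' @param path path to a CSV file.
#' @param schema_version schema identifier; only `"1"` is defined.
#' @return A [cohort()] with `provenance` set to `path`.
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown schema_version: ", schema_version)
  }
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  names(raw) <- tolower(trimws(names(raw)))
  unknown <- setdiff(names(raw), .cohort_columns)
  if (length(unknown) > 0L) {
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- raw[, .cohort_columns]
  for (nc in .cohort_num_cols) {
    v <- suppressWarnings(as.numeric(out[[nc]]))
    bad <- which(!is.na(out[[nc]]) & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("schema error: unparseable numeric in column '%s', row %s",
                   nc, paste(bad, collapse = ",")))
    }
    out[[nc]] <- v
  }
  for (bc in .cohort_bool_cols) {
    p <- .parse_bool_cell(out[[bc]])
    if (length(p$bad) > 0L) {
      stop(sprintf("schema error: unparseable boolean in column '%s', row %s",
                   bc, paste(p$bad, collapse = ",")))
    }
    out[[bc]] <- p$value
  }
  out$sex <- tolower(out$sex)
  out$outcome <- tolower(out$outcome)
  cohort(out, provenance = path)
}

#' Write a cohort to CSV
#'
#' Canonical dialect: fixed column order, booleans as `0`/`1`, missing cells
#' empty, reals written with full precision so that a write/read round trip
#' reproduces every field exactly.
#'
#' @param x a [cohort()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  out <- as.data.frame(x)[, .cohort_columns]
  for (bc in .cohort_bool_cols) out[[bc]] <- as.integer(out[[bc]])
  for (nc in .cohort_num_cols) {
    v <- out[[nc]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    out[[nc]] <- s
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort file: ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Laboratory and vital-sign thresholds for feature derivation
#'
#' Inclusive cutpoints that dichotomize continuous measurements into the
#' binary indicators used by the scores: leukocytosis (WBC >= 10,000/uL),
#' left shift / neutrophilia (PMN >= 75%), CRP elevation at >= 1 mg/dL (the
#' CHANSE component) and >= 5 mg/dL, and fever (>= 38.0 C).
#'
#' @param wbc_per_ul leukocytosis cutoff, cells/uL.
#' @param neutrophil_pct left-shift cutoff, percent.
#' @param crp_low_mg_dl lower CRP cutoff, mg/dL.
#' @param crp_high_mg_dl upper CRP cutoff, mg/dL.
#' @param body_temp_c fever cutoff, degrees Celsius.
#' @return A named list of thresholds.
#' @export
feature_thresholds <- function(wbc_per_ul = 10000, neutrophil_pct = 75,
                               crp_low_mg_dl = 1, crp_high_mg_dl = 5,
                               body_temp_c = 38.0) {
  stopifnot(crp_low_mg_dl <= crp_high_mg_dl)
  list(wbc_per_ul = wbc_per_ul, neutrophil_pct = neutrophil_pct,
       crp_low_mg_dl = crp_low_mg_dl, crp_high_mg_dl = crp_high_mg_dl,
       body_temp_c = body_temp_c)
}

#' Derive binary features from raw clinical values
#'
#' Turns each patient's labs and vitals into the binary indicators feeding
#' the scores, using inclusive (`>=`) thresholds, and passes symptom/sign
#' booleans through unchanged. Missing inputs propagate to `NA` flags; the
#' affected patient is excluded only from computations that need that flag.
#'
#' @param x a [cohort()], or any data frame carrying the relevant columns
#'   (a single-row data frame works for one patient).
#' @param thresholds output of [feature_thresholds()].
#' @return Data frame of logical columns: `leukocytosis`, `left_shift`,
#'   `crp_elevated_1`, `crp_elevated_5`, `fever`, plus the ten pass-through
#'   symptom/sign indicators (and `patient_id` when present in `x`).
#' @export
derive_features <- function(x, thresholds = feature_thresholds()) {
  x <- as.data.frame(x)
  f <- data.frame(
    leukocytosis   = x$wbc_per_ul >= thresholds$wbc_per_ul,
    left_shift     = x$neutrophil_pct >= thresholds$neutrophil_pct,
    crp_elevated_1 = x$crp_mg_dl >= thresholds$crp_low_mg_dl,
    crp_elevated_5 = x$crp_mg_dl >= thresholds$crp_high_mg_dl,
    fever          = x$body_temp_c >= thresholds$body_temp_c
  )
  for (bc in .cohort_bool_cols) f[[bc]] <- as.logical(x[[bc]])
  if (!is.null(x$patient_id)) f <- cbind(patient_id = x$patient_id, f)
  f
}
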