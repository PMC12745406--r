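# CHANSE and Pediatric Appendicitis Score (PAS) computation.

#' CHANSE score components
#'
#' The six equally weighted items of the CHANSE score, named by the feature
#' column that carries each: CRP >= 1 mg/dL, a positive heel drop test,
#' anorexia, nausea or vomiting, left shift (PMN >= 75%) and leukocytosis
#' (WBC >= 10,000/uL). One point each, total 0-6.
#'
#' @return Character vector of the six feature-column names.
#' @export
chanse_components <- function() {
  c("crp_elevated_1", "heel_drop", "anorexia", "nausea_or_vomiting",
    "left_shift", "leukocytosis")
}

#' PAS item weights
#'
#' The eight items of the Pediatric Appendicitis Score with their point
#' values: migration of pain (1), anorexia (1), nausea or vomiting (1),
#' right-lower-quadrant tenderness (2), tenderness on cough/percussion/
#' hopping (2), pyrexia (1), leukocytosis (1) and left shift (1);
#' total 0-10, with >= 7 the conventional high-risk threshold.
#'
#' @return Named integer vector of weights keyed by feature-column name.
#' @export
pas_weights <- function() {
  c(migration = 1L, anorexia = 1L, nausea_or_vomiting = 1L,
    rlq_tenderness = 2L, cough_percussion_hopping = 2L,
    fever = 1L, leukocytosis = 1L, left_shift = 1L)
}

.weighted_score <- function(features, weights) {
  features <- as.data.frame(features)
  missing_cols <- setdiff(names(weights), names(features))
  if (length(missing_cols) > 0L) {
    stop("feature column(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  m <- vapply(names(weights),
              function(v) as.logical(features[[v]]) * weights[[v]],
              numeric(nrow(features)))
  if (nrow(features) == 1L) m <- matrix(m, nrow = 1L)
  as.integer(rowSums(m))  # NA whenever any component is missing
}

#' Compute the CHANSE score
#'
#' Counts how many of the six [chanse_components()] are present: one point
#' per positive item, range 0-6. Any missing component yields `NA` for that
#' patient (the record is excluded from score-based analyses rather than
#' imputed).
#'
#' @param features feature data frame from [derive_features()] (or any data
#'   frame with the six logical component columns).
#' @return Integer vector of scores in 0-6, `NA` where a component is missing.
#' @export
chanse_score <- function(features) {
  w <- rep(1L, 6L)
  names(w) <- chanse_components()
  .weighted_score(features, w)
}

#' Compute the Pediatric Appendicitis Score
#'
#' Weighted sum of the eight [pas_weights()] items, range 0-10. Any missing
#' component yields `NA`.
#'
#' @inheritParams chanse_score
#' @return Integer vector of scores in 0-10, `NA` where a component is missing.
#' @export
pas_score <- function(features) {
  .weighted_score(features, pas_weights())
}

#' Dichotomize a score at a cutoff
#'
#' Positive when `score >= cutoff` (inclusive boundary). Conventional
#' cutoffs: CHANSE >= 3, PAS >= 7.
#'
#' @param score integer score vector.
#' @param cutoff scalar cutoff.
#' @return Logical vector; `NA` scores stay `NA`.
#' @export
classify <- function(score, cutoff) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff))
  score >= cutoff
}

#' Score every patient in a cohort
#'
#' Derives features and computes both scores plus the disease indicator
#' (`outcome != "none"`).
#'
#' @param x a [cohort()].
#' @param thresholds output of [feature_thresholds()].
#' @return Data frame with columns `patient_id`, `chanse`, `pas`,
#'   `disease` and `outcome`, one row per patient in input order.
#' @export
score_cohort <- function(x, thresholds = feature_thresholds()) {
  validate_cohort(x)
  f <- derive_features(x, thresholds)
  data.frame(
    patient_id = x$patient_id,
    chanse  = chanse_score(f),
    pas     = pas_score(f),
    disease = x$outcome != "none",
    outcome = x$outcome,
    stringsAsFactors = FALSE
  )
}
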