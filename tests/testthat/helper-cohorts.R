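# Shared fixtures and independent oracles, all built in code.

# A small hand-built cohort covering all three outcome classes.
manual_cohort_df <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3"),
    age_years = c(9.5, 12, 15.2),
    sex = c("male", "female", "male"),
    body_temp_c = c(38.2, 37.0, 36.8),
    pain_duration_h = c(12, 30, 6),
    anorexia = c(TRUE, FALSE, TRUE),
    nausea_or_vomiting = c(TRUE, FALSE, FALSE),
    diarrhea = c(FALSE, TRUE, FALSE),
    migration = c(TRUE, FALSE, FALSE),
    wbc_per_ul = c(14200, 8300, 10000),
    neutrophil_pct = c(81, 60.5, 75),
    crp_mg_dl = c(6.1, 0.4, 1.0),
    rlq_tenderness = c(TRUE, TRUE, FALSE),
    cough_percussion_hopping = c(TRUE, FALSE, FALSE),
    psoas = c(FALSE, FALSE, TRUE),
    obturator = c(FALSE, TRUE, FALSE),
    rovsing = c(TRUE, FALSE, FALSE),
    heel_drop = c(TRUE, FALSE, TRUE),
    outcome = c("complicated", "none", "uncomplicated"),
    stringsAsFactors = FALSE
  )
}

# Brute-force AUC: favorable pairs + half credit for ties, over all
# (positive, negative) score pairs.
brute_auc <- function(scores, diseased) {
  sp <- scores[diseased]; sn <- scores[!diseased]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random feature frame with all columns the scores need.
random_features <- function(n) {
  cols <- unique(c(chanse_components(), names(pas_weights())))
  out <- as.data.frame(lapply(cols, function(x) sample(c(TRUE, FALSE), n,
                                                       replace = TRUE)))
  names(out) <- cols
  out
}
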