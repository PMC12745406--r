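# Synthetic cohort generator: group-conditional binary features via a
# Gaussian copula, truncated-normal labs drawn consistently with the binary
# flags, three-class outcomes, and a severity calibration for the score
# gradient across outcome classes.

# Canonical registry of copula variables (fixed order: sub-streams are
# indexed by position, so appending a variable never perturbs the others).
# crp_elevated_5 is not an independent copula variable: both CRP flags are
# nested bands of one CRP latent (see generate_cohort).
.copula_vars <- c("male_sex", "anorexia", "nausea_or_vomiting", "diarrhea",
                  "migration", "rlq_tenderness", "cough_percussion_hopping",
                  "psoas", "rovsing", "obturator", "heel_drop",
                  "fever", "leukocytosis", "left_shift", "crp_elevated_1")
.lab_streams <- c("shared_factor", "wbc", "neutrophil", "crp",
                  "temperature", "age", "pain", "shuffle")

#' Specification of a synthetic cohort
#'
#' Bundles everything the generator needs: group sizes, group-conditional
#' prevalence of every binary feature, group-conditional mean/SD of every
#' continuous measurement, the latent (Gaussian-copula) correlation, and
#' optional per-severity-subgroup logit shifts. The defaults are the
#' published summary statistics of the 142-child derivation cohort
#' (84 appendicitis, of whom 32 complicated, versus 58 without), taken from
#' [printed_counts()] and [printed_lab_params()].
#'
#' @param n_disease,n_no_disease group sizes (defaults 84 and 58).
#' @param n_complicated number of complicated cases within the disease
#'   group (default 32; the remaining 52 are uncomplicated).
#' @param binary_prevalence data frame with columns `variable`, `p_disease`,
#'   `p_no_disease` for every binary feature.
#' @param lab_params data frame as [printed_lab_params()].
#' @param correlation scalar exchangeable latent correlation `rho` in
#'   \[0, 1) (0 = independent features, the default: the published tables
#'   identify only the marginals, so joint dependence is an explicit user
#'   knob), or a full positive-semi-definite correlation matrix over the
#'   copula variables.
#' @param match_flag_prevalence if `TRUE` (default), the binary lab flags
#'   (fever, leukocytosis, left shift, both CRP levels) are drawn directly
#'   at their published prevalences and the continuous labs are then drawn
#'   from the group's truncated normal conditioned on the flag, so flag
#'   marginals match the published table exactly. If `FALSE`, continuous
#'   labs are drawn unconditionally and flags are derived by thresholding
#'   ([derive_features()]); flag prevalences then only approximate the
#'   published ones.
#' @param severity_shift named numeric, logit shifts applied uniformly to
#'   the six CHANSE component prevalences (and CRP >= 5, which rides along
#'   to keep the CRP bands nested) of the `uncomplicated` and `complicated`
#'   subgroups; see [calibrate_severity_shift()].
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_disease = 84L, n_no_disease = 58L,
                        n_complicated = 32L,
                        binary_prevalence = NULL,
                        lab_params = printed_lab_params(),
                        correlation = 0,
                        match_flag_prevalence = TRUE,
                        severity_shift = c(uncomplicated = 0, complicated = 0),
                        seed = 1L) {
  if (is.null(binary_prevalence)) {
    pc <- printed_counts()
    binary_prevalence <- data.frame(
      variable = pc$variable,
      p_disease = pc$pos_disease / pc$n_disease,
      p_no_disease = pc$pos_no_disease / pc$n_no_disease,
      stringsAsFactors = FALSE
    )
  }
  spec <- structure(list(
    n_disease = as.integer(n_disease),
    n_no_disease = as.integer(n_no_disease),
    n_complicated = as.integer(n_complicated),
    binary_prevalence = binary_prevalence,
    lab_params = lab_params,
    correlation = correlation,
    match_flag_prevalence = isTRUE(match_flag_prevalence),
    severity_shift = severity_shift,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return The spec, invisibly, or an error.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  bp <- spec$binary_prevalence
  if (spec$n_disease < 0 || spec$n_no_disease < 0 ||
      spec$n_complicated < 0 || spec$n_complicated > spec$n_disease) {
    stop("inconsistent group sizes: need 0 <= n_complicated <= n_disease")
  }
  p <- c(bp$p_disease, bp$p_no_disease)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("binary prevalences must lie in [0, 1]")
  }
  if (any(spec$lab_params$sd_disease <= 0) ||
      any(spec$lab_params$sd_no_disease <= 0)) {
    stop("lab SDs must be positive")
  }
  rho <- spec$correlation
  if (is.matrix(rho)) {
    d <- sum(bp$variable %in% .copula_vars)
    if (nrow(rho) != d || ncol(rho) != d) {
      stop("correlation matrix must be ", d, " x ", d,
           " (one row per copula variable)")
    }
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite")
    }
  } else {
    if (length(rho) != 1L || rho < 0 || rho >= 1) {
      stop("scalar exchangeable correlation must lie in [0, 1)")
    }
  }
  if (!all(c("uncomplicated", "complicated") %in% names(spec$severity_shift))) {
    stop("severity_shift needs 'uncomplicated' and 'complicated' entries")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_spec> %d appendicitis (%d complicated) / %d without; ",
    "rho = %s; flags %s; severity shift (%.2f, %.2f)\n"),
    x$n_disease, x$n_complicated, x$n_no_disease,
    if (is.matrix(x$correlation)) "matrix" else format(x$correlation),
    if (x$match_flag_prevalence) "drawn at published prevalence"
    else "derived from simulated labs",
    x$severity_shift[["uncomplicated"]], x$severity_shift[["complicated"]]))
  invisible(x)
}

# Deterministic sub-stream seeds: one per (group, variable-slot), derived
# once from the master seed so streams are mutually independent and adding
# a registry entry leaves earlier streams untouched.
.substreams <- function(seed, n_groups = 3L) {
  n_slots <- length(.copula_vars) + length(.lab_streams) + 5L
  set.seed(seed)
  m <- matrix(sample.int(.Machine$integer.max - 1L, n_groups * n_slots),
              nrow = n_groups)
  colnames(m) <- c(.copula_vars, .lab_streams,
                   paste0("reserved", seq_len(5L)))
  m
}

# Inverse-CDF truncated normal draw on [lo, hi].
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- plo + stats::runif(n) * (phi - plo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

# Subgroup prevalence vector, with the severity logit shift applied to the
# CHANSE components (plus crp_elevated_5, keeping the CRP bands nested).
.subgroup_prevalence <- function(spec, subgroup) {
  bp <- spec$binary_prevalence
  p <- stats::setNames(
    if (subgroup == "none") bp$p_no_disease else bp$p_disease,
    bp$variable)
  if (subgroup %in% c("uncomplicated", "complicated")) {
    s <- spec$severity_shift[[subgroup]]
    if (s != 0) {
      shift_vars <- intersect(c(chanse_components(), "crp_elevated_5"),
                              names(p))
      p[shift_vars] <- stats::plogis(stats::qlogis(p[shift_vars]) + s)
    }
  }
  p
}

# Draw the binary feature block for one subgroup via the Gaussian copula.
.draw_binaries <- function(n, p, rho, streams) {
  vars <- intersect(.copula_vars, names(p))
  z <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  if (is.matrix(rho)) {
    set.seed(streams[["shared_factor"]])
    z[] <- matrix(stats::rnorm(n * length(vars)), n) %*% chol(rho)
  } else {
    set.seed(streams[["shared_factor"]])
    z0 <- stats::rnorm(n)
    for (v in vars) {
      set.seed(streams[[v]])
      z[, v] <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
    }
  }
  flags <- sweep(z, 2, stats::qnorm(p[vars]), FUN = "<")
  # nested CRP bands from the single CRP latent
  crp_latent <- z[, "crp_elevated_1"]
  flags <- cbind(flags,
                 crp_elevated_5 = crp_latent < stats::qnorm(p[["crp_elevated_5"]]))
  flags
}

#' Generate a synthetic patient-level cohort
#'
#' Draws a cohort with exactly the specified group sizes. Binary features
#' come from a latent Gaussian copula thresholded at the group-conditional
#' prevalences (`rho = 0` reduces to independent Bernoulli draws; the two
#' CRP flags are nested bands of a single latent, so CRP >= 5 always implies
#' CRP >= 1). Continuous labs are truncated-at-zero normals with the
#' group's published mean/SD; in the default `match_flag_prevalence` mode
#' each lab is drawn conditional on its simulated flag (e.g. WBC from the
#' region at or above 10,000/uL when leukocytosis is positive), so derived
#' flags are consistent with the labs AND flag marginals are exact.
#' Fully reproducible from the seed; sub-streams per group and variable
#' mean that adding a variable does not perturb the draws of others.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed (defaults to `spec$seed`).
#' @return A [cohort()] with provenance recording the seed.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  thr <- feature_thresholds()
  streams <- .substreams(seed)
  groups <- list(
    none          = spec$n_no_disease,
    uncomplicated = spec$n_disease - spec$n_complicated,
    complicated   = spec$n_complicated
  )
  pieces <- list()
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    n <- groups[[g]]
    if (n == 0L) next
    p <- .subgroup_prevalence(spec, g)
    st <- streams[gi, ]
    flags <- .draw_binaries(n, p, spec$correlation, st)
    lp <- spec$lab_params
    gsfx <- if (g == "none") "no_disease" else "disease"
    lab <- function(name) {
      i <- match(name, lp$lab)
      c(mean = lp[[paste0("mean_", gsfx)]][i],
        sd = lp[[paste0("sd_", gsfx)]][i])
    }
    wbc_p  <- lab("wbc_10e3_per_ul")
    neut_p <- lab("neutrophil_pct")
    crp_p  <- lab("crp_mg_dl")
    tmp_p  <- lab("body_temp_c")
    age_p  <- lab("age_years")
    pain_p <- lab("pain_duration_h")
    wbc_thr <- thr$wbc_per_ul / 1000  # lab params are in 10^3 cells/uL

    if (spec$match_flag_prevalence) {
      set.seed(st[["wbc"]])
      wbc <- ifelse(flags[, "leukocytosis"],
                    .rtruncnorm(n, wbc_p["mean"], wbc_p["sd"], wbc_thr, Inf),
                    .rtruncnorm(n, wbc_p["mean"], wbc_p["sd"], 0, wbc_thr))
      set.seed(st[["neutrophil"]])
      neut <- ifelse(flags[, "left_shift"],
                     .rtruncnorm(n, neut_p["mean"], neut_p["sd"],
                                 thr$neutrophil_pct, 100),
                     .rtruncnorm(n, neut_p["mean"], neut_p["sd"],
                                 0, thr$neutrophil_pct))
      set.seed(st[["crp"]])
      band_lo <- ifelse(flags[, "crp_elevated_5"], thr$crp_high_mg_dl,
                        ifelse(flags[, "crp_elevated_1"], thr$crp_low_mg_dl, 0))
      band_hi <- ifelse(flags[, "crp_elevated_5"], Inf,
                        ifelse(flags[, "crp_elevated_1"], thr$crp_high_mg_dl,
                               thr$crp_low_mg_dl))
      crp <- .rtruncnorm(n, crp_p["mean"], crp_p["sd"], band_lo, band_hi)
      set.seed(st[["temperature"]])
      temp <- ifelse(flags[, "fever"],
                     .rtruncnorm(n, tmp_p["mean"], tmp_p["sd"],
                                 thr$body_temp_c, Inf),
                     .rtruncnorm(n, tmp_p["mean"], tmp_p["sd"],
                                 -Inf, thr$body_temp_c))
    } else {
      set.seed(st[["wbc"]])
      wbc <- .rtruncnorm(n, wbc_p["mean"], wbc_p["sd"], 0, Inf)
      set.seed(st[["neutrophil"]])
      neut <- .rtruncnorm(n, neut_p["mean"], neut_p["sd"], 0, 100)
      set.seed(st[["crp"]])
      crp <- .rtruncnorm(n, crp_p["mean"], crp_p["sd"], 0, Inf)
      set.seed(st[["temperature"]])
      temp <- stats::rnorm(n, tmp_p["mean"], tmp_p["sd"])
    }
    set.seed(st[["age"]])
    age <- .rtruncnorm(n, age_p["mean"], age_p["sd"], 0, Inf)
    set.seed(st[["pain"]])
    pain <- .rtruncnorm(n, pain_p["mean"], pain_p["sd"], 0, Inf)

    pieces[[g]] <- data.frame(
      patient_id = NA_character_,
      age_years = age,
      sex = ifelse(flags[, "male_sex"], "male", "female"),
      body_temp_c = temp,
      pain_duration_h = pain,
      anorexia = flags[, "anorexia"],
      nausea_or_vomiting = flags[, "nausea_or_vomiting"],
      diarrhea = flags[, "diarrhea"],
      migration = flags[, "migration"],
      wbc_per_ul = wbc * 1000,
      neutrophil_pct = neut,
      crp_mg_dl = crp,
      rlq_tenderness = flags[, "rlq_tenderness"],
      cough_percussion_hopping = flags[, "cough_percussion_hopping"],
      psoas = flags[, "psoas"],
      obturator = flags[, "obturator"],
      rovsing = flags[, "rovsing"],
      heel_drop = flags[, "heel_drop"],
      outcome = g,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
  rho_txt <- if (is.matrix(spec$correlation)) "matrix"
             else format(spec$correlation)
  cohort(out, provenance = sprintf("synthetic: seed=%d, rho=%s", seed, rho_txt))
}

#' Expected CHANSE score mean implied by a spec
#'
#' Under the generator's model the expected score of a subgroup is simply
#' the sum of the six component prevalences (the copula correlation moves
#' the score's variance, never its mean), so the expectation is available
#' in closed form.
#'
#' @param spec a [cohort_spec()].
#' @param subgroup one of `"none"`, `"uncomplicated"`, `"complicated"`.
#' @return Scalar expected score in \[0, 6\].
#' @export
expected_chanse_mean <- function(spec,
                                 subgroup = c("uncomplicated", "complicated",
                                              "none")) {
  subgroup <- match.arg(subgroup)
  p <- .subgroup_prevalence(spec, subgroup)
  sum(p[chanse_components()])
}

#' Calibrate severity-subgroup prevalences to target score means
#'
#' Finds, for each severity subgroup, the single logit shift applied
#' uniformly to all six CHANSE component prevalences such that the
#' subgroup's expected score equals the target (e.g. the published gradient
#' of 3.0 in uncomplicated vs 4.6 in complicated appendicitis). The
#' expected score is an increasing function of the shift, so each shift is
#' the root of a monotone one-dimensional equation. When a target equals
#' the subgroup's unshifted expectation the returned shift is zero.
#'
#' @param spec a [cohort_spec()].
#' @param target_means length-2 numeric: target mean score for the
#'   uncomplicated and complicated subgroups, each strictly inside (0, 6).
#' @return The spec with `severity_shift` set to the fitted shifts.
#' @export
calibrate_severity_shift <- function(spec, target_means = c(3.0, 4.6)) {
  validate_cohort_spec(spec)
  stopifnot(length(target_means) == 2L)
  if (any(target_means <= 0) || any(target_means >= 6)) {
    stop("unreachable target means: must lie strictly between 0 and 6")
  }
  bp <- spec$binary_prevalence
  p_dis <- stats::setNames(bp$p_disease, bp$variable)[chanse_components()]
  mean_at <- function(s) sum(stats::plogis(stats::qlogis(p_dis) + s))
  fit_one <- function(target) {
    stats::uniroot(function(s) mean_at(s) - target,
                   lower = -40, upper = 40, tol = 1e-10)$root
  }
  shifts <- c(uncomplicated = fit_one(target_means[1]),
              complicated = fit_one(target_means[2]))
  shifts[abs(shifts) < 1e-8] <- 0
  spec$severity_shift <- shifts
  spec
}
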