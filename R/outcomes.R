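#' Assess CNV activity at a follow-up visit
#'
#' A visit is active when any of the activity criteria used to steer a
#' treat-and-extend schedule is met: a loss of at least five ETDRS letters
#' together with intraretinal and/or subretinal fluid; macular hemorrhage;
#' fluid persisting since the previous visit; or an increase of central
#' macular thickness in the presence of fluid.
#'
#' @param visit,previous named lists or one-row data.frames with fields
#'   `bcva_letters`, `cmt_um`, `irf`, `srf`, `hemorrhage`.
#' @return TRUE if the visit shows neovascular activity.
#' @export
assess_activity <- function(visit, previous) {
  need <- c("bcva_letters", "cmt_um", "irf", "srf", "hemorrhage")
  for (f in need) {
    if (is.null(visit[[f]]) || is.na(visit[[f]]))
      stop("missing field in current visit: ", f, call. = FALSE)
    if (is.null(previous[[f]]) || is.na(previous[[f]]))
      stop("missing field in previous visit: ", f, call. = FALSE)
  }
  fluid_now <- isTRUE(as.logical(visit$irf)) || isTRUE(as.logical(visit$srf))
  fluid_prev <- isTRUE(as.logical(previous$irf)) || isTRUE(as.logical(previous$srf))
  va_loss <- (previous$bcva_letters - visit$bcva_letters) >= 5
  (va_loss && fluid_now) ||
    isTRUE(as.logical(visit$hemorrhage)) ||
    (fluid_now && fluid_prev) ||
    (visit$cmt_um > previous$cmt_um && fluid_now)
}

#' Classify the anatomic response to the loading dose
#'
#' Good response: complete resolution of intraretinal and subretinal fluid
#' at the 3-month visit, or a decrease of central macular thickness greater
#' than 100 micrometers from baseline. Bad response otherwise (CMT increase
#' or a decrease of at most 100 micrometers without fluid resolution). When
#' fluid resolves but CMT falls by 100 micrometers or less, the resolution
#' clause prevails and the response is good.
#'
#' @param baseline,month3 records with `cmt_um`, `irf`, `srf`.
#' @return `"good"` or `"bad"`.
#' @export
classify_anatomic_response <- function(baseline, month3) {
  for (f in c("cmt_um", "irf", "srf")) {
    if (is.null(baseline[[f]]) || is.na(baseline[[f]]) ||
        is.null(month3[[f]]) || is.na(month3[[f]]))
      stop("missing field: ", f, call. = FALSE)
  }
  resolved <- !as.logical(month3$irf) && !as.logical(month3$srf)
  if (resolved || (baseline$cmt_um - month3$cmt_um) > 100) "good" else "bad"
}

#' Classify the functional response at 12 months
#'
#' Good response: a gain of at least five ETDRS letters between baseline
#' and the 12-month visit. Patients without a 12-month BCVA are excluded
#' (`NA`).
#'
#' @param bcva_baseline,bcva_12m BCVA in ETDRS letters; `bcva_12m` may be
#'   `NA` for patients lost to follow-up.
#' @return `"good"`, `"other"`, or `NA` when the 12-month visit is missing.
#' @export
classify_functional_response <- function(bcva_baseline, bcva_12m) {
  if (is.null(bcva_baseline) || is.na(bcva_baseline))
    stop("missing baseline BCVA", call. = FALSE)
  if (is.null(bcva_12m) || is.na(bcva_12m)) return(NA_character_)
  if (bcva_12m - bcva_baseline >= 5) "good" else "other"
}

#' Classify the treatment burden over the first year
#'
#' Counts injections given before the horizon and applies the regular
#' versus extended cutoff: eight or more intravitreal injections is a
#' regular burden, seven or fewer an extended one.
#'
#' @param course a data.frame of visits with `week` and `injection`
#'   columns (e.g. one patient's rows of a cohort `visits` table), or a
#'   `simulate_tae_course()` result.
#' @param horizon_weeks counting horizon (weeks, exclusive).
#' @return A list with `injection_count` and `burden_class`
#'   (`"regular"`/`"extended"`).
#' @export
classify_burden <- function(course, horizon_weeks = 52) {
  stopifnot(is.data.frame(course), all(c("week", "injection") %in% names(course)))
  n <- sum(course$injection & course$week < horizon_weeks)
  list(injection_count = as.integer(n),
       burden_class = if (n >= 8) "regular" else "extended")
}

#' Label every patient of a simulated cohort
#'
#' Applies the three outcome classifiers to a `tae_cohort`: anatomic
#' response (baseline vs 3-month assessment), functional response
#' (baseline vs 12-month BCVA; `NA` for non-completers) and treatment
#' burden (injections before the horizon).
#'
#' @param cohort a `tae_cohort`.
#' @return A data.frame with one row per patient: `patient_id`,
#'   `anatomic_response`, `functional_response`, `burden_class`,
#'   `injection_count`.
#' @export
label_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "tae_cohort"))
  horizon <- cohort$config$horizon_weeks
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    pid <- cohort$patients$patient_id[i]
    a <- cohort$assessments[cohort$assessments$patient_id == pid, ]
    b <- a[a$week == 0, ]; m3 <- a[a$week == 12, ]; m12 <- a[a$week == 52, ]
    v <- cohort$visits[cohort$visits$patient_id == pid, ]
    completed <- nrow(m12) > 0L
    burden <- classify_burden(v, horizon)
    data.frame(
      patient_id = pid,
      anatomic_response = classify_anatomic_response(b, m3),
      functional_response = classify_functional_response(
        b$bcva_letters, if (completed) m12$bcva_letters else NA),
      # burden over the first year is defined for completers only
      burden_class = if (completed) burden$burden_class else NA_character_,
      injection_count = burden$injection_count)
  })
  do.call(rbind, out)
}
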