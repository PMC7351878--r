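#' Full statistical analysis of a quantified cohort
#'
#' Reproduces the standard analysis table structure for a treated CNV
#' cohort: per-biomarker serial comparisons (baseline vs 3-month and
#' baseline vs 12-month paired tests, with median/IQR summaries),
#' repeatability ICC from the duplicate baseline acquisitions, per-outcome
#' group comparisons of baseline biomarkers (Mann-Whitney), and univariable
#' binary GLMs with odds ratios and ROC discrimination per predictor and
#' outcome. The BCVA change over the loading phase is additionally modeled
#' against the functional response.
#'
#' @param metrics data.frame of per-image biomarkers as produced by
#'   [run_quantify()] or [quantify_cohort_images()]: columns `patient_id`,
#'   `visit_week`, `acquisition`, `fd`, `lac`, `sa_mm2`, `vd`.
#' @param labels per-patient outcome labels from [label_cohort()].
#' @param assessments assessment-visit table (for the BCVA-change model);
#'   optional.
#' @param or_unit_scales named vector of predictor units per reported odds
#'   ratio.
#' @return A nested list of class `cohort_analysis` with elements
#'   `burden`, `serial`, `repeatability`, `groups`, `models`.
#' @export
analyze_cohort <- function(metrics, labels, assessments = NULL,
                           or_unit_scales = c(fd = 0.01, lac = 0.01,
                                              sa_mm2 = 1, vd = 0.01)) {
  params <- c("fd", "lac", "sa_mm2", "vd")
  need <- c("patient_id", "visit_week", "acquisition", params)
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("patient_id", "anatomic_response", "functional_response",
                    "burden_class", "injection_count"), names(labels))
  if (length(miss))
    stop("labels table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  base <- metrics[metrics$visit_week == 0 & metrics$acquisition == 1L, ]
  rep2 <- metrics[metrics$visit_week == 0 & metrics$acquisition == 2L, ]
  m3 <- metrics[metrics$visit_week == 12 & metrics$acquisition == 1L, ]
  m12 <- metrics[metrics$visit_week == 52 & metrics$acquisition == 1L, ]

  paired_tbl <- function(later) {
    ids <- intersect(base$patient_id, later$patient_id)
    b <- base[match(ids, base$patient_id), ]
    l <- later[match(ids, later$patient_id), ]
    setNames(lapply(params, function(p) tryCatch({
      pt <- paired_location_test(b[[p]], l[[p]])
      c(describe_pair(b[[p]], l[[p]]),
        list(p_value = pt$p_value, test = pt$method, n = length(ids)))
    }, error = function(e) list(note = conditionMessage(e)))), params)
  }
  serial <- list(month3 = paired_tbl(m3), month12 = paired_tbl(m12))

  repeatability <- NULL
  if (nrow(rep2) > 2L) {
    ids <- intersect(base$patient_id, rep2$patient_id)
    b <- base[match(ids, base$patient_id), ]
    r <- rep2[match(ids, rep2$patient_id), ]
    repeatability <- setNames(lapply(params, function(p) {
      tryCatch({
        icc <- icc_absolute_agreement(cbind(b[[p]], r[[p]]))
        list(icc = icc$estimate, conf_low = icc$conf_low,
             conf_high = icc$conf_high, n = icc$n, model = icc$model)
      }, error = function(e) list(note = conditionMessage(e)))
    }), params)
  }

  lab <- labels[match(base$patient_id, labels$patient_id), ]
  outcomes <- list(
    anatomic = list(values = lab$anatomic_response, positive = "bad"),
    functional = list(values = lab$functional_response, positive = "other"),
    burden = list(values = lab$burden_class, positive = "regular"))

  # degenerate strata (single class, too few observations) yield a note
  # instead of aborting the whole battery
  safely <- function(expr) tryCatch(expr, error = function(e)
    list(note = conditionMessage(e)))

  groups <- lapply(outcomes, function(oc) {
    keep <- !is.na(oc$values)
    setNames(lapply(params, function(p) safely({
      g1 <- base[[p]][keep & oc$values == oc$positive]
      g0 <- base[[p]][keep & oc$values != oc$positive]
      rs <- rank_sum_test(g1, g0)
      list(positive_class = oc$positive,
           median_positive = median(g1, na.rm = TRUE),
           median_negative = median(g0, na.rm = TRUE),
           p_value = rs$p_value, n = unname(rs$n))
    })), params)
  })

  models <- lapply(outcomes, function(oc) {
    keep <- !is.na(oc$values)
    setNames(lapply(params, function(p) safely({
      fit <- fit_binary_glm(base[[p]][keep],
                            oc$values[keep] == oc$positive,
                            unit_scale = or_unit_scales[[p]])
      list(positive_class = oc$positive,
           odds_ratio = fit$odds_ratio, or_conf_low = fit$or_conf_low,
           or_conf_high = fit$or_conf_high, unit_scale = fit$unit_scale,
           auc = fit$auc$auc, auc_conf_low = fit$auc$conf_low,
           auc_conf_high = fit$auc$conf_high, band = fit$auc$band,
           n = fit$n)
    })), params)
  })

  if (!is.null(assessments)) {
    b <- assessments[assessments$week == 0, ]
    a3 <- assessments[assessments$week == 12, ]
    ids <- labels$patient_id[!is.na(labels$functional_response)]
    ids <- intersect(ids, intersect(b$patient_id, a3$patient_id))
    if (length(ids) >= 10L) {
      gain <- a3$bcva_letters[match(ids, a3$patient_id)] -
        b$bcva_letters[match(ids, b$patient_id)]
      fr <- labels$functional_response[match(ids, labels$patient_id)]
      models$functional$bcva_gain_loading <- safely({
      fit <- fit_binary_glm(gain, fr == "good", unit_scale = 1)
      list(
        positive_class = "good",
        odds_ratio = fit$odds_ratio, or_conf_low = fit$or_conf_low,
        or_conf_high = fit$or_conf_high, unit_scale = 1,
        auc = fit$auc$auc, auc_conf_low = fit$auc$conf_low,
        auc_conf_high = fit$auc$conf_high, band = fit$auc$band, n = fit$n)
      })
    }
  }

  done <- !is.na(labels$burden_class)
  burden <- c(describe(labels$injection_count[done]),
              list(regular_fraction = mean(labels$burden_class[done] ==
                                             "regular")))

  structure(list(burden = burden, serial = serial,
                 repeatability = repeatability, groups = groups,
                 models = models),
            class = "cohort_analysis")
}

describe_pair <- function(b, l) {
  db <- describe(b); dl <- describe(l)
  list(baseline_median = db$median, baseline_q25 = db$q25,
       baseline_q75 = db$q75, followup_median = dl$median,
       followup_q25 = dl$q25, followup_q75 = dl$q75)
}

#' Quantify every angiogram of an in-memory cohort
#'
#' Runs [quantify_lesion()] on each image generated by
#' [generate_cohort()] (requires `with_images = TRUE`) and assembles the
#' per-image biomarker table.
#'
#' @param cohort a `tae_cohort` carrying `images` and `manifest`.
#' @param ... passed to [quantify_lesion()].
#' @return A data.frame with one row per image.
#' @export
quantify_cohort_images <- function(cohort, ...) {
  stopifnot(inherits(cohort, "tae_cohort"))
  if (is.null(cohort$images))
    stop("cohort was generated without images", call. = FALSE)
  rows <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    mf <- cohort$manifest[i, ]
    q <- quantify_lesion(cohort$images[[mf$image_index]], ...)
    metrics_row(q, patient_id = mf$patient_id, visit_week = mf$visit_week,
                acquisition = mf$acquisition)
  })
  do.call(rbind, rows)
}
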