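#' Simulate a cohort and write it to disk
#'
#' Stage 1 of the pipeline: generates a synthetic TAE cohort (tables and,
#' optionally, per-assessment angiograms), writes the patients / visits /
#' assessments CSVs, the images as 8-bit grayscale PNG or TIFF with a
#' manifest CSV, and a fully resolved `run.yaml` (including the seed and an
#' MD5 hash of the configuration) next to the outputs.
#'
#' @param out_dir output directory (created).
#' @param config a [cohort_config()], or a path to a YAML file of
#'   `cohort_config` arguments.
#' @param with_images rasterize and write angiograms.
#' @param image_format `"png"` or `"tiff"`.
#' @param quiet suppress progress messages.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(out_dir, config = cohort_config(),
                         with_images = TRUE, image_format = c("png", "tiff"),
                         quiet = FALSE) {
  image_format <- match.arg(image_format)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  cohort <- generate_cohort(config, with_images = with_images)
  write_cohort(cohort, out_dir)
  if (with_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    mf <- cohort$manifest
    mf$path <- sprintf("images/%s_w%02d_a%d.%s", mf$patient_id,
                       mf$visit_week, mf$acquisition, image_format)
    for (i in seq_len(nrow(mf)))
      write_angiogram(cohort$images[[mf$image_index[i]]],
                      file.path(out_dir, mf$path[i]))
    mf$field_mm <- config$img_spec$field_mm
    write.csv(mf[, c("patient_id", "visit_week", "acquisition", "path",
                     "field_mm")],
              file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  write_run_config(config, file.path(out_dir, "run.yaml"))
  if (!quiet)
    message(sprintf("[simulate] %d patients%s in %.1fs -> %s",
                    nrow(cohort$patients),
                    if (with_images) sprintf(", %d images",
                                             length(cohort$images)) else "",
                    as.numeric(Sys.time() - t0, units = "secs"), out_dir))
  invisible(out_dir)
}

#' Quantify the angiograms of a simulated or imported run
#'
#' Stage 2: reads `manifest.csv` and the referenced grayscale images from
#' `dir`, computes the four biomarkers per image with [quantify_lesion()],
#' and writes `metrics.csv`. Unreadable images are skipped with a flagged
#' row and a message; the run continues.
#'
#' @param dir directory holding `manifest.csv` and the images.
#' @param quiet suppress progress messages.
#' @param ... passed to [quantify_lesion()].
#' @return Invisibly, the metrics data.frame (also written as
#'   `metrics.csv`).
#' @export
run_quantify <- function(dir, quiet = FALSE, ...) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  mf <- read.csv(mf_path)
  if (nrow(mf) == 0L) stop("empty manifest", call. = FALSE)
  t0 <- Sys.time()
  rows <- lapply(seq_len(nrow(mf)), function(i) {
    path <- file.path(dir, mf$path[i])
    q <- tryCatch({
      img <- read_angiogram(path, field_mm = mf$field_mm[i] %||% 4.5)
      quantify_lesion(img, ...)
    }, error = function(e) {
      message(sprintf("[quantify] skipping %s: %s", mf$path[i],
                      conditionMessage(e)))
      structure(list(fd = NA_real_, n0 = NA_real_, lac = NA_real_,
                     sa_mm2 = NA_real_, vd = NA_real_, fit_r2 = NA_real_,
                     fd_spread = NA_real_, n_components = NA_integer_,
                     flags = "unreadable"),
                class = "lesion_metrics")
    })
    metrics_row(q, patient_id = mf$patient_id[i],
                visit_week = mf$visit_week[i],
                acquisition = mf$acquisition[i])
  })
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!quiet)
    message(sprintf("[quantify] %d images in %.1fs -> %s", nrow(metrics),
                    as.numeric(Sys.time() - t0, units = "secs"),
                    file.path(dir, "metrics.csv")))
  invisible(metrics)
}

#' Run the statistical battery of a quantified run
#'
#' Stage 3: reads the cohort tables and `metrics.csv` from `dir`, derives
#' the outcome labels, runs [analyze_cohort()], and writes `labels.csv`,
#' `results.json` and (optionally) ROC / partial-function figures. The
#' JSON is written deterministically, so identical inputs yield identical
#' bytes.
#'
#' @param dir run directory (output of [run_simulate()] + [run_quantify()]).
#' @param figures also write `roc_burden_fd.png` and
#'   `partial_burden_fd.png`.
#' @param quiet suppress progress messages.
#' @return Invisibly, the `cohort_analysis`.
#' @export
run_analyze <- function(dir, figures = TRUE, quiet = FALSE) {
  paths <- file.path(dir, c("patients.csv", "visits.csv", "assessments.csv",
                            "metrics.csv"))
  for (p in paths) if (!file.exists(p)) stop("missing ", p, call. = FALSE)
  patients <- read.csv(paths[1]); visits <- read.csv(paths[2])
  assessments <- read.csv(paths[3]); metrics <- read.csv(paths[4])
  t0 <- Sys.time()
  labels <- label_tables(patients, visits, assessments)
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  res <- analyze_cohort(metrics, labels, assessments)
  meta <- list(config_hash = unname(tools::md5sum(file.path(dir, "run.yaml"))),
               n_patients = nrow(patients))
  jsonlite::write_json(c(list(meta = meta), unclass(res)),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  if (figures) {
    base <- metrics[metrics$visit_week == 0 & metrics$acquisition == 1L, ]
    lab <- labels[match(base$patient_id, labels$patient_id), ]
    keep <- !is.na(lab$burden_class) & !is.na(base$fd)
    if (sum(keep) >= 10L && length(unique(lab$burden_class[keep])) == 2L) {
      fit <- fit_binary_glm(base$fd[keep], lab$burden_class[keep] == "regular",
                            unit_scale = 0.01, smooth_df = 3L)
      grDevices::png(file.path(dir, "roc_burden_fd.png"), 600, 600)
      plot(fit$auc, main = sprintf("Baseline FD vs burden, AUC = %.2f",
                                   fit$auc$auc))
      grDevices::dev.off()
      grDevices::png(file.path(dir, "partial_burden_fd.png"), 600, 600)
      plot(fit, xlab = "baseline FD",
           main = "Partial log-odds of a regular burden")
      grDevices::dev.off()
    }
  }
  if (!quiet)
    message(sprintf("[analyze] results.json written in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
  invisible(res)
}

# outcome labels from the on-disk table representation
label_tables <- function(patients, visits, assessments) {
  out <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    a <- assessments[assessments$patient_id == pid, ]
    b <- a[a$week == 0, ]; m3 <- a[a$week == 12, ]; m12 <- a[a$week == 52, ]
    v <- visits[visits$patient_id == pid, ]
    completed <- nrow(m12) > 0L
    burden <- classify_burden(v)
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

#' Read and write run configuration YAML
#'
#' The YAML holds [cohort_config()] arguments (nested `protocol` and
#' `img_spec` sections); `write_run_config()` stores the fully resolved
#' configuration so a run can be reproduced from its output directory
#' alone.
#'
#' @param path YAML file path.
#' @param config a `cohort_config`.
#' @return `read_run_config()` returns a `cohort_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$protocol)) y$protocol <- do.call(tae_protocol, y$protocol)
  if (!is.null(y$img_spec)) y$img_spec <- do.call(image_spec, y$img_spec)
  do.call(cohort_config, y)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- unclass(config)
  y$protocol <- unclass(y$protocol)
  y$img_spec <- unclass(y$img_spec)
  yaml::write_yaml(y, path)
  invisible(path)
}
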