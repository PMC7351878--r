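#' Configuration of a synthetic treat-and-extend cohort
#'
#' Defines the joint distribution of baseline lesion morphology, the
#' coupling between morphology and per-visit CNV activity, the clinical
#' trajectories, and the TAE protocol. Defaults emulate a typical
#' treatment-naive nAMD cohort under aflibercept: baseline fractal
#' dimension (FD) truncated-normal on \[1.2, 1.6\] around 1.47, blood-flow
#' surface area (SA) log-normal around a 0.62 mm^2 median, and a latent
#' activity drive whose log-odds fall with baseline FD and log-SA — small
#' low-complexity lesions (aggressive angiogenic environments) demand more
#' frequent injections, so both coupling coefficients are negative.
#'
#' @param n_patients cohort size (>= 2); default 64.
#' @param fd_mean,fd_sd,fd_range truncated-normal parameters of baseline FD.
#' @param sa_meanlog,sa_sdlog log-normal parameters of baseline SA (mm^2);
#'   defaults match a 0.62 (0.28-1.52) median (IQR) profile.
#' @param alpha0 intercept of the per-visit activity log-odds at the
#'   reference morphology (FD = `fd_mean`, SA at its median); calibrated so
#'   the median injection count over the first year is 7.
#' @param beta_fd activity log-odds per FD unit (negative by default).
#' @param beta_logsa activity log-odds per unit of log SA (negative).
#' @param carryover added to the activity log-odds at a visit when the
#'   previous visit was active; 0 disables serial correlation.
#' @param bcva_noise_sd per-visit BCVA measurement noise (ETDRS letters).
#' @param dropout_rate fraction of patients lost before the 12-month visit.
#' @param protocol a [tae_protocol()].
#' @param horizon_weeks follow-up span in weeks.
#' @param img_spec an [image_spec()] used when angiograms are generated.
#' @param seed master RNG seed; every patient derives an independent
#'   sub-seed from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 64L,
                          fd_mean = 1.47, fd_sd = 0.08,
                          fd_range = c(1.2, 1.6),
                          sa_meanlog = log(0.62), sa_sdlog = 1.25,
                          alpha0 = -0.65, beta_fd = -22, beta_logsa = -1.2,
                          carryover = 0,
                          bcva_noise_sd = 3,
                          dropout_rate = 0.19,
                          protocol = tae_protocol(),
                          horizon_weeks = 52,
                          img_spec = image_spec(),
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L)
    stop("`n_patients` must be at least 2", call. = FALSE)
  if (horizon_weeks < max(protocol$loading_weeks))
    stop("`horizon_weeks` must cover the loading phase", call. = FALSE)
  if (fd_range[1] >= fd_range[2]) stop("invalid `fd_range`", call. = FALSE)
  structure(list(n_patients = n_patients, fd_mean = fd_mean, fd_sd = fd_sd,
                 fd_range = fd_range, sa_meanlog = sa_meanlog,
                 sa_sdlog = sa_sdlog, alpha0 = alpha0, beta_fd = beta_fd,
                 beta_logsa = beta_logsa, carryover = carryover,
                 bcva_noise_sd = bcva_noise_sd, dropout_rate = dropout_rate,
                 protocol = protocol, horizon_weeks = horizon_weeks,
                 img_spec = img_spec, seed = as.integer(seed)),
            class = "cohort_config")
}

# Calibration of the tree generator measured on rasterized trees at
# radius 0.8 mm (320 px / 4.5 mm grid, length budget 165 mm/mm^2): mean
# skeleton FD and area fill (SA / radius^2) as functions of the complexity
# parameter, averaged over seeds. Used to invert a target (FD, SA) draw
# into (complexity, radius). Measured FD saturates above complexity ~0.45
# at this lesion scale, so high FD draws compress onto the upper range.
.fd_calib <- list(complexity = c(0, 0.15, 0.30, 0.45, 0.60),
                  fd = c(0.88, 1.17, 1.27, 1.301, 1.302),
                  fill = c(0.19, 0.85, 1.48, 2.0, 2.0))

complexity_for_fd <- function(fd) {
  stats::approx(.fd_calib$fd, .fd_calib$complexity, xout = fd, rule = 2)$y
}

radius_for_sa <- function(sa, complexity) {
  fill <- stats::approx(.fd_calib$complexity, .fd_calib$fill,
                        xout = complexity, rule = 2)$y
  clamp(sqrt(sa / fill), 0.35, 2.1)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic treat-and-extend cohort
#'
#' Draws baseline morphology per patient, couples it to a per-visit
#' Bernoulli activity process through a logistic latent drive, simulates
#' each patient's TAE schedule with [simulate_tae_course()], and builds
#' clinically coherent visit records (BCVA, central macular thickness,
#' fluid and hemorrhage flags, one injection per attended visit).
#' Imaging-visit assessments are produced at baseline, the 3-month visit
#' (one month after the last loading injection) and 12 months; when
#' `with_images = TRUE`, synthetic angiograms are generated at those
#' visits — two consecutive baseline acquisitions for repeatability, a
#' pruned tree after the loading dose, and a regrown lesion at 12 months.
#'
#' @param config a [cohort_config()].
#' @param with_images also rasterize per-assessment angiograms (slower).
#' @return An object of class `tae_cohort`: list with data.frames
#'   `patients` (baseline covariates, latent activity probability,
#'   injection count, completion flag), `visits` (one row per attended
#'   injection visit), `assessments` (imaging visits at weeks 0/12/52),
#'   `manifest` + `images` when requested, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), with_images = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  patients <- visits <- assess <- manifest <- list()
  images <- list()
  with_seed(cfg$seed, {
    fd0 <- rtruncnorm1(cfg$n_patients, cfg$fd_mean, cfg$fd_sd,
                       cfg$fd_range[1], cfg$fd_range[2])
    sa0 <- rlnorm(cfg$n_patients, cfg$sa_meanlog, cfg$sa_sdlog)
    sa0 <- clamp(sa0, 0.05, 6)
    drive <- cfg$alpha0 + cfg$beta_fd * (fd0 - cfg$fd_mean) +
      cfg$beta_logsa * (log(sa0) - cfg$sa_meanlog)
    p_act <- plogis(drive)
    bcva0 <- round(rtruncnorm1(cfg$n_patients, 62, 12, 20, 85))
    cmt0 <- round(rtruncnorm1(cfg$n_patients, 390, 116, 180, 800))
    dcmt_load <- rnorm(cfg$n_patients, 110, 90)      # CMT drop over loading
    resolved3 <- runif(cfg$n_patients) < plogis((dcmt_load - 130) / 40)
    gain_load <- rnorm(cfg$n_patients, 5, 6)         # letters by 3 months
    gain12 <- 0.9 * gain_load + rnorm(cfg$n_patients, 3, 4.5)
    dropout <- runif(cfg$n_patients) < cfg$dropout_rate
  })

  for (i in seq_len(cfg$n_patients)) {
    sd_i <- derive_seed(cfg$seed, i)
    course <- simulate_tae_course(
      activity_prob = make_activity_process(p_act[i], cfg$carryover, sd_i),
      protocol = cfg$protocol, horizon_weeks = cfg$horizon_weeks,
      seed = derive_seed(sd_i, 1))
    clin <- with_seed(derive_seed(sd_i, 2), {
      build_clinical_records(course, cfg, bcva0[i], cmt0[i], dcmt_load[i],
                             resolved3[i], gain_load[i], gain12[i],
                             p_act[i], dropout[i])
    })
    n_inj <- sum(clin$visits$week < cfg$horizon_weeks)
    pid <- sprintf("P%03d", i)
    clin$visits$patient_id <- pid
    clin$assessments$patient_id <- pid
    patients[[i]] <- data.frame(
      patient_id = pid, fd_baseline = fd0[i], sa_baseline = sa0[i],
      p_active = p_act[i], bcva_baseline = bcva0[i], cmt_baseline = cmt0[i],
      injection_count = n_inj, completed = !dropout[i])
    visits[[i]] <- clin$visits
    assess[[i]] <- clin$assessments

    if (with_images) {
      cx <- complexity_for_fd(fd0[i])
      rad <- radius_for_sa(sa0[i], cx)
      tree0 <- generate_vessel_tree(cx, field_mm = cfg$img_spec$field_mm,
                                    seed = derive_seed(sd_i, 3),
                                    radius_mm = rad)
      # anti-VEGF pruning: responders lose the two finest caliber levels,
      # the rest one; regrowth restores the lesion slightly enlarged
      cals <- sort(unique(tree0$segments$caliber_um))
      depth <- if (resolved3[i] || dcmt_load[i] > 100) 2L else 1L
      thr <- if (length(cals) > depth) cals[depth + 1L] else 0
      tree3 <- prune_tree(tree0, thr)
      tree12 <- generate_vessel_tree(cx, field_mm = cfg$img_spec$field_mm,
                                     seed = derive_seed(sd_i, 3),
                                     radius_mm = min(rad * 1.08, 2.1))
      img_set <- list(
        list(week = 0, acq = 1L, tree = tree0),
        list(week = 0, acq = 2L, tree = tree0),
        list(week = 12, acq = 1L, tree = tree3))
      if (!dropout[i]) img_set[[4]] <- list(week = 52, acq = 1L, tree = tree12)
      for (im in img_set) {
        img <- rasterize_tree(im$tree, cfg$img_spec,
                              seed = derive_seed(sd_i, 10L + im$acq +
                                                   as.integer(im$week)))
        img$meta$patient_id <- pid
        img$meta$visit_week <- im$week
        img$meta$acquisition <- im$acq
        images[[length(images) + 1L]] <- img
        manifest[[length(manifest) + 1L]] <-
          data.frame(patient_id = pid, visit_week = im$week,
                     acquisition = im$acq, image_index = length(images))
      }
    }
  }
  out <- list(patients = do.call(rbind, patients),
              visits = do.call(rbind, visits),
              assessments = do.call(rbind, assess),
              config = cfg)
  if (with_images) {
    out$images <- images
    out$manifest <- do.call(rbind, manifest)
  }
  class(out) <- "tae_cohort"
  out
}

# Per-visit activity process: constant logistic probability, optionally with
# a carry-over term added to the log-odds when the previous visit was active.
make_activity_process <- function(p, carryover, seed) {
  if (carryover == 0) return(p)
  base_logit <- qlogis(clamp(p, 1e-6, 1 - 1e-6))
  function(week, prev_active = FALSE) {
    plogis(base_logit + if (isTRUE(prev_active)) carryover else 0)
  }
}

# Build visit-level and assessment-level clinical records for one patient.
# Runs inside a seeded context.
build_clinical_records <- function(course, cfg, bcva0, cmt0, dcmt_load,
                                   resolved3, gain_load, gain12, p_act,
                                   dropout) {
  bcva_at <- function(w) {
    drift <- gain_load * pmin(w / 12, 1) +
      (gain12 - gain_load) * pmax(0, pmin((w - 12) / 40, 1))
    bcva0 + drift
  }
  cmt_at <- function(w) cmt0 - dcmt_load * pmin(w / 12, 1)
  mk_flags <- function(active, baseline = FALSE) {
    if (baseline) {
      srf <- runif(1) < 0.75; irf <- runif(1) < 0.5
      if (!srf && !irf) srf <- TRUE
      hem <- runif(1) < 0.05
    } else if (active) {
      srf <- runif(1) < 0.65; irf <- runif(1) < 0.45
      hem <- runif(1) < 0.04
      if (!srf && !irf && !hem) srf <- TRUE
    } else {
      srf <- runif(1) < 0.10; irf <- runif(1) < 0.05; hem <- FALSE
    }
    c(irf = irf, srf = srf, hem = hem)
  }
  vis <- course
  n <- nrow(vis)
  rec <- vector("list", n)
  for (j in seq_len(n)) {
    w <- vis$week[j]
    baseline <- w == 0
    act <- vis$active[j] || baseline         # disease is active at diagnosis
    fl <- mk_flags(act, baseline = baseline)
    fluid_bump <- if (fl["irf"] || fl["srf"]) runif(1, 30, 80) else 0
    act_drop <- if (act && !baseline) runif(1, 2, 8) else 0
    rec[[j]] <- data.frame(
      week = w, phase = vis$phase[j],
      bcva_letters = clamp(round(bcva_at(w) - act_drop +
                                   rnorm(1, 0, cfg$bcva_noise_sd)), 0, 100),
      cmt_um = round(cmt_at(w) + fluid_bump + rnorm(1, 0, 15)),
      irf = unname(fl["irf"]), srf = unname(fl["srf"]),
      hemorrhage = unname(fl["hem"]),
      active = act, injection = TRUE)
  }
  visits <- do.call(rbind, rec)
  if (dropout) {
    cutoff <- runif(1, 12, cfg$horizon_weeks)
    visits <- visits[visits$week <= cutoff, , drop = FALSE]
  }

  # imaging assessments at baseline, 3 months (week 12), 12 months (week 52)
  mk_assess <- function(w, active, baseline = FALSE) {
    fl <- mk_flags(active, baseline = baseline)
    fluid_bump <- if (fl["irf"] || fl["srf"]) runif(1, 30, 80) else 0
    data.frame(week = w,
               bcva_letters = clamp(round(bcva_at(w) +
                                            rnorm(1, 0, cfg$bcva_noise_sd)),
                                    0, 100),
               cmt_um = round(cmt_at(w) + fluid_bump + rnorm(1, 0, 15)),
               irf = unname(fl["irf"]), srf = unname(fl["srf"]),
               hemorrhage = unname(fl["hem"]))
  }
  a0 <- mk_assess(0, TRUE, baseline = TRUE)
  a3 <- mk_assess(12, !resolved3)
  if (resolved3) { a3$irf <- FALSE; a3$srf <- FALSE }  # full resolution
  assessments <- rbind(a0, a3,
                       if (!dropout) mk_assess(52, runif(1) < p_act))
  list(visits = visits, assessments = assessments)
}

#' @export
print.tae_cohort <- function(x, ...) {
  cat(sprintf("<tae_cohort> %d patients, %d visits, median injections %.0f%s\n",
              nrow(x$patients), nrow(x$visits),
              median(x$patients$injection_count),
              if (!is.null(x$images)) sprintf(", %d images", length(x$images))
              else ""))
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Emits the patients and visits tables (and the image manifest when
#' present) as UTF-8 CSVs with a header row.
#'
#' @param cohort a `tae_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tae_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             visits = file.path(dir, "visits.csv"),
             assessments = file.path(dir, "assessments.csv"))
  write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  write.csv(cohort$assessments, paths["assessments"], row.names = FALSE)
  invisible(paths)
}
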