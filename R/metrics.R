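#' Blood-flow surface area
#'
#' Physical area of the binarized flow signal: number of flow pixels times
#' the squared pixel pitch.
#'
#' @param mask a `binary_flow_mask`.
#' @return Area in mm^2 (0 for an empty mask).
#' @export
surface_area <- function(mask) {
  stopifnot(inherits(mask, "binary_flow_mask"))
  sum(mask$mask) * mask$pixel_pitch_mm^2
}

#' Vessel density within the lesion region
#'
#' Fraction of the delineated lesion region (by default the convex hull of
#' the flow) occupied by flow pixels.
#'
#' @param mask a `binary_flow_mask` of the flow.
#' @param region a `binary_flow_mask` of the analysis region; must be
#'   non-empty.
#' @return A fraction in (0, 1\] (0 if the flow mask is empty).
#' @export
vessel_density <- function(mask, region) {
  stopifnot(inherits(mask, "binary_flow_mask"),
            inherits(region, "binary_flow_mask"))
  denom <- sum(region$mask)
  if (denom == 0L) stop("empty lesion region: vessel density undefined",
                        call. = FALSE)
  sum(mask$mask & region$mask) / denom
}

#' Quantify a CNV lesion on an en-face angiogram
#'
#' Runs the full biomarker pipeline: flow binarization, lesion delineation,
#' skeletonization, multi-origin box counting, and computes the four
#' biomarkers — fractal dimension (FD), lacunarity (LAC), blood-flow
#' surface area (SA, mm^2) and vessel density (VD). When no lesion is
#' detected a flagged record with SA = 0 and undefined FD/LAC/VD is
#' returned rather than an error.
#'
#' @param img an `enface_angiogram`.
#' @param binarize_options named list passed to [binarize_flow()].
#' @param n_origins grid origins per box size for [box_count_multi_origin()].
#' @param envelope_px satellite-envelope radius for [delineate_lesion()].
#' @param keep_intermediates keep the masks and box-count curve in the
#'   result.
#' @return A list of class `lesion_metrics`: `fd`, `n0`, `lac`, `sa_mm2`,
#'   `vd`, `fit_r2`, `fd_spread`, `n_components`, `flags` (character
#'   vector, e.g. `"empty_lesion"`, `"fd_clipped"`), plus `intermediates`
#'   when requested.
#' @export
quantify_lesion <- function(img, binarize_options = list(), n_origins = 4L,
                            envelope_px = 20L, keep_intermediates = FALSE) {
  stopifnot(inherits(img, "enface_angiogram"))
  flow <- do.call(binarize_flow, c(list(img), binarize_options))
  les <- delineate_lesion(flow, envelope_px = envelope_px)
  flags <- character()
  if (les$empty || !any(les$mask$mask)) {
    out <- list(fd = NA_real_, n0 = NA_real_, lac = NA_real_, sa_mm2 = 0,
                vd = NA_real_, fit_r2 = NA_real_, fd_spread = NA_real_,
                n_components = 0L, flags = "empty_lesion")
    class(out) <- "lesion_metrics"
    return(out)
  }
  skel <- skeletonize_mask(les$mask)
  curve <- box_count_multi_origin(skel, n_origins = n_origins)
  fd <- estimate_fractal_dimension(curve)
  if (fd$clipped) flags <- c(flags, "fd_clipped")
  lac <- estimate_lacunarity(curve)
  out <- list(fd = fd$fd, n0 = fd$n0, lac = lac,
              sa_mm2 = surface_area(les$mask),
              vd = vessel_density(les$mask, les$region),
              fit_r2 = fd$r_squared, fd_spread = fd$fd_spread,
              n_components = les$n_components, flags = flags)
  if (keep_intermediates)
    out$intermediates <- list(flow = flow, lesion = les, skeleton = skel,
                              curve = curve)
  class(out) <- "lesion_metrics"
  out
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("<lesion_metrics> FD %.3f  LAC %.3f  SA %.3f mm2  VD %.3f%s\n",
              x$fd, x$lac, x$sa_mm2, x$vd,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

# one-row data.frame view used by the pipeline writers
metrics_row <- function(m, patient_id = NA, visit_week = NA, acquisition = 1L) {
  data.frame(patient_id = patient_id, visit_week = visit_week,
             acquisition = acquisition,
             fd = m$fd, n0 = m$n0, lac = m$lac, sa_mm2 = m$sa_mm2, vd = m$vd,
             fit_r2 = m$fit_r2, fd_spread = m$fd_spread,
             n_components = m$n_components,
             flags = paste(m$flags, collapse = ";"))
}
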