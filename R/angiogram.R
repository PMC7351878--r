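#' Specification of a synthetic en-face angiogram raster
#'
#' @param width_px,height_px image size in pixels; square images of at least
#'   64 px are required (default 320, the native grid of a 4.5 mm swept-source
#'   en-face scan).
#' @param field_mm physical side length covered by the image (default 4.5 mm).
#' @param noise_level speckle noise amplitude as a fraction of the dynamic
#'   range, in \[0, 1).
#' @param background_level background flow signal as a fraction of the
#'   dynamic range.
#' @param bit_depth 8 or 16.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width_px = 320L, height_px = width_px, field_mm = 4.5,
                       noise_level = 0.05, background_level = 0.08,
                       bit_depth = 8L) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px != height_px || width_px < 64L)
    stop("images must be square with side >= 64 px", call. = FALSE)
  if (field_mm <= 0) stop("`field_mm` must be positive", call. = FALSE)
  if (noise_level < 0 || noise_level >= 1)
    stop("`noise_level` must lie in [0, 1)", call. = FALSE)
  if (background_level < 0 || background_level >= 1)
    stop("`background_level` must lie in [0, 1)", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 field_mm = field_mm, noise_level = noise_level,
                 background_level = background_level,
                 bit_depth = as.integer(bit_depth)),
            class = "image_spec")
}

#' Construct an en-face angiogram object
#'
#' @param pixels integer matrix of non-negative intensities (rows = image
#'   rows, top-left origin).
#' @param pixel_pitch_mm physical size of one pixel (mm).
#' @param bit_depth 8 or 16.
#' @param meta optional named list (patient id, visit week, eye, ...).
#' @return An object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(pixels, pixel_pitch_mm, bit_depth = 8L,
                             meta = list()) {
  if (!is.matrix(pixels) || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (any(pixels < 0)) stop("pixel intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("`pixel_pitch_mm` must be positive", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_pitch_mm = pixel_pitch_mm,
                 bit_depth = as.integer(bit_depth), meta = meta),
            class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %d x %d px, pitch %.4f mm (%.2f mm field), %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_mm,
              x$pixel_pitch_mm * ncol(x$pixels), x$bit_depth))
  invisible(x)
}

#' Rasterize a vessel tree into a synthetic angiogram
#'
#' Draws every segment as an anti-aliased stroke of width
#' `caliber / pixel pitch` (with an 18-um physical floor so the finest
#' capillaries stay resolvable, as they are on real flow images),
#' composites strokes by maximum coverage, adds multiplicative plus
#' additive speckle at the spec's `noise_level`, and quantizes to the
#' requested bit depth.
#'
#' @param tree a `vessel_tree` whose coordinates lie within the field.
#' @param spec an `image_spec`; its `field_mm` must match the tree's.
#' @param seed RNG seed for the speckle noise; the noise-free geometry is
#'   seed-independent.
#' @return An `enface_angiogram`.
#' @export
rasterize_tree <- function(tree, spec = image_spec(), seed = 1) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(spec, "image_spec"))
  if (abs(tree$field_mm - spec$field_mm) > 1e-9)
    stop("tree and image spec cover different fields", call. = FALSE)
  seg <- tree$segments
  if (nrow(seg) > 0L) {
    xy <- c(seg$x0, seg$x1, seg$y0, seg$y1)
    if (any(xy < 0) || any(xy > spec$field_mm))
      stop("tree coordinates fall outside the field", call. = FALSE)
  }
  W <- spec$width_px; H <- spec$height_px
  pitch <- spec$field_mm / W
  cov <- matrix(0, nrow = H, ncol = W)
  if (nrow(seg) > 0L) {
    # pixel centers: column j spans x in [(j-1)*pitch, j*pitch)
    px_of <- function(mm) mm / pitch + 0.5  # 1-based pixel-center coordinate
    for (i in seq_len(nrow(seg))) {
      # render at least an 18-um stroke (the OCT-A flow signal broadens the
      # finest capillaries to the resolution limit); a physical floor keeps
      # the drawn area independent of the raster resolution
      w <- max(seg$caliber_um[i], 18) / 1000 / pitch
      x0 <- px_of(seg$x0[i]); y0 <- px_of(seg$y0[i])
      x1 <- px_of(seg$x1[i]); y1 <- px_of(seg$y1[i])
      pad <- w / 2 + 1.5
      cl <- max(1L, floor(min(x0, x1) - pad)); cr <- min(W, ceiling(max(x0, x1) + pad))
      rt <- max(1L, floor(min(y0, y1) - pad)); rb <- min(H, ceiling(max(y0, y1) + pad))
      if (cl > cr || rt > rb) next
      cx <- cl:cr; ry <- rt:rb
      dx <- x1 - x0; dy <- y1 - y0
      len2 <- dx * dx + dy * dy
      PX <- matrix(cx, nrow = length(ry), ncol = length(cx), byrow = TRUE)
      PY <- matrix(ry, nrow = length(ry), ncol = length(cx))
      if (len2 < 1e-12) {
        d <- sqrt((PX - x0)^2 + (PY - y0)^2)
      } else {
        t <- clamp(((PX - x0) * dx + (PY - y0) * dy) / len2, 0, 1)
        d <- sqrt((PX - (x0 + t * dx))^2 + (PY - (y0 + t * dy))^2)
      }
      a <- clamp(w / 2 + 0.5 - d, 0, 1)   # anti-aliased stroke coverage
      cov[ry, cx] <- pmax(cov[ry, cx], a)
    }
  }
  signal <- 0.85
  img <- spec$background_level + (signal - spec$background_level) * cov
  img <- with_seed(seed, {
    n <- spec$noise_level
    if (n > 0) {
      img <- img * (1 + n * matrix(rnorm(H * W), H, W)) +
        0.35 * n * abs(matrix(rnorm(H * W), H, W))
    }
    img
  })
  maxv <- 2^spec$bit_depth - 1
  enface_angiogram(matrix(as.integer(round(clamp(img, 0, 1) * maxv)), H, W),
                   pixel_pitch_mm = pitch, bit_depth = spec$bit_depth,
                   meta = list(seed = as.integer(seed),
                               complexity = tree$complexity))
}

#' Read and write grayscale angiograms
#'
#' `write_angiogram()` stores an angiogram as an 8/16-bit grayscale TIFF or
#' PNG depending on the file extension; `read_angiogram()` loads one back,
#' attaching the physical field size (sidecar metadata is not stored in the
#' raster formats).
#'
#' @param img an `enface_angiogram`.
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param field_mm physical side length of the imaged field (mm).
#' @param meta optional metadata list attached on read.
#' @return `read_angiogram()` returns an `enface_angiogram`;
#'   `write_angiogram()` invisibly returns `path`.
#' @export
write_angiogram <- function(img, path) {
  stopifnot(inherits(img, "enface_angiogram"))
  maxv <- 2^img$bit_depth - 1
  m <- img$pixels / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_angiogram
#' @export
read_angiogram <- function(path, field_mm = 4.5, meta = list()) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]   # collapse grayscale channels
  bit_depth <- 8L
  enface_angiogram(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
                   pixel_pitch_mm = field_mm / ncol(m),
                   bit_depth = bit_depth, meta = meta)
}
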