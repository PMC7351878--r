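#' Reference binary patterns of known fractal dimension
#'
#' Generators for patterns whose box-counting dimension is known in closed
#' form, used to calibrate the FD estimator: a straight line (dimension 1),
#' the Koch curve (log 4 / log 3 ~ 1.2619), the Sierpinski triangle
#' (log 3 / log 2 ~ 1.5850) and a filled square (dimension 2).
#'
#' `koch_curve_mask()` rasterizes the order-n Koch polyline at one pixel per
#' smallest segment step; `sierpinski_mask()` uses the exact binary
#' construction on a `2^order` grid (a pixel is set when its row and column
#' indices share no set bit), which is self-similar by construction.
#'
#' @param order recursion depth.
#' @param width image side (line/square) in pixels.
#' @return A logical matrix.
#' @export
line_mask <- function(width = 512L) {
  m <- matrix(FALSE, width, width)
  m[width %/% 2L, ] <- TRUE
  m
}

#' @rdname line_mask
#' @export
filled_square_mask <- function(width = 256L) {
  matrix(TRUE, width, width)
}

#' @rdname line_mask
#' @export
sierpinski_mask <- function(order = 7L) {
  n <- 2L^as.integer(order)
  i <- rep(0:(n - 1L), times = n)
  j <- rep(0:(n - 1L), each = n)
  matrix(bitwAnd(i, j) == 0L, n, n)
}

#' @rdname line_mask
#' @export
koch_curve_mask <- function(order = 5L) {
  # build the polyline by the L-system F -> F+F--F+F (60-degree turns);
  # `turns` holds the turn (in units of 60 degrees) taken before each segment
  turns <- 0L
  for (k in seq_len(order)) {
    out <- integer(0)
    for (t in turns) out <- c(out, t, 1L, -2L, 1L)
    turns <- out
  }
  n_seg <- length(turns)                      # 4^order segments
  ang <- cumsum(turns) * pi / 3
  step <- 1
  xs <- cumsum(c(0, step * cos(ang)))
  ys <- cumsum(c(0, step * sin(ang)))
  # scale to ~3 px per smallest segment and rasterize by dense sampling
  scale <- 3
  xs <- xs * scale; ys <- ys * scale
  W <- ceiling(max(xs) - min(xs)) + 9L
  H <- ceiling(max(ys) - min(ys)) + 9L
  xs <- xs - min(xs) + 5; ys <- ys - min(ys) + 5
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_seg)) {
    t <- seq(0, 1, length.out = 8L)
    px <- round(xs[i] + t * (xs[i + 1] - xs[i]))
    py <- round(ys[i] + t * (ys[i + 1] - ys[i]))
    m[cbind(py + 1L, px + 1L)] <- TRUE
  }
  m
}
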