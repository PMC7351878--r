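#' Skeletonize a binary flow mask
#'
#' Reduces the flow mask to one-pixel-wide medial centerlines with
#' Zhang-Suen parallel thinning. The skeleton is a subset of the mask and
#' preserves the number of 8-connected components, so network topology
#' survives the reduction.
#'
#' @param flow a `binary_flow_mask` (or plain logical matrix).
#' @param pixel_pitch_mm required when `flow` is a plain matrix.
#' @return A `skeleton_mask`.
#' @export
skeletonize_mask <- function(flow, pixel_pitch_mm = NULL) {
  if (inherits(flow, "binary_flow_mask")) {
    m <- flow$mask; pitch <- flow$pixel_pitch_mm
  } else {
    m <- mask_matrix(flow)
    pitch <- pixel_pitch_mm %||% stop("`pixel_pitch_mm` required", call. = FALSE)
  }
  skeleton_mask(thin_zhang_suen(m), pitch)
}

# Zhang-Suen thinning on a logical matrix, implemented with whole-matrix
# shifts; the two subiterations alternate until no pixel changes.
thin_zhang_suen <- function(m) {
  if (!any(m)) return(m)
  H <- nrow(m); W <- ncol(m)
  # pad with FALSE so neighbor shifts never wrap
  P <- matrix(FALSE, H + 2L, W + 2L)
  P[2:(H + 1L), 2:(W + 1L)] <- m
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    rs <- (1L + max(0L, dr)):(nrow(x) + min(0L, dr))
    cs <- (1L + max(0L, dc)):(ncol(x) + min(0L, dc))
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      p2 <- shift(P, 1L, 0L);  p3 <- shift(P, 1L, -1L)
      p4 <- shift(P, 0L, -1L); p5 <- shift(P, -1L, -1L)
      p6 <- shift(P, -1L, 0L); p7 <- shift(P, -1L, 1L)
      p8 <- shift(P, 0L, 1L);  p9 <- shift(P, 1L, 1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- P & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { P <- P & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  P[2:(H + 1L), 2:(W + 1L)]
}

# 8-connected component labelling: 4-connected labels from EBImage::bwlabel,
# then diagonal-neighbor label pairs merged with union-find.
label_components <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # \ diagonal
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# number of 8-connected components of a logical matrix
count_components <- function(m) {
  if (!any(m)) return(0L)
  max(label_components(m))
}
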