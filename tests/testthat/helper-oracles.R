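# Independent oracles used across tests. These deliberately avoid the
# package's vectorized implementations: counts are accumulated pixel by
# pixel with scalar arithmetic, and exact test distributions are built by
# explicit enumeration.

# Occupied-box count and per-box masses for one box size and origin offset,
# by scalar per-pixel accumulation over the image-anchored toroidal grid.
brute_box_count <- function(mask, R, ox, oy) {
  H <- nrow(mask); W <- ncol(mask)
  n_by <- ceiling(H / R); n_bx <- ceiling(W / R)
  counts <- matrix(0L, n_by, n_bx)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c]) {
      bi <- (((r - 1) + oy) %/% R) %% n_by
      bj <- (((c - 1) + ox) %/% R) %% n_bx
      counts[bi + 1L, bj + 1L] <- counts[bi + 1L, bj + 1L] + 1L
    }
  }
  counts
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments under the null.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# AUC by explicit concordant-pair counting (ties count half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  conc / (length(pos) * length(neg))
}

# 8-connected component count by scalar flood fill (for small fixtures)
count8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (m[r0, c0] && !seen[r0, c0]) {
      n <- n + 1L
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  n
}

# a hand-buildable vessel tree for fixture tests
manual_tree <- function(segments, field_mm = 4.5) {
  structure(list(segments = segments,
                 root_xy = c(segments$x0[1], segments$y0[1]),
                 field_mm = field_mm, complexity = NA_real_, seed = 0L),
            class = "vessel_tree")
}
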