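#' Generate a synthetic CNV vessel tree
#'
#' Grows a branching vascular network by recursive stochastic branching, the
#' qualitative anatomy of a choroidal neovascular membrane: a central feeder
#' trunk from which finer capillaries ramify. The single `complexity` knob
#' controls branching probability, terminal density and depth, so that the
#' fractal dimension of the rasterized tree rises monotonically with it.
#'
#' @param complexity scalar in \[0, 1\]; 0 gives a single unbranched trunk
#'   chain, values near 1 give densely branched networks with short terminal
#'   twigs.
#' @param field_mm physical side length of the square field the lesion must
#'   fit in (default 4.5 mm, the en-face scan size).
#' @param seed integer RNG seed; the tree is a deterministic function of
#'   `(complexity, field_mm, seed)` and the optional shape arguments.
#' @param radius_mm maximum lesion radius from the root (default 1.1 mm);
#'   scales the overall footprint and hence the blood-flow surface area.
#' @param root_caliber_um caliber of the generation-0 trunk in micrometers.
#' @param caliber_decay multiplicative caliber loss per generation; must be
#'   in (0, 1) so caliber strictly decreases with generation.
#' @param min_caliber_um growth stops once a branch would fall below this
#'   caliber.
#' @param max_length_mm growth stops once the summed centerline length
#'   reaches this budget; normalizes space-filling across complexities.
#'   The default `165 * radius_mm^2` keeps the fill factor (and hence the
#'   measured FD at a given complexity) roughly independent of lesion size.
#' @param max_segments hard safety cap on the number of segments.
#'
#' @return An object of class `vessel_tree`: a list with
#'   \describe{
#'     \item{segments}{data.frame with columns `id`, `parent` (0 for the first
#'       segment), `x0`, `y0`, `x1`, `y1` (mm), `caliber_um`, `generation`.}
#'     \item{root_xy}{mm coordinates of the root.}
#'     \item{field_mm, complexity, seed}{generation parameters.}
#'   }
#'   Every non-root segment starts where its parent ends, so the tree is
#'   connected by construction.
#' @export
#' @examples
#' tr <- generate_vessel_tree(0.6, seed = 1)
#' nrow(tr$segments)
generate_vessel_tree <- function(complexity, field_mm = 4.5, seed = 1,
                                 radius_mm = 1.1, root_caliber_um = 60,
                                 caliber_decay = 0.85, min_caliber_um = 6,
                                 max_length_mm = NULL, max_segments = 8000) {
  if (!is.numeric(complexity) || length(complexity) != 1L ||
      is.na(complexity) || complexity < 0 || complexity > 1)
    stop("`complexity` must be a single number in [0, 1]", call. = FALSE)
  if (field_mm <= 0) stop("`field_mm` must be positive", call. = FALSE)
  if (caliber_decay <= 0 || caliber_decay >= 1)
    stop("`caliber_decay` must be in (0, 1)", call. = FALSE)
  radius_mm <- min(radius_mm, 0.48 * field_mm)
  if (is.null(max_length_mm)) max_length_mm <- 165 * radius_mm^2

  p_branch <- 0.80 * complexity^0.6
  step_mm  <- 0.22    # terminal segments shorten via per-generation decay
  max_gen  <- if (complexity == 0) 0L else 2L + ceiling(9 * complexity)
  p_stop   <- 0.05 - 0.02 * complexity           # per-step chain termination

  root <- c(field_mm / 2, field_mm / 2)

  with_seed(seed, {
    n_alloc <- max_segments
    s_parent <- integer(n_alloc)
    s_x0 <- s_y0 <- s_x1 <- s_y1 <- s_cal <- numeric(n_alloc)
    s_gen <- integer(n_alloc)
    n_seg <- 0L
    add_segment <- function(parent, p0, p1, caliber, gen) {
      n_seg <<- n_seg + 1L
      s_parent[n_seg] <<- parent
      s_x0[n_seg] <<- p0[1]; s_y0[n_seg] <<- p0[2]
      s_x1[n_seg] <<- p1[1]; s_y1[n_seg] <<- p1[2]
      s_cal[n_seg] <<- caliber; s_gen[n_seg] <<- gen
      n_seg
    }

    # active tips: list of (segment id, position, direction, caliber, gen,
    # steps taken along current chain)
    dir0 <- runif(1, 0, 2 * pi)
    tips <- list(list(id = 0L, pos = root, dir = dir0,
                      caliber = root_caliber_um, gen = 0L, steps = 0L))
    # a second trunk arm in the opposite direction keeps the root central
    tips[[2]] <- list(id = 0L, pos = root, dir = dir0 + pi,
                      caliber = root_caliber_um, gen = 0L, steps = 0L)

    max_chain <- ceiling(radius_mm / step_mm) + 2L
    total_len <- 0
    while (length(tips) > 0L && n_seg < max_segments &&
           total_len < max_length_mm) {
      tip <- tips[[1]]; tips <- tips[-1]
      if (tip$caliber < min_caliber_um) next
      len <- step_mm * 0.92^tip$gen * runif(1, 0.7, 1.3)
      len <- max(len, 0.04)
      turn <- rnorm(1, 0, 0.20 + 0.15 * complexity)
      ndir <- tip$dir + turn
      npos <- tip$pos + len * c(cos(ndir), sin(ndir))
      if (sqrt(sum((npos - root)^2)) > radius_mm) {
        # deflect inward once (peripheral arcades) instead of dying outright
        ndir <- atan2(root[2] - tip$pos[2], root[1] - tip$pos[1]) +
          rnorm(1, 0, 0.6)
        npos <- tip$pos + len * c(cos(ndir), sin(ndir))
        if (sqrt(sum((npos - root)^2)) > radius_mm) next
      }
      id <- add_segment(tip$id, tip$pos, npos, tip$caliber, tip$gen)
      total_len <- total_len + len
      branch <- tip$gen < max_gen && runif(1) < p_branch
      if (branch) {
        spread <- runif(1, 0.35, 0.75)
        child_cal <- tip$caliber * caliber_decay
        for (s in c(-1, 1)) {
          tips[[length(tips) + 1L]] <-
            list(id = id, pos = npos, dir = ndir + s * spread,
                 caliber = child_cal, gen = tip$gen + 1L, steps = 0L)
        }
      } else if (tip$steps + 1L < max_chain && runif(1) > p_stop) {
        tips[[length(tips) + 1L]] <-
          list(id = id, pos = npos, dir = ndir, caliber = tip$caliber,
               gen = tip$gen, steps = tip$steps + 1L)
      }
    }
    i <- seq_len(n_seg)
    seg <- data.frame(id = i, parent = s_parent[i],
                      x0 = s_x0[i], y0 = s_y0[i], x1 = s_x1[i], y1 = s_y1[i],
                      caliber_um = s_cal[i], generation = s_gen[i])
    structure(list(segments = seg, root_xy = root, field_mm = field_mm,
                   complexity = complexity, seed = as.integer(seed)),
              class = "vessel_tree")
  })
}

#' Prune the fine vessels of a tree
#'
#' Removes every non-trunk segment whose caliber falls below a threshold,
#' together with all its descendants, emulating the pruning effect of
#' anti-VEGF on the tiny peripheral capillaries of a CNV while the central
#' feeder trunk persists. The generation-0 trunk is always retained, so the
#' result is a connected tree with the same root.
#'
#' @param tree a `vessel_tree`.
#' @param caliber_threshold_um non-negative caliber cutoff in micrometers;
#'   `0` leaves the tree unchanged, `Inf` reduces it to the trunk.
#' @return A `vessel_tree` with the surviving segments.
#' @export
prune_tree <- function(tree, caliber_threshold_um) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (!is.numeric(caliber_threshold_um) || length(caliber_threshold_um) != 1L ||
      is.na(caliber_threshold_um) || caliber_threshold_um < 0)
    stop("`caliber_threshold_um` must be a single non-negative number",
         call. = FALSE)
  seg <- tree$segments
  if (nrow(seg) == 0L) return(tree)
  keep <- seg$generation == 0L | seg$caliber_um >= caliber_threshold_um
  # drop descendants of removed segments; parents always have smaller ids
  for (i in seq_len(nrow(seg))) {
    p <- seg$parent[i]
    if (p > 0L && !keep[p]) keep[i] <- FALSE
  }
  out <- tree
  out$segments <- seg[keep, , drop = FALSE]
  rownames(out$segments) <- NULL
  out
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, %d generations, complexity %.2f, seed %d\n",
              nrow(x$segments),
              if (nrow(x$segments)) max(x$segments$generation) + 1L else 0L,
              x$complexity, x$seed))
  invisible(x)
}
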