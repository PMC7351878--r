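#' Treat-and-extend protocol parameters
#'
#' Dosing schedule of an anti-VEGF treat-and-extend (TAE) regimen: a
#' loading phase of three monthly injections, then visits whose spacing is
#' lengthened by `step_weeks` after an inactive visit and shortened by the
#' same step after an active one, clamped to `[floor_weeks, cap_weeks]`. An
#' injection is given at every visit regardless of activity.
#'
#' The defaults (loading at weeks 0/4/8, first post-loading interval 8
#' weeks, step 2, floor 4, cap 12) make a patient who never shows activity
#' attend weeks 0, 4, 8, 16, 26, 38, 50 — seven injections in the first
#' year — while a patient active at every visit receives twelve, matching
#' the spread observed under this regimen in clinical practice.
#'
#' @param loading_weeks weeks of the loading-phase injections.
#' @param initial_interval_weeks interval from the last loading injection
#'   to the first TAE visit.
#' @param step_weeks extension/shortening step (> 0).
#' @param floor_weeks,cap_weeks clamp bounds for the interval.
#' @return An object of class `tae_protocol`.
#' @export
tae_protocol <- function(loading_weeks = c(0, 4, 8),
                         initial_interval_weeks = 8,
                         step_weeks = 2, floor_weeks = 4, cap_weeks = 12) {
  if (step_weeks <= 0) stop("`step_weeks` must be positive", call. = FALSE)
  if (!(floor_weeks <= initial_interval_weeks &&
        initial_interval_weeks <= cap_weeks))
    stop("protocol requires floor <= initial interval <= cap", call. = FALSE)
  if (is.unsorted(loading_weeks, strictly = TRUE))
    stop("`loading_weeks` must be strictly increasing", call. = FALSE)
  structure(list(loading_weeks = loading_weeks,
                 initial_interval_weeks = initial_interval_weeks,
                 step_weeks = step_weeks, floor_weeks = floor_weeks,
                 cap_weeks = cap_weeks),
            class = "tae_protocol")
}

#' Simulate one patient's treat-and-extend visit schedule
#'
#' Plays the TAE state machine forward: loading injections at the protocol
#' cadence, then visits spaced by an interval that extends by one step
#' after each inactive visit and shortens by one step after each active
#' one, clamped to the protocol bounds. Activity at each visit is drawn as
#' a Bernoulli event with probability `activity_prob(week)`. An injection
#' is recorded at every visit.
#'
#' @param activity_prob a single probability, a function of the visit week,
#'   or a function `(week, prev_active)` (enabling serial correlation)
#'   returning the probability that CNV activity is present.
#' @param protocol a [tae_protocol()].
#' @param horizon_weeks follow-up span; must cover the loading phase.
#' @param seed RNG seed for the activity draws.
#' @return A data.frame with one row per visit: `week`, `phase`
#'   (`"loading"`/`"tae"`), `active`, `injection` (always TRUE),
#'   `next_interval_weeks` (NA after the last visit inside the horizon).
#' @export
simulate_tae_course <- function(activity_prob, protocol = tae_protocol(),
                                horizon_weeks = 52, seed = 1) {
  stopifnot(inherits(protocol, "tae_protocol"))
  if (horizon_weeks < max(protocol$loading_weeks))
    stop("`horizon_weeks` must cover the loading phase", call. = FALSE)
  pfun <- if (!is.function(activity_prob)) function(week) activity_prob
          else activity_prob
  takes_prev <- length(formals(pfun)) >= 2L
  with_seed(seed, {
    weeks <- phases <- active <- list()
    interval <- protocol$initial_interval_weeks
    week <- NULL
    n <- 0L
    add_visit <- function(w, phase) {
      prev <- if (n > 0L) active[[n]] else FALSE
      n <<- n + 1L
      p <- if (takes_prev) pfun(w, prev) else pfun(w)
      if (!is.finite(p) || p < 0 || p > 1)
        stop("activity probability must lie in [0, 1]", call. = FALSE)
      weeks[[n]] <<- w; phases[[n]] <<- phase
      active[[n]] <<- runif(1) < p
    }
    for (w in protocol$loading_weeks) add_visit(w, "loading")
    week <- protocol$loading_weeks[length(protocol$loading_weeks)] + interval
    while (week <= horizon_weeks) {
      add_visit(week, "tae")
      interval <- clamp(interval +
                          if (active[[n]]) -protocol$step_weeks
                          else protocol$step_weeks,
                        protocol$floor_weeks, protocol$cap_weeks)
      week <- week + interval
    }
    out <- data.frame(week = unlist(weeks), phase = unlist(phases),
                      active = unlist(active), injection = TRUE)
    out$next_interval_weeks <- c(diff(out$week), NA_real_)
    out
  })
}
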