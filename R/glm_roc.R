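#' ROC curve and AUC with DeLong confidence interval
#'
#' Discrimination of a binary outcome by a continuous score. The AUC is the
#' rank (Mann-Whitney) probability that a randomly chosen case scores above
#' a randomly chosen control, computed with the convention that cases are
#' expected to score higher (`direction = "<"` in pROC terms), so scores
#' anti-associated with the outcome give AUC below 0.5. The confidence
#' interval is DeLong's. The qualitative band follows the usual reading:
#' above 0.80 very good, 0.70-0.80 good, 0.50-0.70 weak.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (0/1, logical, or two-level factor).
#' @param conf_level confidence level.
#' @return An object of class `roc_result`: `auc`, `conf_low`, `conf_high`,
#'   `band`, and `curve` (data.frame of specificity/sensitivity points).
#' @export
roc_curve_auc <- function(scores, labels, conf_level = 0.95) {
  lab <- as_binary_label(labels)
  if (length(unique(lab)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  r <- pROC::roc(response = lab, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  band <- if (auc > 0.8) "very good" else if (auc >= 0.7) "good"
          else if (auc >= 0.5) "weak" else "inverse"
  structure(list(auc = auc, conf_low = ci[1], conf_high = ci[3],
                 band = band,
                 curve = data.frame(specificity = r$specificities,
                                    sensitivity = r$sensitivities),
                 n = c(controls = sum(lab == 0), cases = sum(lab == 1))),
            class = "roc_result")
}

as_binary_label <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) > 2L) stop("outcome must be binary", call. = FALSE)
    as.integer(as.character(labels) == lev[length(lev)])
  } else as.integer(as.logical(labels))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %s discriminative ability\n",
              x$auc, x$conf_low, x$conf_high, x$band))
  invisible(x)
}

#' Binary-outcome generalized linear model with odds ratio and partial effect
#'
#' Logistic regression of a binary outcome on a single predictor. With
#' `smooth_df = 1` the predictor enters linearly and the odds ratio per
#' `unit_scale` units is reported with its Wald interval. With
#' `smooth_df > 1` the predictor enters through a natural (restricted)
#' cubic spline basis and the partial log-odds function — the fitted
#' log-odds relative to the median predictor value, with pointwise Wald
#' bands — is returned for plotting; the linear odds ratio is then refit
#' separately so both presentations are available. Discrimination of the
#' fitted probabilities is summarized by [roc_curve_auc()].
#'
#' @param x numeric predictor.
#' @param y binary outcome.
#' @param unit_scale predictor units per reported odds ratio (e.g. `0.01`
#'   reports the OR per 0.01 FD units).
#' @param smooth_df spline degrees of freedom (1 = linear logit).
#' @param grid_n points of the partial-function grid.
#' @param conf_level confidence level.
#' @return An object of class `glm_fit`: `coefficients` (data.frame),
#'   `odds_ratio`, `or_conf_low`, `or_conf_high`, `unit_scale`, `auc`
#'   (a `roc_result`), `partial` (data.frame `x`, `log_odds`, `conf_low`,
#'   `conf_high`), `separation` flag, `n`.
#' @export
fit_binary_glm <- function(x, y, unit_scale = 1, smooth_df = 1L,
                           grid_n = 100L, conf_level = 0.95) {
  lab <- as_binary_label(y)
  ok <- complete.cases(x, lab)
  x <- x[ok]; lab <- lab[ok]
  if (length(x) < 10L) stop("at least 10 observations required", call. = FALSE)
  if (length(unique(lab)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)

  lin <- glm(lab ~ x, family = binomial())
  beta <- coef(lin)[["x"]]
  se <- sqrt(vcov(lin)["x", "x"])
  separation <- !lin$converged || abs(beta) * sd(x) > 15
  or <- exp(beta * unit_scale)
  or_lo <- if (separation) 0 else exp((beta - z * se) * unit_scale)
  or_hi <- if (separation) Inf else exp((beta + z * se) * unit_scale)

  if (smooth_df > 1L) {
    basis <- splines::ns(x, df = smooth_df)
    fit <- glm(lab ~ basis, family = binomial())
    grid <- seq(min(x), max(x), length.out = grid_n)
    gb <- predict(basis, grid)
    ref <- predict(basis, median(x))
    # design difference versus the reference point; intercept cancels
    dd <- cbind(0, gb - matrix(ref, nrow(gb), ncol(gb), byrow = TRUE))
    eta <- as.vector(dd %*% coef(fit))
    se_eta <- sqrt(rowSums((dd %*% vcov(fit)) * dd))
    partial <- data.frame(x = grid, log_odds = eta,
                          conf_low = eta - z * se_eta,
                          conf_high = eta + z * se_eta)
    fitted_p <- fitted(fit)
  } else {
    grid <- seq(min(x), max(x), length.out = grid_n)
    eta <- beta * (grid - median(x))
    se_eta <- abs(grid - median(x)) * se
    partial <- data.frame(x = grid, log_odds = eta,
                          conf_low = eta - z * se_eta,
                          conf_high = eta + z * se_eta)
    fitted_p <- fitted(lin)
  }
  coefs <- data.frame(term = names(coef(lin)), estimate = unname(coef(lin)),
                      std_error = sqrt(diag(vcov(lin))))
  structure(list(coefficients = coefs, odds_ratio = or,
                 or_conf_low = or_lo, or_conf_high = or_hi,
                 unit_scale = unit_scale,
                 auc = roc_curve_auc(fitted_p, lab, conf_level),
                 partial = partial, separation = separation,
                 smooth_df = smooth_df, n = length(x)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("binary GLM (n = %d%s): OR per %g units = %.3f (95%% CI %.3f-%.3f)\n",
              x$n, if (x$smooth_df > 1) sprintf(", spline df %d", x$smooth_df)
                   else "",
              x$unit_scale, x$odds_ratio, x$or_conf_low, x$or_conf_high))
  if (x$separation) cat("  warning: quasi-separation; interval unbounded\n")
  print(x$auc)
  invisible(x)
}

#' Plot helpers for ROC curves and partial-effect functions
#'
#' Base-graphics renderings of a [roc_curve_auc()] result and of the
#' partial log-odds function of a [fit_binary_glm()] (solid estimate,
#' dashed pointwise confidence bands).
#'
#' @param x a `roc_result` or `glm_fit`.
#' @param xlab,ylab,main usual plot annotations.
#' @param ... passed to `plot()`.
#' @return Invisibly, `x`.
#' @export
plot.roc_result <- function(x, xlab = "False positive rate",
                            ylab = "Sensitivity", main = NULL, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  graphics::plot(1 - x$curve$specificity[o], x$curve$sensitivity[o],
                 type = "l", xlab = xlab, ylab = ylab,
                 main = main %||% sprintf("AUC = %.2f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @rdname plot.roc_result
#' @export
plot.glm_fit <- function(x, xlab = "predictor",
                         ylab = "partial log-odds", main = NULL, ...) {
  p <- x$partial
  graphics::plot(p$x, p$log_odds, type = "l",
                 ylim = range(p$conf_low, p$conf_high),
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(p$x, p$conf_low, lty = 2)
  graphics::lines(p$x, p$conf_high, lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
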