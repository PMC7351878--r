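#' Intraclass correlation for absolute agreement of repeated acquisitions
#'
#' Two-way mixed-effects, absolute-agreement, mean-of-k-raters intraclass
#' correlation — ICC(A,k) in the McGraw & Wong nomenclature — estimated
#' from the two-way ANOVA decomposition of an n-subjects-by-k-repeats
#' table:
#' \deqn{ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' where MS_R, MS_C and MS_E are the row (subject), column (acquisition)
#' and error mean squares. The confidence interval is obtained by the
#' F-based method for the single-rater coefficient and stepped up with the
#' Spearman-Brown relation.
#'
#' @param measurements numeric matrix or data.frame, one row per subject,
#'   one column per repeated acquisition (k = 2 for test-retest
#'   repeatability); no missing cells, at least 3 subjects.
#' @param conf_level confidence level of the interval.
#' @return An object of class `icc_result`: `estimate`, `conf_low`,
#'   `conf_high`, `model` descriptor, `n`, `k`, and the mean squares
#'   `ms_rows`, `ms_cols`, `ms_error`.
#' @export
icc_absolute_agreement <- function(measurements, conf_level = 0.95) {
  x <- as.matrix(measurements)
  if (any(is.na(x))) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("at least 3 subjects are required", call. = FALSE)
  if (k < 2L) stop("at least 2 repeats are required", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= 0 && ms_e <= 0 && ms_c <= 0)
    stop("zero variance: ICC undefined for constant data", call. = FALSE)
  icc_k <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  icc_1 <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)

  if (1 - icc_1 < 1e-12) {          # perfect agreement: degenerate interval
    return(structure(list(estimate = icc_k, conf_low = icc_k,
                          conf_high = icc_k,
                          model = sprintf(
                            "two-way mixed, absolute agreement, mean of k=%d", k),
                          n = n, k = k, ms_rows = ms_r, ms_cols = ms_c,
                          ms_error = ms_e, conf_level = conf_level),
                     class = "icc_result"))
  }
  # F-based interval for ICC(A,1) (McGraw & Wong), Spearman-Brown step-up
  alpha <- 1 - conf_level
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (ms_r - f_l * ms_e) /
    (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
  hi1 <- n * (f_u * ms_r - ms_e) /
    (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  structure(list(estimate = icc_k,
                 conf_low = min(sb(lo1), icc_k), conf_high = min(sb(hi1), 1),
                 model = sprintf(
                   "two-way mixed, absolute agreement, mean of k=%d", k),
                 n = n, k = k,
                 ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.4f (%d%% CI %.4f-%.4f), %s, n = %d\n",
              x$k, x$estimate, round(100 * x$conf_level), x$conf_low,
              x$conf_high, x$model, x$n))
  invisible(x)
}
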