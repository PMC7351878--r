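#' Paired location tests (exact Wilcoxon signed-rank, sign test)
#'
#' Serial within-group comparisons of a biomarker between two visits. The
#' signed-rank test uses the exact permutation null up to n = 25 pairs
#' (beyond that, the normal approximation with continuity correction); the
#' sign test is the exact binomial test on the sign of the differences.
#' Zero differences are discarded, as is conventional for both tests; if
#' every difference is zero the p-value is 1 with a warning.
#'
#' @param x,y paired measurements of equal length.
#' @param method `"wilcoxon_exact"` or `"sign"`.
#' @param exact_limit maximum number of non-zero pairs for which the exact
#'   signed-rank null is enumerated.
#' @return An object of class `oq_test`: `statistic`, `p_value`, `method`,
#'   `n` (non-zero pairs).
#' @export
paired_location_test <- function(x, y,
                                 method = c("wilcoxon_exact", "sign"),
                                 exact_limit = 25L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero")
    return(oq_test(statistic = 0, p_value = 1, method = method, n = 0L))
  }
  if (method == "sign") {
    ht <- binom.test(sum(nz > 0), length(nz), p = 0.5)
    oq_test(statistic = unname(ht$statistic), p_value = ht$p.value,
            method = "exact sign test", n = length(nz))
  } else {
    exact <- length(nz) <= exact_limit && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(
      wilcox.test(x[ok], y[ok], paired = TRUE, exact = exact,
                  correct = TRUE))
    oq_test(statistic = unname(ht$statistic), p_value = ht$p.value,
            method = if (exact) "exact Wilcoxon signed-rank test"
                     else "Wilcoxon signed-rank test (normal approximation)",
            n = length(nz))
  }
}

#' Mann-Whitney rank-sum test for two independent groups
#'
#' Intergroup comparison of a biomarker. The exact null distribution is
#' used for small tie-free samples (both groups at or below `exact_limit`),
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_limit per-group size cap for the exact null.
#' @return An `oq_test` with the Mann-Whitney U statistic (counting pairs
#'   where `a` precedes `b`), two-sided p-value, and per-group sizes.
#' @export
rank_sum_test <- function(a, b, exact_limit = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= exact_limit && length(b) <= exact_limit && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  oq_test(statistic = unname(ht$statistic), p_value = ht$p.value,
          method = if (exact) "exact Mann-Whitney test"
                   else "Mann-Whitney test (normal approximation)",
          n = c(n1 = length(a), n2 = length(b)))
}

oq_test <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n),
            class = "oq_test")
}

#' @export
print.oq_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Distribution summary in the median / interquartile convention
#'
#' Median and 25th-75th percentiles (linear interpolation between order
#' statistics, the default sample-quantile definition), plus the range.
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @return A list: `n`, `median`, `q25`, `q75`, `min`, `max`.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(values), median = q[2], q25 = q[1], q75 = q[3],
       min = min(values), max = max(values))
}
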