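#' Welch's unequal-variances two-sample t-test
#'
#' Two-sided test with Welch-Satterthwaite degrees of freedom, computed
#' directly from the textbook formulas (used e.g. to compare TAD counts
#' between the two chromatin types).
#'
#' @param sample_a,sample_b Numeric samples, each with n >= 2 and nonzero
#'   variance.
#' @return Object of class `TestResult`: `statistic`, `p_value`, `df`,
#'   and per-group `summary` (n, mean, var).
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) stop("degenerate samples: both variances are zero")
  se2 <- va / na + vb / nb
  t <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(statistic = t, p_value = p, df = df,
                 summary = data.frame(group = c("a", "b"), n = c(na, nb),
                                      mean = c(mean(sample_a), mean(sample_b)),
                                      var = c(va, vb))),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, two-sided p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson correlation over jointly unmasked entries
#'
#' @param x,y Numeric vectors of equal length; `NA` = masked.
#' @param mask Optional logical vector; `FALSE` entries are excluded in
#'   addition to `NA`s.
#' @return Pearson r.
#' @export
masked_pearson <- function(x, y, mask = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 3) stop("need >= 3 jointly unmasked entries")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("constant input")
  stats::cor(x[keep], y[keep])
}
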