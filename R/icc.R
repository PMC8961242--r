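#' Intraclass correlation: two-way mixed model, absolute agreement
#'
#' Single-measure absolute-agreement intraclass correlation between k
#' fixed raters/methods measuring n subjects (e.g. lesion counts per
#' subject on artificial vs conventional DIR). From the two-way ANOVA
#' decomposition of the n x k matrix into between-subject (`MSR`),
#' between-method (`MSC`) and residual (`MSE`) mean squares, the
#' coefficient is
#'
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' The 95% confidence interval uses the F-distribution bounds for the
#' absolute-agreement single-measure coefficient (Satterthwaite
#' approximation for the denominator degrees of freedom), and the reported
#' F statistic is `MSR / MSE` with degrees of freedom `(n - 1)` and the
#' same approximated denominator.
#'
#' @param counts numeric matrix, n subjects x k methods (k = 2 for the
#'   aDIR/cDIR comparison); data.frames are coerced.
#' @param conf confidence level (default 0.95).
#' @return an [IccResult-class].
#' @examples
#' m <- cbind(a = c(10, 4, 7, 12, 3, 8), c = c(11, 2, 8, 14, 4, 7))
#' iccAbsoluteAgreement(m)
#' @export
iccAbsoluteAgreement <- function(counts, conf = 0.95) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 methods")
  if (anyNA(m)) stop("counts must be complete")
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= .Machine$double.eps)
    stop("zero total variance: ICC undefined")
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom
  alpha <- 1 - conf
  # Satterthwaite df for the compound denominator mean square
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- if (mse > 0) {
    (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  } else Inf
  if (!is.finite(v) || v <= 0) v <- (n - 1) * (k - 1)
  v <- min(v, 1e6)   # cap: beyond this the F quantile is numerically flat
  fL <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
  fU <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
  ciLow <- n * (msr - fL * mse) /
    (fL * (k * msc + (k * n - k - n) * mse) + n * msr)
  ciHigh <- n * (fU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fU * msr)
  if (mse <= .Machine$double.eps && msc <= .Machine$double.eps) {
    # perfect agreement: degenerate interval at 1
    ciLow <- 1; ciHigh <- 1
  }
  if (!is.finite(ciLow)) ciLow <- -1
  if (!is.finite(ciHigh)) ciHigh <- 1
  fStat <- if (mse > 0) msr / mse else Inf
  p <- if (is.finite(fStat)) pf(fStat, n - 1, v, lower.tail = FALSE) else 0
  new("IccResult", icc = icc,
      ciLow = min(ciLow, icc), ciHigh = min(1, max(ciHigh, icc)),
      fStat = fStat, df1 = n - 1, df2 = v, p = p,
      n = as.integer(n), k = as.integer(k), msr = msr, msc = msc,
      mse = mse)
}
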