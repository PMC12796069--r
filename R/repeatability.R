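# Test-retest repeatability statistics: repeatability coefficient,
# coefficient of variation, intraclass correlation, Bland-Altman limits.

#' Repeatability statistics for paired measurements
#'
#' For paired test/retest values the differences d = test - retest give
#' the repeatability coefficient RPC = 2 * SD(d) (sample SD), the
#' coefficient of variation CoV = SD(d) / grand mean * 100 (%), and the
#' Bland-Altman limits of agreement mean(d) +/- 1.96 * SD(d). The
#' intraclass correlation is the two-way mixed, single-score form,
#' computed from the two-way ANOVA decomposition; the consistency form
#' ICC(3,1) = (MS_subject - MS_error) / (MS_subject + (k-1) MS_error)
#' is the default, and the absolute-agreement form ICC(2,1) is also
#' returned.
#'
#' @param pairs data.frame with columns `subject`, `test`, `retest`
#'   (consistent units).
#' @return list with `rpc`, `cov_pct`, `icc` (consistency), also exposed
#'   as `icc_consistency` plus `icc_agreement`, `mean_diff`, `loa_low`,
#'   `loa_high`, `n`.
#' @examples
#' p <- data.frame(subject = 1:4, test = c(10, 12, 9, 14),
#'                 retest = c(11, 11, 9, 15))
#' repeatabilityStats(p)$rpc
#' @export
repeatabilityStats <- function(pairs) {
  stopifnot(all(c("test", "retest") %in% names(pairs)))
  x <- pairs$test
  y <- pairs$retest
  if (length(x) < 2) stop("at least 2 paired measurements are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in pairs")
  d <- x - y
  sdd <- sd(d)
  grand <- mean(c(x, y))
  if (abs(grand) < .Machine$double.eps * 100)
    stop("coefficient of variation undefined: grand mean is zero")
  n <- length(x)
  k <- 2
  m <- matrix(c(x, y), n, k)
  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssRows <- k * sum((rowm - gm)^2)
  ssCols <- n * sum((colm - gm)^2)
  ssTot <- sum((m - gm)^2)
  ssErr <- ssTot - ssRows - ssCols
  msRows <- ssRows / (n - 1)
  msCols <- ssCols / (k - 1)
  msErr <- ssErr / ((n - 1) * (k - 1))
  denomC <- msRows + (k - 1) * msErr
  iccC <- if (denomC > 0) (msRows - msErr) / denomC else NA_real_
  denomA <- msRows + (k - 1) * msErr + k / n * (msCols - msErr)
  iccA <- if (denomA > 0) (msRows - msErr) / denomA else NA_real_
  list(rpc = 2 * sdd,
       cov_pct = sdd / grand * 100,
       icc = iccC, icc_consistency = iccC, icc_agreement = iccA,
       mean_diff = mean(d),
       loa_low = mean(d) - 1.96 * sdd,
       loa_high = mean(d) + 1.96 * sdd,
       n = n)
}
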