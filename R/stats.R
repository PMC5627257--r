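#' Pooled-variance two-sample t test from summary statistics
#'
#' Classical equal-variance two-sample t test computed from group means,
#' SDs and sizes (no raw data needed), with `n1 + n2 - 2` degrees of
#' freedom. Useful for published summaries, e.g. comparing group bodyweights
#' reported as mean and SD.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value` (two-sided).
#' @export
#' @examples
#' pooled_t_test(405, 10, 4, 592, 95, 4)   # p ~ 0.008
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      t <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p degenerates to 0")
      t <- sign(mean1 - mean2) * Inf; p <- 0
    }
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 estimate = c(`mean difference` = mean1 - mean2),
                 method = "Pooled-variance two-sample t test (summary statistics)",
                 data.name = sprintf("group 1 (n=%d) vs group 2 (n=%d)", n1, n2)),
            class = "htest")
}
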