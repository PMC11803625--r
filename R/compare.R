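#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic `D` is the supremum of the absolute difference between the
#' two empirical cumulative distribution functions, computed exactly on the
#' pooled sorted values. The p-value uses the asymptotic Kolmogorov
#' distribution evaluated at `sqrt(ne) * D` with effective sample size
#' `ne = n1 * n2 / (n1 + n2)` (the paper-scale regime is large n, where the
#' asymptotic form is adequate).
#'
#' @param x1,x2 Numeric samples (non-empty).
#' @return List with `d_stat` and `p_value`.
#' @export
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50))
ks_two_sample <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  w <- c(x1, x2)
  o <- order(w)
  steps <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[o]
  cum <- cumsum(steps)
  # with ties, |F1 - F2| is only attained after the full tie group
  keep <- c(diff(w[o]) != 0, TRUE)
  d <- max(abs(cum[keep]))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * d
  p <- if (lambda < 0.2) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(d_stat = d, p_value = p)
}

#' Cohen's d effect size from summary statistics
#'
#' `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`, using the equal-weight
#' pooled standard deviation. The statistic is antisymmetric under swapping
#' the groups and invariant under a common affine rescaling.
#'
#' @param mean1,sd1 Mean and SD of group 1.
#' @param mean2,sd2 Mean and SD of group 2.
#' @return Signed effect size; `NA` with a warning when both SDs are zero.
#' @export
#' @examples
#' cohens_d(10.84, 4.36, 7.62, 4.69)  # ~0.71
cohens_d <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean1 - mean2) / pooled
}

#' Cohen's d from raw samples
#'
#' @param x1,x2 Numeric samples (each of length >= 2).
#' @return Signed effect size as in [cohens_d()].
#' @export
cohens_d_samples <- function(x1, x2) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  cohens_d(mean(x1), stats::sd(x1), mean(x2), stats::sd(x2))
}

#' Compare two samples: KS test plus effect size
#'
#' @param x1,x2 Numeric samples.
#' @param label1,label2 Group labels carried into the result.
#' @return One-row data frame with `d_stat`, `p_value`, `cohens_d`, `n1`,
#'   `n2`, `label1`, `label2`.
#' @export
compare_distributions <- function(x1, x2, label1 = "group1",
                                  label2 = "group2") {
  ks <- ks_two_sample(x1, x2)
  data.frame(d_stat = ks$d_stat, p_value = ks$p_value,
             cohens_d = cohens_d_samples(x1, x2),
             n1 = length(x1), n2 = length(x2),
             label1 = label1, label2 = label2)
}
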