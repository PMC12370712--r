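#' Classification metrics
#'
#' `accuracy()` is the fraction of correct predictions. `macro_f1()` is the
#' unweighted mean of per-class F1 scores over the classes present in either
#' the truth or the prediction vector; a class absent from both contributes
#' nothing. Per class, `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param truth,pred equal-length nonempty label vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' macro_f1(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0.5
#' @export
accuracy <- function(truth, pred) {
  check_label_pair(truth, pred)
  mean(truth == pred)
}

#' @rdname accuracy
#' @export
macro_f1 <- function(truth, pred) {
  check_label_pair(truth, pred)
  classes <- sort(unique(c(truth, pred)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

check_label_pair <- function(truth, pred) {
  if (!length(truth)) stopf("empty label vectors")
  if (length(truth) != length(pred)) {
    stopf("truth and pred lengths differ (%d vs %d)", length(truth),
          length(pred))
  }
}

#' Paired t-test on two metric vectors
#'
#' The classical paired t statistic on the differences `a - b`, with a
#' two-sided p-value from the t distribution with `n - 1` degrees of
#' freedom. Degenerate conventions: identical vectors give `t = 0, p = 1`;
#' constant nonzero differences (zero spread, nonzero mean) give
#' `t = +/-Inf` with the p-value reported as the smallest positive
#' normalized double, i.e. below machine precision.
#'
#' @param a,b equal-length numeric vectors with `n >= 2`.
#' @return List with `t`, `df` and `p`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))  # t = 3.4641, p ~ 0.0742
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must have equal length")
  n <- length(a)
  if (n < 2) stopf("need n >= 2 pairs")
  d <- a - b
  if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
  s <- sd(d)
  if (s == 0) {
    return(list(t = sign(mean(d)) * Inf, df = n - 1,
                p = .Machine$double.xmin))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}
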