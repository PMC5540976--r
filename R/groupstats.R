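# Group-level tests shared across analyses.

#' Wilcoxon signed-rank test across subjects
#'
#' One-sample signed-rank test of per-subject values against a null value.
#' Zero differences are excluded before ranking. The exact null
#' distribution is used up to n = 25 (when there are no ties in the
#' absolute differences); larger samples or tied data use the normal
#' approximation with continuity correction.
#'
#' @param values per-subject values.
#' @param mu null value.
#' @param alternative `"greater"`, `"two.sided"` or `"less"`.
#' @return data frame of class `group_test`: `test`, `statistic`, `p`,
#'   `alternative`, `n` (non-zero differences), `n_zero`.
#' @examples
#' wilcoxon_signed_rank(c(0.7, 0.6, 0.8, 0.66, 0.71), mu = 0.5,
#'                      alternative = "greater")$p # 1/32
#' @export
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("greater", "two.sided",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_("values must be finite numbers")
  d <- values - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_("degenerate input: all differences are zero")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alternative, exact = exact,
                       correct = TRUE))
  out <- data.frame(test = "wilcoxon_signed_rank",
                    statistic = unname(res$statistic), p = res$p.value,
                    alternative = alternative, n = n, n_zero = n_zero,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_test", "data.frame")
  out
}

#' Across-subject one-sample t-test
#'
#' One-sample t-test of within-subject differences against zero, treating
#' subject as a random effect (the standard random-effects group test for
#' per-subject summary statistics such as percentage-point preference
#' differences).
#'
#' @param differences one value per subject.
#' @param two_sided two-sided (default) or one-sided (greater) test.
#' @return data frame of class `group_test`: `test`, `statistic` (t), `df`,
#'   `p`, `alternative`, `n`.
#' @export
across_subject_ttest <- function(differences, two_sided = TRUE) {
  if (!is.numeric(differences) || any(!is.finite(differences)))
    stop_("differences must be finite numbers")
  n <- length(differences)
  if (n < 2L) stop_("need at least 2 subjects")
  if (sd(differences) == 0)
    stop_("degenerate input: zero variance across subjects")
  alternative <- if (two_sided) "two.sided" else "greater"
  res <- stats::t.test(differences, mu = 0, alternative = alternative)
  out <- data.frame(test = "across_subject_ttest",
                    statistic = unname(res$statistic),
                    df = unname(res$parameter), p = res$p.value,
                    alternative = alternative, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_test", "data.frame")
  out
}
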