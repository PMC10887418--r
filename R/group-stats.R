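#' Significance star annotation
#'
#' The conventional star thresholds: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05 (all strict), otherwise `ns`.
#'
#' @param p_value A p-value in `[0, 1]`.
#' @return `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
star_label <- function(p_value) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1)
    stop("`p_value` must lie in [0, 1]")
  if (p_value < 0.001) "***"
  else if (p_value < 0.01) "**"
  else if (p_value < 0.05) "*"
  else "ns"
}

#' Normality-driven two-group comparison
#'
#' The test-selection procedure used for all stiffness and shape
#' comparisons: Shapiro-Wilk normality test on each group; if both pass at
#' `alpha`, Levene's homoscedasticity test (classical form, centered on the
#' group means) decides between the pooled-variance Student t-test (Levene
#' passes) and Welch's t-test (Levene rejects); if either group fails
#' normality, the two-sided Wilcoxon rank-sum test is used. All tests are
#' two-sided and unpaired. The full decision trace is returned.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 3, finite.
#' @param alpha Decision level for the Shapiro and Levene gates and for the
#'   significance verdict. Default 0.05.
#' @return An object of class `test_decision`: `shapiro_p_a`, `shapiro_p_b`,
#'   `levene_p` (NA when the Wilcoxon branch was taken), `chosen_test`
#'   (`"student_pooled"`, `"welch"` or `"wilcoxon"`), `statistic`,
#'   `p_value`, `stars`, `alpha`, `n_a`, `n_b`.
#' @examples
#' g <- simulate_two_groups(list("normal", mean = 0, sd = 1),
#'                          list("normal", mean = 2, sd = 1), 20, 20, seed = 1)
#' compare_groups(g$a, g$b)
#' @export
compare_groups <- function(sample_a, sample_b, alpha = 0.05) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  decision <- function(chosen, stat, p, pa, pb, pl) {
    structure(list(shapiro_p_a = pa, shapiro_p_b = pb, levene_p = pl,
                   chosen_test = chosen, statistic = unname(stat),
                   p_value = p, stars = star_label(p), alpha = alpha,
                   n_a = length(a), n_b = length(b)),
              class = "test_decision")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(decision("student_pooled", 0, 1, NA_real_, NA_real_, NA_real_))
    # two distinct constants: ranks separate the groups completely
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
    return(decision("wilcoxon", w$statistic, w$p.value,
                    NA_real_, NA_real_, NA_real_))
  }
  shapiro_p <- function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  if (pa > alpha && pb > alpha) {
    df <- data.frame(value = c(a, b),
                     group = factor(rep(c("a", "b"), c(length(a), length(b)))))
    pl <- car::leveneTest(value ~ group, data = df, center = mean)[1, "Pr(>F)"]
    tt <- stats::t.test(a, b, var.equal = pl > alpha)
    decision(if (pl > alpha) "student_pooled" else "welch",
             tt$statistic, tt$p.value, pa, pb, pl)
  } else {
    exact <- min(length(a), length(b)) <= 12 &&
      !any(duplicated(c(a, b)))
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = TRUE))
    decision("wilcoxon", w$statistic, w$p.value, pa, pb, NA_real_)
  }
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("<test_decision> %s: statistic = %.4g, p = %.3g (%s)\n",
              x$chosen_test, x$statistic, x$p_value, x$stars))
  cat(sprintf("  shapiro p: a = %.3g, b = %.3g; levene p = %.3g; alpha = %g\n",
              x$shapiro_p_a, x$shapiro_p_b, x$levene_p, x$alpha))
  invisible(x)
}
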