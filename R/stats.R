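#' Normality gate for metric vectors
#'
#' Shapiro-Wilk at alpha = 0.05 decides between the paired t test and the
#' Wilcoxon signed-rank test downstream. Constant (degenerate) vectors are
#' declared non-normal with a warning.
#'
#' @param x numeric vector, length >= 3.
#' @param alpha significance level of the gate.
#' @return `"normal"` or `"non-normal"`; attribute `"p"` carries the
#'   Shapiro-Wilk p-value (NA for degenerate input).
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop("normality_gate: need at least 3 values")
  if (sd(x) == 0) {
    warning("normality_gate: constant vector, treated as non-normal")
    return(structure("non-normal", p = NA_real_))
  }
  p <- shapiro.test(x)$p.value
  structure(if (p >= alpha) "normal" else "non-normal", p = p)
}

#' Paired comparison with gated test choice and Bonferroni correction
#'
#' The paired differences pass through [normality_gate()]; normal
#' differences get a paired Student t test, otherwise a Wilcoxon signed-rank
#' test (zero differences dropped, the signed-rank convention). The family
#' alpha is Bonferroni-divided by the number of comparisons, so with the
#' default family alpha 0.05 over 3 comparisons significance requires
#' p < 0.0166... (the truncated 0.016 threshold in common use).
#'
#' @param a,b paired numeric vectors of equal length.
#' @param label text label for reporting.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 3).
#' @return list of class `paired_comparison`: `label`, `test_used`, `p`,
#'   `adjusted_alpha`, `significant`, `median_diff`, `n`, `all_zero`.
#' @export
paired_compare <- function(a, b, label = "", alpha_family = 0.05,
                           n_comparisons = 3) {
  if (length(a) != length(b)) stop("paired_compare: unequal lengths")
  d <- a - b
  adj <- alpha_family / n_comparisons
  if (all(d == 0)) {
    return(structure(list(label = label, test_used = "wilcoxon",
                          p = 1, adjusted_alpha = adj, significant = FALSE,
                          median_diff = 0, n = length(d), all_zero = TRUE),
                     class = "paired_comparison"))
  }
  gate <- suppressWarnings(normality_gate(d))
  if (identical(as.character(gate), "normal")) {
    test_used <- "t"
    p <- t.test(a, b, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    dz <- d[d != 0]
    p <- suppressWarnings(wilcox.test(dz, mu = 0)$p.value)
  }
  structure(list(label = label, test_used = test_used, p = p,
                 adjusted_alpha = adj, significant = p < adj,
                 median_diff = median(d), n = length(d), all_zero = FALSE),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: %s test, p = %.4g (alpha_adj = %.4g) %s\n",
              x$label, x$test_used, x$p, x$adjusted_alpha,
              if (x$significant) "*" else ""))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), nonzero variance.
#' @return R^2 in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r2: unequal lengths")
  if (length(x) < 3) stop("pearson_r2: need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) stop("pearson_r2: zero variance")
  cor(x, y)^2
}
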