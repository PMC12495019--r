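# Normality-gated descriptive and inferential statistics. Every sample is
# formally tested for normality (Shapiro-Wilk at 0.05); the gate selects
# between the parametric branch (t / Welch tests, Cohen's d) and the
# non-parametric branch (Wilcoxon tests, probability of superiority). All
# p-values are two-sided.

#' Describe a sample
#'
#' Always reports n, mean, SD and the 95% t confidence interval of the mean.
#' When the Shapiro-Wilk test rejects normality at 0.05, also reports the
#' median, the interquartile interval and the binomial order-statistic 95%
#' confidence interval of the median.
#'
#' @param x numeric vector, n >= 3.
#' @param conf confidence level (default 0.95).
#' @return an object of class `sample_descriptor`.
#' @export
describe_sample <- function(x, conf = 0.95) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("describe_sample needs n >= 3", call. = FALSE)
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  n <- length(x)
  m <- mean(x); s <- sd(x)
  half <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  sw_p <- if (s > 0) shapiro.test(x)$p.value else 0
  out <- list(n = n, mean = m, sd = s, ci_mean = c(m - half, m + half),
              shapiro_p = sw_p, is_normal = sw_p >= 0.05)
  if (!out$is_normal) {
    sx <- sort(x)
    out$median <- median(x)
    out$iqi <- unname(quantile(x, c(0.25, 0.75), type = 7))
    j <- qbinom((1 - conf) / 2, n, 0.5)
    while (j > 0 && pbinom(n - j, n, 0.5) - pbinom(j - 1, n, 0.5) < conf) j <- j - 1
    j <- max(j, 1L)
    out$ci_median <- c(sx[j], sx[n - j + 1])
  }
  structure(out, class = "sample_descriptor")
}

#' @export
print.sample_descriptor <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, SD = %.4g, CI_mean = [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$ci_mean[1], x$ci_mean[2]))
  cat(sprintf("Shapiro-Wilk p = %.3g -> %s\n", x$shapiro_p,
              if (x$is_normal) "normal" else "non-normal"))
  if (!x$is_normal)
    cat(sprintf("median = %.4g, IQI = [%.4g, %.4g], CI_median = [%.4g, %.4g]\n",
                x$median, x$iqi[1], x$iqi[2], x$ci_median[1], x$ci_median[2]))
  invisible(x)
}

# Probability of superiority with tie halving.
prob_superiority <- function(a, b = NULL, mu0 = NULL) {
  if (is.null(b)) {
    (sum(a > mu0) + 0.5 * sum(a == mu0)) / length(a)
  } else {
    u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u / (length(a) * length(b))
  }
}

is_normal_sample <- function(x, alpha = 0.05) {
  if (sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value >= alpha
}

#' Normality-gated two-sided comparison
#'
#' One-sample, paired or unpaired location comparison. The normality gate
#' (Shapiro-Wilk at `alpha_normal`) is applied to the relevant quantity: the
#' sample itself for one-sample tests, the paired differences for paired
#' tests, and each group for unpaired tests (both must pass). The parametric
#' branch uses Student's t (one-sample, paired) or Welch's unequal-variances
#' t (unpaired) with Cohen's d and d'; the non-parametric branch uses the
#' Wilcoxon signed-rank (one-sample, paired) or rank-sum (unpaired) test with
#' the probability of superiority as effect size.
#'
#' Effect-size conventions: positive d means the first argument's location
#' exceeds `mu0` / the second argument's. For paired designs d is
#' `mean(diff) / sd(diff)` and d' is `mean(diff)` over the RMS of the two
#' sample SDs; for unpaired designs d uses the pooled (n-1 weighted) SD and
#' d' the RMS of the two SDs.
#'
#' @param a numeric vector (first sample).
#' @param b second sample (paired or unpaired designs).
#' @param mu0 reference value (one-sample design).
#' @param design `"one_sample"`, `"paired"` or `"unpaired"`.
#' @param alpha_normal normality-gate level (default 0.05).
#' @return an object of class `comparison_result`.
#' @export
compare_samples <- function(a, b = NULL, mu0 = NULL,
                            design = c("one_sample", "paired", "unpaired"),
                            alpha_normal = 0.05) {
  design <- match.arg(design)
  a <- as.numeric(a)
  if (design == "one_sample") {
    if (is.null(mu0)) stop("one-sample design needs `mu0`", call. = FALSE)
  } else {
    if (is.null(b)) stop(sprintf("%s design needs `b`", design), call. = FALSE)
    b <- as.numeric(b)
  }
  if (design == "paired" && length(a) != length(b))
    stop("paired design needs equal lengths", call. = FALSE)

  # No location difference at all: report p = 1 and zero effect, flagged, so
  # the caller can tell an uninformative comparison from a computed one.
  degenerate <- function(msg) {
    warning(sprintf("degenerate comparison: %s", msg))
    structure(list(design = design, test_used = "t", p = 1,
                   statistic = 0, normal = NA, degenerate = TRUE,
                   effect = list(cohens_d = 0, cohens_d_prime = 0,
                                 prob_superiority = 0.5)),
              class = "comparison_result")
  }

  if (design == "one_sample") {
    if (sd(a) == 0 && all(a == mu0)) return(degenerate("all values tied at mu0"))
    normal <- is_normal_sample(a, alpha_normal)
    if (normal) {
      tt <- t.test(a, mu = mu0)
      eff <- list(cohens_d = (mean(a) - mu0) / sd(a),
                  prob_superiority = prob_superiority(a, mu0 = mu0))
      res <- list(test_used = "t", p = tt$p.value, statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(wilcox.test(a, mu = mu0))
      eff <- list(prob_superiority = prob_superiority(a, mu0 = mu0))
      res <- list(test_used = "wilcoxon_signed_rank", p = wt$p.value,
                  statistic = unname(wt$statistic))
    }
  } else if (design == "paired") {
    d <- a - b
    if (all(d == 0)) return(degenerate("all paired differences are zero"))
    normal <- is_normal_sample(d, alpha_normal)
    rms_sd <- sqrt((var(a) + var(b)) / 2)
    if (normal) {
      tt <- t.test(a, b, paired = TRUE)
      eff <- list(cohens_d = mean(d) / sd(d),
                  cohens_d_prime = mean(d) / rms_sd,
                  prob_superiority = prob_superiority(d, mu0 = 0))
      res <- list(test_used = "t", p = tt$p.value, statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
      eff <- list(prob_superiority = prob_superiority(d, mu0 = 0))
      res <- list(test_used = "wilcoxon_signed_rank", p = wt$p.value,
                  statistic = unname(wt$statistic))
    }
  } else {
    if (sd(c(a, b)) == 0) return(degenerate("all values tied"))
    normal <- is_normal_sample(a, alpha_normal) && is_normal_sample(b, alpha_normal)
    n1 <- length(a); n2 <- length(b)
    pooled <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
    rms_sd <- sqrt((var(a) + var(b)) / 2)
    if (normal) {
      tt <- t.test(a, b, var.equal = FALSE)
      eff <- list(cohens_d = (mean(a) - mean(b)) / pooled,
                  cohens_d_prime = (mean(a) - mean(b)) / rms_sd,
                  prob_superiority = prob_superiority(a, b))
      res <- list(test_used = "welch_t", p = tt$p.value, statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(wilcox.test(a, b))
      eff <- list(prob_superiority = prob_superiority(a, b))
      res <- list(test_used = "wilcoxon_rank_sum", p = wt$p.value,
                  statistic = unname(wt$statistic))
    }
  }
  structure(c(list(design = design), res,
              list(normal = normal, degenerate = FALSE, effect = eff,
                   n = if (design == "one_sample") length(a) else c(length(a), length(b)))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<comparison_result> %s: degenerate (p undefined)\n", x$design))
    return(invisible(x))
  }
  cat(sprintf("<comparison_result> %s, %s test: p = %.4g (two-sided)\n",
              x$design, x$test_used, x$p))
  eff <- x$effect
  if (!is.null(eff$cohens_d))
    cat(sprintf("  Cohen's d = %.3f%s\n", eff$cohens_d,
                if (!is.null(eff$cohens_d_prime))
                  sprintf(", d' = %.3f", eff$cohens_d_prime) else ""))
  if (!is.null(eff$prob_superiority))
    cat(sprintf("  probability of superiority = %.3f\n", eff$prob_superiority))
  invisible(x)
}
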