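#' Compare a subject metric to its null-ensemble means at one threshold
#'
#' Paired t-test of per-subject metric values against the means of each
#' subject's own null ensemble, with Bonferroni correction over the number
#' of thresholds in the active grid.
#'
#' @param subject_values per-subject metric at one threshold.
#' @param null_values per-subject null-ensemble mean at the same threshold.
#' @param alpha family-wise significance level (default 0.01).
#' @param n_tests number of thresholds corrected over (e.g. 19 for the
#'   correlation grid).
#' @return list: `mean_subject`, `mean_null`, `t`, `df`, `p_value`,
#'   `significant` (Bonferroni-corrected flag), `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
compare_metric_to_null <- function(subject_values, null_values,
                                   alpha = 0.01, n_tests = 1) {
    if (length(subject_values) != length(null_values)) {
        stopf("paired vectors must have equal length")
    }
    ok <- is.finite(subject_values) & is.finite(null_values)
    x <- subject_values[ok]
    y <- null_values[ok]
    if (length(x) < 3) stopf("need at least 3 paired subjects")
    d <- x - y
    if (sd(d) < 1e-12 * max(1, abs(mean(d)))) {
        return(list(mean_subject = mean(x), mean_null = mean(y),
                    t = NA_real_, df = NA_real_, p_value = NA_real_,
                    significant = NA, flag = "zero_variance"))
    }
    tt <- t.test(x, y, paired = TRUE)
    list(mean_subject = mean(x), mean_null = mean(y),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         significant = tt$p.value < alpha / n_tests,
         flag = "ok")
}

#' Confidence interval for the small-world index
#'
#' t-based confidence interval for the mean of per-subject sigma values at
#' one threshold, with a flag indicating whether the whole interval exceeds
#' 1 (the small-world criterion).
#'
#' @param sigma_values per-subject small-world indices.
#' @param level confidence level (default 0.99).
#' @return list: `mean`, `lower`, `upper`, `exceeds_one`.
#' @export
swi_interval <- function(sigma_values, level = 0.99) {
    x <- sigma_values[is.finite(sigma_values)]
    if (length(x) < 3) stopf("need at least 3 values")
    m <- mean(x)
    se <- sd(x) / sqrt(length(x))
    tq <- qt(1 - (1 - level) / 2, df = length(x) - 1)
    lower <- m - tq * se
    upper <- m + tq * se
    list(mean = m, lower = lower, upper = upper, exceeds_one = lower > 1)
}
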