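#' Per-subject, per-threshold metric sweep
#'
#' The analysis workhorse: thresholds every subject's connectivity matrix at
#' every grid value, computes C, L, Eglob, Eloc, and cost, generates a
#' degree-preserving rewired null ensemble per subject and threshold, and
#' derives gamma, lambda, and the small-world index from the ensemble means.
#'
#' @param matrices list of subject connectivity matrices.
#' @param scheme thresholding scheme: `"r"`, `"cost"`, or `"k"`.
#' @param grid threshold values (defaults to the scheme's standard grid).
#' @param n_nulls rewired nulls per subject and threshold (the full design
#'   uses 100 for r/k grids and 20 for the cost grid; scale down for fast
#'   runs).
#' @param swaps_per_edge rewiring intensity.
#' @param seed master seed.
#' @return data.frame with one row per subject x threshold: `subject`,
#'   `threshold`, `C`, `L`, `Eglob`, `Eloc`, `cost`, `lcc_fraction`,
#'   `null_C`, `null_L`, `gamma`, `lambda`, `sigma`, `cost_efficiency`.
#' @export
metric_sweep <- function(matrices, scheme = c("r", "cost", "k"), grid = NULL,
                         n_nulls = 100, swaps_per_edge = 10, seed = 1L) {
    scheme <- match.arg(scheme)
    if (is.null(grid)) {
        grid <- switch(scheme, r = r_grid(), cost = cost_grid(), k = k_grid())
    }
    thr_fun <- switch(scheme, r = threshold_by_r, cost = threshold_by_cost,
                      k = threshold_by_degree)
    seeds <- child_seeds(seed, length(matrices) * length(grid))
    rows <- list()
    idx <- 0L
    for (s in seq_along(matrices)) {
        for (ti in seq_along(grid)) {
            idx <- idx + 1L
            g <- thr_fun(matrices[[s]], grid[ti])
            met <- graph_metrics(g)
            null_C <- null_L <- NA_real_
            gamma <- lambda <- sigma <- NA_real_
            if (n_nulls > 0 && n_edges(g) >= 2) {
                e <- edge_list(g)
                attempts <- as.integer(ceiling(swaps_per_edge * nrow(e)))
                cl <- with_seed(seeds[idx],
                                cpp_null_cl(e, n_nodes(g), attempts, n_nulls))
                null_C <- mean(cl[, 1])
                null_L <- mean(cl[, 2], na.rm = TRUE)
                if (is.finite(null_C) && null_C > 0 &&
                    is.finite(null_L) && null_L > 0 && is.finite(met$L)) {
                    sws <- small_world_summary(met$C, met$L, null_C, null_L,
                                               met$Eglob, met$cost)
                    gamma <- sws$gamma; lambda <- sws$lambda; sigma <- sws$sigma
                }
            }
            rows[[idx]] <- data.frame(
                subject = s, threshold = grid[ti],
                C = met$C, L = met$L, Eglob = met$Eglob, Eloc = met$Eloc,
                cost = met$cost, lcc_fraction = met$lcc_fraction,
                null_C = null_C, null_L = null_L,
                gamma = gamma, lambda = lambda, sigma = sigma,
                cost_efficiency = met$Eglob - met$cost)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "scheme") <- scheme
    out
}

#' Threshold-wise inference table from a metric sweep
#'
#' For each threshold, runs the paired subject-vs-null comparison for a
#' chosen metric and the confidence interval for sigma.
#'
#' @param sweep a [metric_sweep()] result.
#' @param metric column to compare against its null (default `"C"`;
#'   `null_<metric>` must exist, so `"C"` or `"L"`).
#' @param alpha family-wise level; Bonferroni over the grid length.
#' @param level confidence level for the sigma interval.
#' @return data.frame with one row per threshold.
#' @export
sweep_inference <- function(sweep, metric = "C", alpha = 0.01, level = 0.99) {
    grid <- sort(unique(sweep$threshold))
    n_tests <- length(grid)
    rows <- lapply(grid, function(th) {
        sub <- sweep[sweep$threshold == th, ]
        cmp <- tryCatch(
            compare_metric_to_null(sub[[metric]], sub[[paste0("null_", metric)]],
                                   alpha = alpha, n_tests = n_tests),
            error = function(e) list(mean_subject = mean(sub[[metric]], na.rm = TRUE),
                                     mean_null = NA_real_, t = NA_real_,
                                     p_value = NA_real_, significant = NA,
                                     flag = "insufficient_data"))
        swi <- tryCatch(swi_interval(sub$sigma, level = level),
                        error = function(e) list(mean = NA, lower = NA,
                                                 upper = NA, exceeds_one = NA))
        data.frame(threshold = th,
                   mean_subject = cmp$mean_subject, mean_null = cmp$mean_null,
                   t = cmp$t, p_value = cmp$p_value,
                   significant = cmp$significant, flag = cmp$flag,
                   sigma_mean = swi$mean, sigma_lower = swi$lower,
                   sigma_upper = swi$upper, sigma_exceeds_one = swi$exceeds_one,
                   mean_lcc_fraction = mean(sub$lcc_fraction))
    })
    do.call(rbind, rows)
}
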