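#' Cumulative degree distribution
#'
#' The empirical survival function `P(K >= k)` over the distinct observed
#' degrees `k >= 1`; the value at the smallest observed degree is 1 and the
#' function is strictly decreasing over its support. Zero-degree nodes are
#' excluded from the fit domain.
#'
#' @param degrees integer vector of node degrees.
#' @return data.frame with columns `k` and `p` (survival probability).
#' @export
cumulative_distribution <- function(degrees) {
    degrees <- degrees[degrees >= 1]
    if (length(degrees) == 0) stopf("no positive degrees")
    ks <- sort(unique(degrees))
    p <- vapply(ks, function(k) mean(degrees >= k), numeric(1))
    data.frame(k = ks, p = p)
}

model_design <- function(model, k) {
    switch(model,
        power_law = cbind(intercept = 1, log_k = log(k)),
        exponential = cbind(intercept = 1, k = k),
        truncated_power_law = cbind(intercept = 1, log_k = log(k), k = k))
}

#' Fit one degree-distribution model to a cumulative distribution
#'
#' Least squares on the log survival function, mirroring the classic
#' log-log presentation of brain-network degree distributions. The three
#' families all have survival forms linear in their parameters:
#' power law `log P = a - alpha log k`; exponential `log P = a - rate k`;
#' truncated power law `log P = a + (alpha - 1) log k - k / kc`. The
#' truncated family therefore nests the other two. AIC is
#' `n log(RSS / n) + 2 p` with `p` counting the intercept.
#'
#' When the unconstrained truncated fit yields a non-decaying cutoff
#' (`kc <= 0`), the fit is refit at the boundary `kc = Inf` (i.e. the pure
#' power law), keeping the invariant `kc > 0`.
#'
#' @param cdd a [cumulative_distribution()] data.frame.
#' @param model one of `"power_law"`, `"exponential"`,
#'   `"truncated_power_law"`.
#' @return list of class `model_fit`: `model`, `parameters`, `rss`, `aic`,
#'   `n_points`, `n_params`, `valid`, `fitted` (fitted log-survival values).
#' @export
fit_degree_model <- function(cdd, model = c("power_law", "exponential",
                                            "truncated_power_law")) {
    model <- match.arg(model)
    n_params <- if (model == "truncated_power_law") 3L else 2L
    if (length(unique(cdd$k)) < n_params + 2) {
        stopf("need at least %d distinct degrees for %s", n_params + 2, model)
    }
    y <- log(cdd$p)
    X <- model_design(model, cdd$k)
    fit <- lm.fit(X, y)
    coefs <- fit$coefficients
    if (model == "truncated_power_law" && coefs[["k"]] >= 0) {
        # boundary refit: cutoff pushed to infinity, slope term dropped
        Xr <- model_design("power_law", cdd$k)
        fr <- lm.fit(Xr, y)
        coefs <- c(fr$coefficients, k = 0)
        fit <- fr
    }
    rss <- sum(fit$residuals^2)
    params <- switch(model,
        power_law = list(alpha = -coefs[["log_k"]]),
        exponential = list(rate = -coefs[["k"]]),
        truncated_power_law = list(
            alpha = coefs[["log_k"]] + 1,
            kc = if (coefs[["k"]] == 0) Inf else -1 / coefs[["k"]]))
    n <- nrow(cdd)
    structure(list(model = model, parameters = params, rss = rss,
                   aic = n * log(rss / n) + 2 * n_params,
                   n_points = n, n_params = n_params,
                   valid = all(is.finite(unlist(fit$coefficients))),
                   fitted = y - fit$residuals),
              class = "model_fit")
}

#' Fit all three degree-distribution models
#'
#' @param degrees integer degree vector (a graph's degree sequence).
#' @return named list of `model_fit` objects.
#' @export
fit_degree_models <- function(degrees) {
    cdd <- cumulative_distribution(degrees)
    models <- c("power_law", "exponential", "truncated_power_law")
    fits <- lapply(models, function(m) {
        tryCatch(fit_degree_model(cdd, m), error = function(e) NULL)
    })
    names(fits) <- models
    fits[!vapply(fits, is.null, logical(1))]
}

#' Select the best-fitting model by AIC
#'
#' Minimum AIC wins; exact ties go to the model with fewer parameters.
#' Fits flagged invalid are excluded with a warning.
#'
#' @param fits list of `model_fit` objects (see [fit_degree_models()]).
#' @return list: `best` (the winning fit), `model` (its name), `aic` (named
#'   vector of all AICs), `margin` (AIC gap to the runner-up).
#' @export
select_model <- function(fits) {
    ok <- vapply(fits, function(f) isTRUE(f$valid) && is.finite(f$aic), logical(1))
    if (any(!ok)) warnf("excluding %d invalid fit(s)", sum(!ok))
    fits <- fits[ok]
    if (length(fits) < 2) stopf("need at least 2 valid fits to select a model")
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    npar <- vapply(fits, function(f) f$n_params, integer(1))
    ord <- order(aics, npar)
    best <- fits[[ord[1]]]
    list(best = best, model = best$model, aic = aics,
         margin = aics[ord[2]] - aics[ord[1]])
}
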