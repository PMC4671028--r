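test_that("cumulative distribution is a proper survival function", {
    cdd <- cumulative_distribution(c(1, 1, 2))
    expect_equal(cdd$k, c(1, 2))
    expect_equal(cdd$p, c(1, 1 / 3))
    cdd2 <- cumulative_distribution(rep(5, 10))
    expect_equal(nrow(cdd2), 1)
    expect_equal(cdd2$p, 1)
    expect_error(cumulative_distribution(c(0, 0)), "positive")
    # property: non-increasing survival, P = 1 at the minimum degree
    for (i in 1:10) {
        d <- generate_degree_sequence("truncated_power_law", n = 200,
                                      seed = 50 + i)
        cd <- cumulative_distribution(d)
        expect_true(all(diff(cd$p) < 0))
        expect_equal(cd$p[1], 1)
    }
})

test_that("noise-free model data is inverted exactly", {
    k <- 1:20
    # exponential survival with rate 0.3
    f_exp <- fit_degree_model(data.frame(k = k, p = exp(-0.3 * (k - 1))),
                              "exponential")
    expect_lt(abs(f_exp$parameters$rate - 0.3), 1e-6)
    expect_lt(f_exp$rss, 1e-20)
    # power-law survival with exponent 2.1
    f_pow <- fit_degree_model(data.frame(k = k, p = k^(-2.1)), "power_law")
    expect_lt(abs(f_pow$parameters$alpha - 2.1), 1e-6)
    # truncated survival: alpha 1.7, kc 8
    p_tr <- k^(0.7) * exp(-k / 8); p_tr <- p_tr / p_tr[1]
    f_tr <- fit_degree_model(data.frame(k = k, p = p_tr), "truncated_power_law")
    expect_lt(abs(f_tr$parameters$alpha - 1.7), 1e-6)
    expect_lt(abs(f_tr$parameters$kc - 8), 1e-6)
})

test_that("the truncated family nests the power law", {
    # nesting: the 3-parameter truncated fit can always reproduce the pure
    # power law (kc -> Inf), so its RSS never exceeds the power-law RSS
    for (i in 1:20) {
        d <- generate_degree_sequence("power_law", list(alpha = 2.2), 200,
                                      seed = 400 + i)
        cdd <- cumulative_distribution(d)
        if (length(unique(cdd$k)) < 5) next
        f_pow <- fit_degree_model(cdd, "power_law")
        f_tr <- fit_degree_model(cdd, "truncated_power_law")
        expect_lte(f_tr$rss, f_pow$rss + 1e-9)
    }
})

test_that("AIC selection follows minimum AIC with ties to fewer parameters", {
    mk_fit <- function(model, aic, n_params) {
        structure(list(model = model, aic = aic, n_params = n_params,
                       valid = TRUE), class = "model_fit")
    }
    fits <- list(mk_fit("power_law", 10, 2L), mk_fit("exponential", 12, 2L),
                 mk_fit("truncated_power_law", 8, 3L))
    sel <- select_model(fits)
    expect_equal(sel$model, "truncated_power_law")
    expect_equal(sel$margin, 2)
    # tie: 2-parameter model wins
    tie <- list(mk_fit("truncated_power_law", 5, 3L), mk_fit("exponential", 5, 2L))
    expect_equal(select_model(tie)$model, "exponential")
    # invalid fits excluded; under 2 valid fits errors
    bad <- list(mk_fit("power_law", 3, 2L),
                structure(list(model = "exponential", aic = NaN, n_params = 2L,
                               valid = FALSE), class = "model_fit"))
    expect_warning(expect_error(select_model(bad), "2 valid fits"), "invalid")
})

test_that("AIC decreases with RSS at fixed parameter count", {
    k <- 1:15
    base <- data.frame(k = k, p = exp(-0.2 * (k - 1)))
    f_clean <- fit_degree_model(base, "power_law")
    noisy <- base
    set.seed(9)
    noisy$p <- noisy$p * exp(rnorm(15, 0, 0.3))
    noisy$p <- rev(sort(noisy$p)) / max(noisy$p) # keep it a survival function
    f_noisy <- fit_degree_model(noisy, "power_law")
    expect_equal(f_clean$n_params, f_noisy$n_params)
    expect_equal(f_clean$aic < f_noisy$aic, f_clean$rss < f_noisy$rss)
})

test_that("Watts-Strogatz-like sequences reject the pure power law", {
    hits <- vapply(1:20, function(i) {
        ws <- generate_reference_graph("ws_small_world", 90,
                                       list(neighbors = 10, p_rewire = 0.1),
                                       seed = 700 + i)
        sel <- tryCatch(
            suppressWarnings(select_model(fit_degree_models(degrees(ws)))),
            error = function(e) NULL)
        is.null(sel) || sel$model %in% c("exponential", "truncated_power_law")
    }, logical(1))
    expect_gte(mean(hits), 0.90)
})
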