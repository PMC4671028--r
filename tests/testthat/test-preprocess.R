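test_that("framewise displacement sums absolute differences with arc-length rotations", {
    z <- matrix(0, 5, 6)
    expect_equal(framewise_displacement(z), rep(0, 5))
    # single 0.2 mm x-translation step
    m <- z; m[3:5, 1] <- 0.2
    expect_equal(framewise_displacement(m, 50), c(0, 0, 0.2, 0, 0))
    # 0.004 rad rotation step at 50 mm radius -> 0.2 mm
    r <- z; r[2:5, 4] <- 0.004
    expect_equal(framewise_displacement(r, 50), c(0, 0.2, 0, 0, 0))
    # all six parameters move together
    b <- z; b[2, ] <- c(0.1, 0.1, 0.1, 0.001, 0.001, 0.001)
    expect_equal(framewise_displacement(b, 50)[2], 0.3 + 50 * 0.003)
    expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("censor mask drops frames by strict FD/outlier union", {
    m <- build_censor_mask(c(0, 0.31, 0.1), c(0, 0, 0))
    expect_equal(m$retain, c(TRUE, FALSE, TRUE))
    m2 <- build_censor_mask(c(0, 0, 0), c(0.2, 0, 0))
    expect_equal(m2$retain, c(FALSE, TRUE, TRUE))
    # union counted once
    m3 <- build_censor_mask(c(0, 0.4), c(0.2, 0.2))
    expect_equal(m3$n_dropped, 2)
    expect_equal(m3$n_dropped_fd, 1)
    expect_equal(m3$n_dropped_outlier, 2)
    # boundary values are retained (strict inequalities)
    m4 <- build_censor_mask(c(0.3, 0.300001), c(0.10, 0.10))
    expect_equal(m4$retain, c(TRUE, FALSE))
})

test_that("cleaning residuals are orthogonal to confounds and out-of-band regressors", {
    set.seed(5)
    n <- 200; tr <- 2
    ts <- matrix(rnorm(n * 4), n, 4)
    conf <- matrix(rnorm(n * 2), n, 2)
    resid <- clean_timeseries(ts, confounds = conf, tr = tr)
    idx <- attr(resid, "retained")
    expect_lt(max(abs(crossprod(conf[idx, ], resid))) /
              max(abs(resid)), 1e-8)
    # regressing an ROI on itself zeroes it
    r2 <- clean_timeseries(ts, confounds = ts[, 1, drop = FALSE], tr = tr)
    expect_lt(max(abs(r2[, 1])), 1e-10)
    # collinear design is reported
    expect_error(clean_timeseries(ts, confounds = cbind(conf, conf[, 1]), tr = tr),
                 "collinear")
})

test_that("pass-band sinusoids survive and stop-band sinusoids are removed", {
    n <- 196; tr <- 2
    t_sec <- (seq_len(n) - 1) * tr
    pass <- sin(2 * pi * 0.05 * t_sec)
    stopb <- sin(2 * pi * 0.005 * t_sec)
    hi <- sin(2 * pi * 0.2 * t_sec)
    out <- clean_timeseries(cbind(pass, stopb, hi), tr = tr)
    expect_gt(cor(out[, 1], pass), 0.99)
    expect_lt(var(out[, 2]) / var(stopb), 0.01)
    expect_lt(var(out[, 3]) / var(hi), 0.01)
})

test_that("censoring then correlating equals correlating retained frames", {
    set.seed(8)
    ts <- matrix(rnorm(60 * 5), 60, 5)
    fd <- rep(0, 60); fd[c(10, 20, 30)] <- 1
    mask <- build_censor_mask(fd, numeric(60))
    # identity cleaning (no confounds, pass-band covering every DFT bin)
    r <- clean_timeseries(ts, mask = mask, band = c(1e-9, 10), tr = 2)
    keep <- attr(r, "retained")
    expect_equal(keep, setdiff(1:60, c(10, 20, 30)))
    direct <- ts[keep, ]
    direct <- sweep(direct, 2, colMeans(direct))
    expect_equal(correlation_matrix(r), correlation_matrix(direct),
                 tolerance = 1e-8)
})

test_that("correlation_matrix is a unit-diagonal symmetric Pearson matrix", {
    x <- c(1, 2, 3, 4)
    y <- c(1, 2, 2, 4)
    M <- correlation_matrix(cbind(a = x, b = y, c = -x, d = x))
    expect_equal(M["a", "d"], 1)
    expect_equal(M["a", "c"], -1)
    expect_equal(M["a", "b"], 0.923380516877113) # frozen from direct Pearson
    expect_identical(M, t(M))
    expect_equal(diag(M), c(a = 1, b = 1, c = 1, d = 1))
    expect_error(correlation_matrix(cbind(x, rep(1, 4))), "zero-variance")
    expect_error(correlation_matrix(cbind(x[1:2], y[1:2])), "3 retained")
})

test_that("group averaging is element-wise and symmetry-preserving", {
    set.seed(2)
    M <- correlation_matrix(matrix(rnorm(50 * 4), 50, 4))
    expect_equal(group_average(list(M)), M)
    flip <- -M; diag(flip) <- 1
    avg <- group_average(list(M, flip))
    expect_equal(avg[upper.tri(avg)], rep(0, 6))
    A <- M; A[1, 2] <- A[2, 1] <- 0.2
    B <- M; B[1, 2] <- B[2, 1] <- 0.4
    expect_equal(group_average(list(A, B))[1, 2], 0.3)
    expect_error(group_average(list(M, M[1:3, 1:3])), "dimensions")
})

test_that("synthetic cohorts reproduce the censoring bookkeeping", {
    spec <- cohort_spec(n_subjects = 12, seed = 44)
    cohort <- generate_cohort(spec)
    retained <- vapply(cohort, function(s) {
        fd <- framewise_displacement(s$motion)
        sum(build_censor_mask(fd, s$motion$outlier_fraction)$retain)
    }, numeric(1))
    # design target: ~173 of 196 frames survive on average
    expect_gt(mean(retained), 160)
    expect_lt(mean(retained), 185)
})
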