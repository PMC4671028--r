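#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the six rigid-body parameters, with rotations (radians)
#' converted to arc length on a sphere of radius `head_radius_mm`.
#' `FD[1] = 0` by convention.
#'
#' @param motion a `motion_trace` (see [generate_motion()]) or an
#'   `n_frames x 6` matrix: three translations (mm) then three rotations
#'   (radians).
#' @param head_radius_mm conversion radius for rotations; 50 mm is the adult
#'   field standard and stays configurable for neonatal head sizes.
#' @return numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
    params <- if (inherits(motion, "motion_trace")) motion$params else
        as.matrix(motion)
    if (ncol(params) != 6) stopf("motion must have 6 columns, got %d", ncol(params))
    if (nrow(params) < 2) stopf("need at least 2 frames")
    d <- abs(diff(params))
    fd <- rowSums(d[, 1:3, drop = FALSE]) +
        head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
    c(0, fd)
}

#' Build a frame-censoring mask
#'
#' A frame is dropped iff `FD > fd_thresh` (strictly) or its outlier-voxel
#' fraction exceeds `outlier_thresh` (strictly); frames failing both rules
#' are counted once in the total.
#'
#' @param fd per-frame framewise displacement (mm).
#' @param outlier_fraction per-frame fraction of outlier voxels in `[0, 1]`.
#' @param fd_thresh censoring threshold in mm (default 0.3).
#' @param outlier_thresh outlier-fraction threshold (default 0.10).
#' @return list of class `censor_mask`: `retain` (logical, TRUE = keep),
#'   `n_dropped`, `n_dropped_fd`, `n_dropped_outlier`.
#' @export
build_censor_mask <- function(fd, outlier_fraction = NULL,
                              fd_thresh = 0.3, outlier_thresh = 0.10) {
    n <- length(fd)
    if (is.null(outlier_fraction)) outlier_fraction <- numeric(n)
    if (length(outlier_fraction) != n) {
        stopf("fd and outlier_fraction must have equal length")
    }
    drop_fd <- fd > fd_thresh
    drop_out <- outlier_fraction > outlier_thresh
    retain <- !(drop_fd | drop_out)
    structure(list(retain = retain,
                   n_dropped = sum(!retain),
                   n_dropped_fd = sum(drop_fd),
                   n_dropped_outlier = sum(drop_out)),
              class = "censor_mask")
}

# sine/cosine regressors at the DFT frequencies of the ORIGINAL frame grid
# that fall outside [band[1], band[2]]; evaluated at retained frame times.
# Band-stop filtering by regression avoids smearing across censored gaps.
bandstop_regressors <- function(n_frames, tr, band, retained_idx) {
    total <- n_frames * tr
    jmax <- floor(n_frames / 2)
    freqs <- seq_len(jmax) / total
    out_of_band <- freqs < band[1] | freqs > band[2]
    f <- freqs[out_of_band]
    if (length(f) == 0) return(NULL)
    t_sec <- (retained_idx - 1) * tr
    reg <- do.call(cbind, lapply(f, function(fi) {
        cbind(sin(2 * pi * fi * t_sec), cos(2 * pi * fi * t_sec))
    }))
    # at the Nyquist frequency the sine column is identically ~0: drop it
    keep <- apply(reg, 2, function(col) sd(col) > 1e-10)
    reg[, keep, drop = FALSE]
}

#' Censor, regress, and band-pass ROI time series in one projection
#'
#' Implements simultaneous censoring, nuisance regression, and band-pass
#' filtering as a single least-squares projection on the retained frames:
#' the design holds an intercept, the supplied confounds, and sine/cosine
#' regressors at every out-of-band DFT frequency of the original frame grid
#' (band-stop by regression). Residuals are exactly orthogonal to all
#' regressors over the retained frames.
#'
#' @param ts `n_frames x n_rois` numeric matrix.
#' @param confounds optional `n_frames x q` matrix (e.g. motion parameters).
#' @param mask optional [build_censor_mask()] result; all frames retained
#'   when `NULL`.
#' @param band pass-band in Hz (default `c(0.01, 0.1)`).
#' @param tr repetition time in seconds.
#' @return residual matrix on the retained frames only, with an attribute
#'   `retained` giving the original frame indices.
#' @export
clean_timeseries <- function(ts, confounds = NULL, mask = NULL,
                             band = c(0.01, 0.1), tr = 2.0) {
    ts <- as.matrix(ts)
    n <- nrow(ts)
    retain <- if (is.null(mask)) rep(TRUE, n) else mask$retain
    if (length(retain) != n) stopf("mask length != n_frames")
    idx <- which(retain)
    X <- matrix(1, length(idx), 1)
    if (!is.null(confounds)) {
        confounds <- as.matrix(confounds)
        if (nrow(confounds) != n) stopf("confounds must have n_frames rows")
        X <- cbind(X, confounds[idx, , drop = FALSE])
    }
    bs <- bandstop_regressors(n, tr, band, idx)
    if (!is.null(bs)) X <- cbind(X, bs)
    if (length(idx) <= ncol(X)) {
        stopf("only %d retained frames for %d regressors", length(idx), ncol(X))
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
        stopf("rank-deficient design; collinear columns: %s",
              paste(bad, collapse = ", "))
    }
    resid <- qr.resid(qrX, ts[idx, , drop = FALSE])
    colnames(resid) <- colnames(ts)
    attr(resid, "retained") <- idx
    resid
}

#' Pearson connectivity matrix
#'
#' @param ts `frames x ROIs` matrix of (cleaned, retained-frame) series.
#' @return symmetric correlation matrix with a unit diagonal and ROI labels.
#' @export
correlation_matrix <- function(ts) {
    ts <- as.matrix(ts)
    if (nrow(ts) < 3) stopf("need at least 3 retained frames")
    v <- apply(ts, 2, var)
    if (any(v == 0)) {
        bad <- colnames(ts)[v == 0] %||% which(v == 0)
        stopf("zero-variance ROI(s): %s", paste(bad, collapse = ", "))
    }
    M <- cor(ts)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
}

#' Element-wise mean of subject connectivity matrices
#'
#' Correlations are averaged directly (no Fisher transform), matching the
#' group-matrix construction of the analysis design.
#'
#' @param matrices list of equally-sized symmetric matrices.
#' @return the group-mean connectivity matrix.
#' @export
group_average <- function(matrices) {
    if (length(matrices) == 0) stopf("no matrices supplied")
    dims <- vapply(matrices, function(m) dim(m), integer(2))
    if (any(dims != dims[, 1])) stopf("matrices must share dimensions")
    out <- Reduce(`+`, matrices) / length(matrices)
    diag(out) <- 1
    out
}

#' Preprocess one subject end to end
#'
#' Convenience wrapper: FD, censor mask, projection cleaning, correlation.
#'
#' @param ts raw `frames x ROIs` matrix.
#' @param motion a `motion_trace` or NULL.
#' @param fd_thresh,outlier_thresh censoring thresholds.
#' @param band,tr filter settings.
#' @param head_radius_mm FD rotation radius.
#' @return list: `M` (connectivity matrix), `mask`, `clean` (residual series).
#' @export
preprocess_subject <- function(ts, motion = NULL, fd_thresh = 0.3,
                               outlier_thresh = 0.10, band = c(0.01, 0.1),
                               tr = 2.0, head_radius_mm = 50) {
    mask <- NULL
    confounds <- NULL
    if (!is.null(motion)) {
        fd <- framewise_displacement(motion, head_radius_mm)
        mask <- build_censor_mask(fd, motion$outlier_fraction,
                                  fd_thresh, outlier_thresh)
        confounds <- motion$params
        # drop constant motion columns (e.g. all-zero rotations)
        keep <- apply(confounds, 2, function(col) sd(col[mask$retain]) > 1e-12)
        confounds <- if (any(keep)) confounds[, keep, drop = FALSE] else NULL
    }
    clean <- clean_timeseries(ts, confounds = confounds, mask = mask,
                              band = band, tr = tr)
    list(M = correlation_matrix(clean), mask = mask, clean = clean)
}
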