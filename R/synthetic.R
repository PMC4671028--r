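#' Synthetic cohort specification
#'
#' Describes a simulated resting-state cohort: per-subject ROI time series
#' with planted modular correlation structure, a handful of cross-module hub
#' regions, and motion traces with occasional spikes. Defaults emulate the
#' target study design: 60 subjects, 90 ROIs, 196 retained frames at
#' TR = 2 s, four modules of sizes 26/26/18/20.
#'
#' The generative model for ROI `i` in module `m` is
#' `x_i(t) = sqrt(w - b) s_m(t) + sqrt(b) gl(t) + noise_sd * eps_i(t)`,
#' with unit-variance module latents `s_m`, a global latent `gl`, white (or
#' band-limited) noise, `w = within_module_r` and `b = between_module_r`.
#' With the default `noise_sd = sqrt(1 - w)` the expected Pearson correlation
#' is exactly `w` within modules and `b` across modules. Hub ROIs get an
#' extra loading `sqrt(hub_r / (M - 1))` on every other module's latent
#' (noise rescaled to keep unit variance), which raises their cross-module
#' correlations and so their degree and betweenness after thresholding.
#'
#' @param n_subjects,n_rois,n_frames cohort dimensions.
#' @param module_sizes integer vector summing to `n_rois`.
#' @param within_module_r,between_module_r target Pearson correlations within
#'   and between modules; `0 <= between < within < 1`.
#' @param hub_fraction fraction of ROIs planted as cross-module hubs.
#' @param hub_r extra cross-module correlation budget given to each hub.
#' @param noise_sd noise standard deviation; default `sqrt(1 - within_module_r)`
#'   calibrates raw correlations to the stated targets.
#' @param tr_seconds repetition time.
#' @param band_limited if `TRUE` (default) latents and noise are synthesized
#'   inside the 0.01-0.1 Hz analysis band, making the band-pass stage a
#'   near-no-op on clean data.
#' @param spike_prob,spike_mm motion-spike probability per frame and spike
#'   displacement; the default 0.11 / 0.5 mm yields censoring bookkeeping of
#'   roughly 23 dropped frames per subject.
#' @param seed master RNG seed for the cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60, n_rois = 90, n_frames = 196,
                        module_sizes = c(26, 26, 18, 20),
                        within_module_r = 0.5, between_module_r = 0.1,
                        hub_fraction = 0.1, hub_r = 0.15,
                        noise_sd = NULL, tr_seconds = 2.0,
                        band_limited = TRUE,
                        spike_prob = 0.11, spike_mm = 0.5,
                        seed = 1L) {
    if (sum(module_sizes) != n_rois) {
        stopf("module_sizes must sum to n_rois (%d != %d)",
              sum(module_sizes), n_rois)
    }
    if (!(between_module_r >= 0 && between_module_r < within_module_r &&
          within_module_r < 1)) {
        stopf("need 0 <= between_module_r < within_module_r < 1")
    }
    if (n_frames < 2) stopf("n_frames must be >= 2")
    if (is.null(noise_sd)) noise_sd <- sqrt(1 - within_module_r)
    structure(list(n_subjects = n_subjects, n_rois = n_rois,
                   n_frames = n_frames, module_sizes = module_sizes,
                   within_module_r = within_module_r,
                   between_module_r = between_module_r,
                   hub_fraction = hub_fraction, hub_r = hub_r,
                   noise_sd = noise_sd, tr_seconds = tr_seconds,
                   band_limited = band_limited,
                   spike_prob = spike_prob, spike_mm = spike_mm,
                   seed = as.integer(seed)),
              class = "cohort_spec")
}

# module label per ROI, and planted hub indices (spread evenly over modules)
module_labels <- function(spec) {
    rep(seq_along(spec$module_sizes), spec$module_sizes)
}

planted_hubs <- function(spec) {
    n_hubs <- round(spec$hub_fraction * spec$n_rois)
    if (n_hubs == 0) return(integer(0))
    labels <- module_labels(spec)
    mods <- seq_along(spec$module_sizes)
    # round-robin over modules, taking the first ROIs of each
    picks <- integer(0)
    depth <- 1L
    while (length(picks) < n_hubs) {
        for (m in mods) {
            cand <- which(labels == m)
            if (depth <= length(cand) && length(picks) < n_hubs) {
                picks <- c(picks, cand[depth])
            }
        }
        depth <- depth + 1L
    }
    sort(picks)
}

# unit-variance band-limited (0.01-0.1 Hz) or white signals, n x k
latent_signals <- function(n_frames, k, tr, band_limited) {
    if (!band_limited) {
        return(matrix(rnorm(n_frames * k), n_frames, k))
    }
    t_sec <- (seq_len(n_frames) - 1) * tr
    total <- n_frames * tr
    freqs <- seq_len(floor(n_frames / 2)) / total
    keep <- freqs > 0.01 & freqs < 0.1
    f <- freqs[keep]
    out <- vapply(seq_len(k), function(j) {
        amp <- rnorm(length(f))
        phase <- runif(length(f), 0, 2 * pi)
        x <- rowSums(sapply(seq_along(f), function(i)
            amp[i] * sin(2 * pi * f[i] * t_sec + phase[i])))
        as.numeric(scale(x))
    }, numeric(n_frames))
    matrix(out, n_frames, k)
}

#' Generate one subject's ROI time series
#'
#' @param spec a [cohort_spec()].
#' @param seed subject-level seed.
#' @return `n_frames x n_rois` matrix with ROI labels as column names.
#' @export
generate_subject_timeseries <- function(spec, seed = NULL) {
    with_seed(seed, {
        n <- spec$n_frames
        p <- spec$n_rois
        labels <- module_labels(spec)
        M <- length(spec$module_sizes)
        hubs <- planted_hubs(spec)
        w <- spec$within_module_r
        b <- spec$between_module_r
        lat <- latent_signals(n, M, spec$tr_seconds, spec$band_limited)
        gl <- latent_signals(n, 1, spec$tr_seconds, spec$band_limited)[, 1]
        noise <- latent_signals(n, p, spec$tr_seconds, spec$band_limited)
        ts <- matrix(0, n, p)
        hub_load <- if (M > 1) sqrt(spec$hub_r / (M - 1)) else 0
        for (i in seq_len(p)) {
            x <- sqrt(w - b) * lat[, labels[i]] + sqrt(b) * gl
            sig_var <- w
            if (i %in% hubs && M > 1) {
                others <- setdiff(seq_len(M), labels[i])
                x <- x + hub_load * rowSums(lat[, others, drop = FALSE])
                sig_var <- sig_var + spec$hub_r
            }
            # noise sd shrinks for hubs to keep total variance near 1;
            # scales linearly with the user's noise_sd relative to its default
            nv <- sqrt(max(1 - sig_var, 0.05)) / sqrt(1 - w)
            ts[, i] <- x + spec$noise_sd * nv * noise[, i]
        }
        colnames(ts) <- sprintf("ROI_%03d", seq_len(p))
        ts
    })
}

#' Generate a synthetic motion trace
#'
#' Baseline motion is exactly zero; at spike frames the head position jumps
#' by `spike_mm` along one randomly chosen translation axis (and stays), so
#' framewise displacement shows an isolated spike of magnitude `spike_mm`.
#' An outlier-voxel fraction series is returned alongside: a small baseline
#' (uniform on `[0, 0.05]`) with occasional excursions above the 10%
#' censoring threshold.
#'
#' @param n_frames number of frames.
#' @param spike_prob per-frame probability of a motion spike.
#' @param spike_mm spike displacement in mm (>= 0).
#' @param outlier_spike_prob per-frame probability of an outlier excursion.
#' @param seed RNG seed.
#' @return list of class `motion_trace`: `params` (`n_frames x 6`,
#'   translations mm then rotations radians) and `outlier_fraction`.
#' @export
generate_motion <- function(n_frames, spike_prob = 0.11, spike_mm = 0.5,
                            outlier_spike_prob = 0.01, seed = NULL) {
    if (spike_mm < 0) stopf("spike_mm must be >= 0")
    with_seed(seed, {
        params <- matrix(0, n_frames, 6,
                         dimnames = list(NULL, c("tx", "ty", "tz",
                                                 "rx", "ry", "rz")))
        spikes <- which(runif(n_frames) < spike_prob)
        spikes <- setdiff(spikes, 1L) # frame 1 has no backward difference
        if (spike_mm > 0) {
            for (s in spikes) {
                axis <- sample(1:3, 1)
                params[s:n_frames, axis] <- params[s:n_frames, axis] + spike_mm
            }
        }
        outlier <- runif(n_frames, 0, 0.05)
        out_spikes <- which(runif(n_frames) < outlier_spike_prob)
        outlier[out_spikes] <- runif(length(out_spikes), 0.10, 0.30)
        structure(list(params = params, outlier_fraction = outlier),
                  class = "motion_trace")
    })
}

#' Generate the full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`: one element per subject, each a list with
#'   `ts` (frames x ROIs) and `motion` (a `motion_trace`), plus the spec as
#'   an attribute. Deterministic for a fixed `spec$seed`.
#' @export
generate_cohort <- function(spec) {
    stopifnot(inherits(spec, "cohort_spec"))
    seeds <- child_seeds(spec$seed, 2 * spec$n_subjects)
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
        list(ts = generate_subject_timeseries(spec, seed = seeds[2 * s - 1]),
             motion = generate_motion(spec$n_frames,
                                      spike_prob = spec$spike_prob,
                                      spike_mm = spec$spike_mm,
                                      seed = seeds[2 * s]))
    })
    names(subjects) <- sprintf("sub%03d", seq_len(spec$n_subjects))
    structure(subjects, class = "cohort", spec = spec)
}

#' Reference graphs of known topology
#'
#' Deterministic and random fixtures used to validate the graph metrics:
#' ring lattices, Watts-Strogatz small-world graphs, Erdos-Renyi random
#' graphs, Barabasi-Albert scale-free graphs, stars, complete graphs, and
#' paths.
#'
#' @param kind one of `"ring_lattice"`, `"ws_small_world"`, `"er_random"`,
#'   `"ba_scale_free"`, `"star"`, `"complete"`, `"path"`.
#' @param n node count.
#' @param params kind-specific parameters: `edges` (ring_lattice),
#'   `neighbors` + `p_rewire` (ws_small_world), `edges` or `p` (er_random),
#'   `density` (ba_scale_free).
#' @param seed RNG seed for the stochastic kinds.
#' @return a [binary_graph()].
#' @export
generate_reference_graph <- function(kind, n, params = list(), seed = NULL) {
    kind <- match.arg(kind, c("ring_lattice", "ws_small_world", "er_random",
                              "ba_scale_free", "star", "complete", "path"))
    max_e <- n * (n - 1) / 2
    switch(kind,
        ring_lattice = {
            e <- params$edges %||% (2L * n)
            lattice_graph(n, e)
        },
        ws_small_world = {
            k <- params$neighbors %||% 4L # per-side-total even degree
            p <- params$p_rewire %||% 0.1
            ws_graph(n, k, p, seed)
        },
        er_random = {
            e <- params$edges %||% round((params$p %||% 0.1) * max_e)
            if (e > max_e) stopf("edges > n(n-1)/2")
            with_seed(seed, {
                idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
                pick <- sample(nrow(idx), e)
                graph_from_edges(idx[pick, , drop = FALSE], n,
                                 provenance = list(scheme = "er", value = e))
            })
        },
        ba_scale_free = scale_free_graph(n, params$density %||% 0.1, seed),
        star = {
            graph_from_edges(cbind(1L, 2:n), n,
                             provenance = list(scheme = "star"))
        },
        complete = {
            a <- matrix(1L, n, n); diag(a) <- 0L
            binary_graph(a, provenance = list(scheme = "complete"))
        },
        path = {
            graph_from_edges(cbind(1:(n - 1), 2:n), n,
                             provenance = list(scheme = "path"))
        })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Watts-Strogatz: ring lattice with `k` neighbours per node (k even), each
# edge rewired with probability p to a uniform non-duplicate endpoint.
ws_graph <- function(n, k, p, seed = NULL) {
    if (k %% 2 != 0) stopf("ws_small_world needs an even neighbor count")
    g <- lattice_graph(n, n * k / 2)
    with_seed(seed, {
        a <- g$adjacency
        e <- edge_list(g)
        for (r in seq_len(nrow(e))) {
            if (runif(1) < p) {
                i <- e[r, 1]; j <- e[r, 2]
                cand <- which(a[i, ] == 0L)
                cand <- setdiff(cand, i)
                if (length(cand) > 0) {
                    jj <- cand[sample.int(length(cand), 1)]
                    a[i, j] <- a[j, i] <- 0L
                    a[i, jj] <- a[jj, i] <- 1L
                }
            }
        }
        binary_graph(a, provenance = list(scheme = "ws", value = p))
    })
}

#' Draw a synthetic degree sequence from a named law
#'
#' Samples integer degrees `k >= 1` from a discrete power law
#' `p(k) ~ k^-alpha`, an exponential `p(k) ~ exp(-rate k)`, or an
#' exponentially truncated power law `p(k) ~ k^(alpha - 1) exp(-k / kc)`
#' (decaying cutoff), truncated at `k_max`.
#'
#' @param model one of `"power_law"`, `"exponential"`,
#'   `"truncated_power_law"`.
#' @param params list: `alpha` (power law), `rate` (exponential),
#'   `alpha` + `kc` (truncated).
#' @param n sequence length.
#' @param k_max support upper bound (default 1000).
#' @param seed RNG seed.
#' @return integer vector of length `n`.
#' @export
generate_degree_sequence <- function(model = c("power_law", "exponential",
                                               "truncated_power_law"),
                                     params = list(), n = 90,
                                     k_max = 1000L, seed = NULL) {
    model <- match.arg(model)
    k <- seq_len(k_max)
    pmf <- switch(model,
        power_law = k^(-(params$alpha %||% 2.0)),
        exponential = exp(-(params$rate %||% 0.1) * k),
        truncated_power_law = k^((params$alpha %||% 1.8) - 1) *
            exp(-k / (params$kc %||% 10)))
    pmf <- pmf / sum(pmf)
    with_seed(seed, sample(k, n, replace = TRUE, prob = pmf))
}
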