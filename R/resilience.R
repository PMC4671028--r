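attack_curve_row <- function(n_original, remaining_adj, n_removed, e0) {
    if (length(remaining_adj) == 0 || nrow(remaining_adj) == 0) {
        return(c(lcc_fraction = 0, lcc_fraction_remaining = NA,
                 eglob = 0, eglob_pct = 0))
    }
    g <- binary_graph(remaining_adj)
    comp <- cpp_components(g$adjacency)
    lcc <- max(tabulate(comp))
    eg <- global_efficiency(g)
    c(lcc_fraction = lcc / n_original,
      lcc_fraction_remaining = lcc / nrow(remaining_adj),
      eglob = eg,
      eglob_pct = if (e0 > 0) 100 * eg / e0 else NA_real_)
}

run_attack <- function(g, order, n_steps) {
    n <- n_nodes(g)
    e0 <- global_efficiency(g)
    rows <- matrix(NA_real_, n_steps + 1, 4)
    rows[1, ] <- attack_curve_row(n, g$adjacency, 0, e0)
    remaining <- seq_len(n)
    for (s in seq_len(n_steps)) {
        remaining <- setdiff(remaining, order[s])
        rows[s + 1, ] <- attack_curve_row(
            n, g$adjacency[remaining, remaining, drop = FALSE], s, e0)
    }
    out <- as.data.frame(rows)
    names(out) <- c("lcc_fraction", "lcc_fraction_remaining",
                    "eglob", "eglob_pct")
    cbind(n_removed = 0:n_steps, out)
}

#' Targeted attack on high-centrality nodes
#'
#' Removes nodes one by one in descending centrality of the intact graph
#' (static ranking by default; set `recompute = TRUE` to re-rank after each
#' removal). After each removal the largest-connected-component fraction
#' (relative to the original N, with the remaining-node convention reported
#' alongside) and the global efficiency of the remaining graph (absolute and
#' as a percentage of the intact value) are recorded. Ranking ties are
#' broken by node index ascending.
#'
#' @param g a [binary_graph()].
#' @param strategy `"degree"` or `"betweenness"`.
#' @param n_steps removals to perform (default `N - 1`).
#' @param recompute re-rank centralities after each removal.
#' @return data.frame of class `attack_curve` with one row per step
#'   (including step 0).
#' @export
targeted_attack <- function(g, strategy = c("degree", "betweenness"),
                            n_steps = n_nodes(g) - 1, recompute = FALSE) {
    strategy <- match.arg(strategy)
    cent_fun <- switch(strategy,
                       degree = function(gg) rowSums(gg$adjacency),
                       betweenness = function(gg) cpp_betweenness(gg$adjacency))
    n <- n_nodes(g)
    e0 <- global_efficiency(g)
    if (!recompute) {
        cent <- cent_fun(g)
        order_nodes <- order(-cent, seq_len(n))
        curve <- run_attack(g, order_nodes, n_steps)
    } else {
        rows <- matrix(NA_real_, n_steps + 1, 4)
        rows[1, ] <- attack_curve_row(n, g$adjacency, 0, e0)
        remaining <- seq_len(n)
        for (s in seq_len(n_steps)) {
            sub <- binary_graph(g$adjacency[remaining, remaining, drop = FALSE])
            cent <- cent_fun(sub)
            victim <- remaining[order(-cent, seq_along(remaining))[1]]
            remaining <- setdiff(remaining, victim)
            rows[s + 1, ] <- attack_curve_row(
                n, g$adjacency[remaining, remaining, drop = FALSE], s, e0)
        }
        curve <- as.data.frame(rows)
        names(curve) <- c("lcc_fraction", "lcc_fraction_remaining",
                          "eglob", "eglob_pct")
        curve <- cbind(n_removed = 0:n_steps, curve)
    }
    attr(curve, "strategy") <- strategy
    class(curve) <- c("attack_curve", class(curve))
    curve
}

#' Random node failure
#'
#' Averages the attack curve over `n_runs` independent uniformly random
#' removal orders.
#'
#' @param g a [binary_graph()].
#' @param n_runs number of random orders (>= 1).
#' @param n_steps removals per run (default `N - 1`).
#' @param seed master RNG seed.
#' @return data.frame of class `attack_curve` with per-step means across
#'   runs, plus `lcc_fraction_sd`.
#' @export
random_failure <- function(g, n_runs = 20, n_steps = n_nodes(g) - 1,
                           seed = NULL) {
    if (n_runs < 1) stopf("n_runs must be >= 1")
    n <- n_nodes(g)
    seeds <- if (is.null(seed)) rep(list(NULL), n_runs) else
        as.list(child_seeds(seed, n_runs))
    curves <- lapply(seq_len(n_runs), function(r) {
        ord <- with_seed(seeds[[r]], sample.int(n))
        run_attack(g, ord, n_steps)
    })
    out <- curves[[1]]
    for (col in c("lcc_fraction", "lcc_fraction_remaining",
                  "eglob", "eglob_pct")) {
        out[[col]] <- rowMeans(sapply(curves, function(cv) cv[[col]]))
    }
    out$lcc_fraction_sd <- apply(sapply(curves, function(cv) cv$lcc_fraction),
                                 1, sd)
    attr(out, "strategy") <- "random"
    attr(out, "n_runs") <- n_runs
    class(out) <- c("attack_curve", class(out))
    out
}

#' Isolated single-node removal sweep
#'
#' For each node, removes that node (alone) and reports the percent change
#' in global efficiency relative to the intact graph,
#' `100 * (Eglob(G - i) - Eglob(G)) / Eglob(G)`. The table is sorted
#' ascending so the most harmful removals come first.
#'
#' @param g a [binary_graph()] with at least 3 nodes.
#' @return data.frame of class `isolated_removal_table`: `node`, `label`,
#'   `delta_eglob_pct`, sorted ascending by `delta_eglob_pct`.
#' @export
isolated_removal_sweep <- function(g) {
    n <- n_nodes(g)
    if (n < 3) stopf("need at least 3 nodes")
    e0 <- global_efficiency(g)
    if (e0 == 0) stopf("intact graph has zero global efficiency")
    delta <- vapply(seq_len(n), function(i) {
        keep <- setdiff(seq_len(n), i)
        ei <- global_efficiency(
            binary_graph(g$adjacency[keep, keep, drop = FALSE]))
        100 * (ei - e0) / e0
    }, numeric(1))
    out <- data.frame(node = seq_len(n), label = g$labels,
                      delta_eglob_pct = delta)
    out <- out[order(out$delta_eglob_pct, out$node), ]
    rownames(out) <- NULL
    class(out) <- c("isolated_removal_table", class(out))
    out
}

# resolve a hub-class argument into per-group delta-Eglob entries.
# `hubs` is either an integer node set (used as is) or a length-N centrality
# vector from which the top `top_fraction` nodes are taken; centrality ties
# spanning the selection boundary are collapsed into ONE entry holding the
# mean delta-Eglob of the tied nodes.
hub_class_values <- function(table, hubs, n, top_fraction) {
    delta <- table$delta_eglob_pct[order(table$node)]
    if (inherits(hubs, "hub_report")) hubs <- hubs$hubs
    if (length(hubs) == n) {
        cent <- as.numeric(hubs)
        n_take <- ceiling(top_fraction * n)
        ord <- order(-cent, seq_len(n))
        boundary <- cent[ord[n_take]]
        above <- which(cent > boundary)
        tied <- which(cent == boundary)
        vals <- delta[above]
        if (length(tied) > 0 && (length(above) + length(tied)) > n_take) {
            vals <- c(vals, mean(delta[tied])) # tie block averaged, one entry
        } else {
            vals <- c(vals, delta[tied])
        }
        vals
    } else {
        delta[hubs]
    }
}

#' Compare efficiency loss between degree and betweenness hub classes
#'
#' Welch two-sample t-test on the per-node percent global-efficiency change
#' (from [isolated_removal_sweep()]) of two hub classes. Each class may be
#' given as an explicit node set (e.g. from [identify_hubs()]) or as a
#' full-length centrality vector, in which case the top `top_fraction`
#' nodes are selected and centrality ties straddling the selection boundary
#' are averaged into a single entry.
#'
#' @param table an [isolated_removal_sweep()] result.
#' @param degree_hubs,betweenness_hubs node sets or centrality vectors.
#' @param top_fraction selection fraction for the centrality-vector form.
#' @return list: per-class `mean`, `sd`, `n`, plus `t`, `df`, `p_value`.
#' @export
compare_hub_classes <- function(table, degree_hubs, betweenness_hubs,
                                top_fraction = 0.20) {
    n <- nrow(table)
    x <- hub_class_values(table, degree_hubs, n, top_fraction)
    y <- hub_class_values(table, betweenness_hubs, n, top_fraction)
    if (length(x) < 2 || length(y) < 2) stopf("hub classes must have >= 2 entries")
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    if (isTRUE(all.equal(sort(x), sort(y)))) {
        tt <- list(statistic = c(t = 0), parameter = c(df = NA), p.value = 1)
    } else if (se < 1e-12 * max(1, abs(mean(x) - mean(y)))) {
        # perfectly separated constant groups: infinite t, zero p
        tt <- list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                   parameter = c(df = NA), p.value = 0)
    } else {
        tt <- t.test(x, y)
    }
    list(degree = list(mean = mean(x), sd = sd(x), n = length(x)),
         betweenness = list(mean = mean(y), sd = sd(y), n = length(y)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}
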