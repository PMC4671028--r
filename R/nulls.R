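#' Degree-preserving randomization
#'
#' Randomizes a graph by Maslov-Sneppen double-edge swaps: two edges (a,b)
#' and (c,d) are repeatedly replaced by (a,d),(c,b) (orientation chosen at
#' random), rejecting swaps that would create self-loops or multi-edges.
#' Every node keeps its degree exactly. `swaps_per_edge * E` swap attempts
#' are made.
#'
#' @param g a [binary_graph()].
#' @param swaps_per_edge attempted swaps per edge (default 10, a standard
#'   mixing heuristic).
#' @param seed RNG seed (optional; uses the session RNG state when `NULL`).
#' @return a rewired [binary_graph()] with the same degree sequence.
#' @export
rewire_degree_preserving <- function(g, swaps_per_edge = 10, seed = NULL) {
    e <- edge_list(g)
    if (nrow(e) < 2) {
        warnf("graph has fewer than 2 edges; returning it unchanged")
        return(g)
    }
    attempts <- as.integer(ceiling(swaps_per_edge * nrow(e)))
    e2 <- with_seed(seed, cpp_rewire(e, n_nodes(g), attempts))
    out <- graph_from_edges(e2, n_nodes(g), labels = g$labels,
                            provenance = list(scheme = "rewired",
                                              source = g$provenance))
    stopifnot(identical(sort(rowSums(out$adjacency)),
                        sort(rowSums(g$adjacency))))
    out
}

#' Ring-lattice benchmark graph
#'
#' Places `E` edges by filling nearest-neighbour rings outward: first all
#' (i, i+1) pairs around the ring, then (i, i+2), and so on, truncating the
#' outermost ring so exactly `E` edges are placed.
#'
#' @param n node count.
#' @param e edge count, at most `n(n-1)/2`.
#' @return a [binary_graph()].
#' @export
lattice_graph <- function(n, e) {
    if (!is_count(n) || n < 2) stopf("n must be a count >= 2")
    max_e <- n * (n - 1) / 2
    if (e > max_e) stopf("e exceeds n(n-1)/2 = %d", max_e)
    edges <- matrix(integer(0), 0, 2)
    placed <- 0L
    offset <- 1L
    while (placed < e) {
        ring <- cbind(seq_len(n), (seq_len(n) + offset - 1L) %% n + 1L)
        ring <- t(apply(ring, 1, sort))
        ring <- unique(ring)
        take <- min(nrow(ring), e - placed)
        edges <- rbind(edges, ring[seq_len(take), , drop = FALSE])
        placed <- placed + take
        offset <- offset + 1L
    }
    graph_from_edges(edges, n, provenance = list(scheme = "lattice", value = e))
}

# Barabasi-Albert attachment parameter whose realized edge count
# (n - m) * m best matches the target density.
ba_attachment_for_density <- function(n, target_density) {
    n_possible <- n * (n - 1) / 2
    cand <- seq_len(n - 1)
    realized <- (n - cand) * cand / n_possible
    cand[which.min(abs(realized - target_density))]
}

#' Preferential-attachment (scale-free) comparison graph
#'
#' Barabasi-Albert construction: `m` seed nodes, each subsequent node
#' attaching `m` edges to existing nodes with probability proportional to
#' degree (the first added node connects to all seeds). `m` is chosen so the
#' realized edge count `(n - m) m` is closest to the target density.
#'
#' @param n node count.
#' @param target_density desired fraction of possible edges.
#' @param seed RNG seed.
#' @return a [binary_graph()] with a heavy-tailed degree sequence.
#' @export
scale_free_graph <- function(n, target_density, seed = NULL) {
    if (!is_count(n) || n < 3) stopf("n must be a count >= 3")
    m <- ba_attachment_for_density(n, target_density)
    with_seed(seed, {
        a <- matrix(0L, n, n)
        deg <- integer(n)
        # first attached node links to every seed node
        first <- m + 1L
        a[first, 1:m] <- a[1:m, first] <- 1L
        deg[1:m] <- 1L
        deg[first] <- m
        if (first < n) {
            for (v in (first + 1L):n) {
                pool <- seq_len(v - 1L)
                targets <- sample(pool, size = m, prob = deg[pool])
                a[v, targets] <- a[targets, v] <- 1L
                deg[targets] <- deg[targets] + 1L
                deg[v] <- m
            }
        }
        binary_graph(a, provenance = list(scheme = "ba", value = m))
    })
}

#' Degree-preserving latticization
#'
#' The lattice counterpart of [rewire_degree_preserving()]: the same
#' double-edge-swap walk, but swaps are accepted only when they do not
#' increase the total ring distance of the swapped edges, so edges migrate
#' toward the ring diagonal while every node keeps its degree. This is the
#' stochastic "lattice network" benchmark used when 20 distinct lattice
#' comparisons per graph are required (a deterministic ring lattice cannot
#' supply an ensemble).
#'
#' @inheritParams rewire_degree_preserving
#' @return a latticized [binary_graph()] with the same degree sequence.
#' @export
latticize_degree_preserving <- function(g, swaps_per_edge = 10, seed = NULL) {
    e <- edge_list(g)
    if (nrow(e) < 2) {
        warnf("graph has fewer than 2 edges; returning it unchanged")
        return(g)
    }
    attempts <- as.integer(ceiling(swaps_per_edge * nrow(e)))
    e2 <- with_seed(seed, cpp_latticize(e, n_nodes(g), attempts))
    out <- graph_from_edges(e2, n_nodes(g), labels = g$labels,
                            provenance = list(scheme = "latticized",
                                              source = g$provenance))
    stopifnot(identical(sort(rowSums(out$adjacency)),
                        sort(rowSums(g$adjacency))))
    out
}

#' Null/comparison ensembles
#'
#' Generates a list of graphs matched to `g`: degree-preserving rewired
#' randomizations, ring lattices at the same (N, E), or preferential-
#' attachment graphs at the same density. Defaults follow the analysis
#' design: 100 rewired nulls per correlation/degree threshold and 20 random
#' plus 20 lattice comparison graphs per cost threshold.
#'
#' @param g source [binary_graph()].
#' @param kind one of `"rewired_random"`, `"lattice"`, `"scale_free"`.
#' @param size ensemble size.
#' @param seed master seed; member seeds are spawned from it.
#' @return list of [binary_graph()] (for `"lattice"`, identical members are
#'   returned since the construction is deterministic).
#' @export
null_ensemble <- function(g, kind = c("rewired_random", "lattice",
                                      "latticized", "scale_free"),
                          size = 100, seed = NULL) {
    kind <- match.arg(kind)
    seeds <- if (is.null(seed)) rep(list(NULL), size) else
        as.list(child_seeds(seed, size))
    lapply(seq_len(size), function(i) {
        switch(kind,
               rewired_random = rewire_degree_preserving(g, seed = seeds[[i]]),
               lattice = lattice_graph(n_nodes(g), n_edges(g)),
               latticized = latticize_degree_preserving(g, seed = seeds[[i]]),
               scale_free = scale_free_graph(n_nodes(g), network_cost(g),
                                             seed = seeds[[i]]))
    })
}
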