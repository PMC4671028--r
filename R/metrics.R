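#' Clustering coefficient
#'
#' Per-node clustering is the fraction of a node's neighbour pairs that are
#' themselves connected, `t_i / (k_i (k_i - 1) / 2)`; nodes with degree < 2
#' contribute 0. The summary mean is taken over the nodes of the largest
#' connected component, matching the component rule used for path length.
#'
#' @param g a [binary_graph()].
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
clustering_coefficient <- function(g) {
    a <- g$adjacency
    k <- rowSums(a)
    # rowSums((A %*% A) * A) counts 2 * triangles through each node
    tri <- rowSums((a %*% a) * a) / 2
    cc <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
    names(cc) <- g$labels
    lc <- largest_component(g)
    list(per_node = cc, mean = mean(cc[lc$nodes]))
}

#' Characteristic path length
#'
#' Mean geodesic distance over all unordered node pairs within the largest
#' connected component.
#'
#' @param g a [binary_graph()].
#' @return scalar L, or `NA` when the largest component is a singleton.
#' @export
characteristic_path_length <- function(g) {
    lc <- largest_component(g)
    if (length(lc$nodes) < 2) return(NA_real_)
    D <- cpp_all_pairs_dist(lc$graph$adjacency)
    mean(D[upper.tri(D)])
}

#' Global efficiency
#'
#' Mean inverse geodesic distance over all node pairs of the full graph;
#' disconnected pairs contribute 0, so fragmentation lowers efficiency.
#'
#' @param g a [binary_graph()].
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
    n <- n_nodes(g)
    if (n < 2) return(0)
    D <- cpp_all_pairs_dist(g$adjacency)
    d <- D[upper.tri(D)]
    inv <- ifelse(d > 0, 1 / d, 0)
    mean(inv)
}

#' Local efficiency
#'
#' Mean, over all nodes, of the global efficiency of the subgraph induced by
#' each node's neighbours; nodes with fewer than two neighbours contribute 0.
#'
#' @param g a [binary_graph()].
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
    a <- g$adjacency
    n <- n_nodes(g)
    vals <- vapply(seq_len(n), function(i) {
        nb <- which(a[i, ] == 1L)
        if (length(nb) < 2) return(0)
        sub <- a[nb, nb, drop = FALSE]
        D <- cpp_all_pairs_dist(sub)
        d <- D[upper.tri(D)]
        mean(ifelse(d > 0, 1 / d, 0))
    }, numeric(1))
    mean(vals)
}

#' Betweenness centrality
#'
#' Brandes' algorithm on the unweighted graph: for each node, the number of
#' shortest paths between other node pairs passing through it, with fractional
#' credit when a pair has several shortest paths. Values are unnormalized and
#' endpoints are excluded; each unordered pair is credited once.
#'
#' @param g a [binary_graph()].
#' @return named numeric vector of length N.
#' @export
betweenness <- function(g) {
    b <- cpp_betweenness(g$adjacency)
    names(b) <- g$labels
    b
}

#' Network cost
#'
#' Fraction of possible edges present, `E / (N(N-1)/2)`.
#'
#' @param g a [binary_graph()].
#' @export
network_cost <- function(g) {
    n <- n_nodes(g)
    if (n < 2) stopf("network cost needs at least 2 nodes")
    n_edges(g) / (n * (n - 1) / 2)
}

#' Small-world and cost-efficiency summary
#'
#' Combines a graph's clustering and path length with the corresponding null
#' ensemble means into the normalized quantities gamma = C/C_null,
#' lambda = L/L_null, the small-world index sigma = gamma/lambda, and
#' cost efficiency = Eglob - cost.
#'
#' @param C,L clustering coefficient and characteristic path length.
#' @param null_C_mean,null_L_mean means over the matched null ensemble.
#' @param Eglob global efficiency; `cost` network cost.
#' @return list with `gamma`, `lambda`, `sigma`, `cost_efficiency`.
#' @export
small_world_summary <- function(C, L, null_C_mean, null_L_mean, Eglob, cost) {
    if (is.na(null_C_mean) || is.na(null_L_mean) ||
        null_C_mean <= 0 || null_L_mean <= 0) {
        stopf("null ensemble means must be positive")
    }
    gamma <- C / null_C_mean
    lambda <- L / null_L_mean
    list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         cost_efficiency = Eglob - cost)
}

#' All standard metrics for one graph
#'
#' @param g a [binary_graph()].
#' @param include_betweenness compute betweenness too (slower).
#' @return list with per-node `degree`, `clustering`, optionally
#'   `betweenness`, and scalars `C`, `L`, `Eglob`, `Eloc`, `cost`,
#'   `lcc_fraction`.
#' @export
graph_metrics <- function(g, include_betweenness = FALSE) {
    cc <- clustering_coefficient(g)
    lc <- largest_component(g)
    out <- list(degree = degrees(g),
                clustering = cc$per_node,
                C = cc$mean,
                L = characteristic_path_length(g),
                Eglob = global_efficiency(g),
                Eloc = local_efficiency(g),
                cost = network_cost(g),
                lcc_fraction = lc$fraction)
    if (include_betweenness) out$betweenness <- betweenness(g)
    out
}
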