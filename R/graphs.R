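#' Binary graph objects
#'
#' The package represents thresholded functional networks as plain undirected,
#' unweighted graphs: a symmetric 0/1 adjacency matrix with a zero diagonal,
#' node labels, and a provenance record describing the thresholding rule that
#' produced the graph.
#'
#' @param adjacency square numeric/integer matrix; coerced to 0/1. Must be
#'   symmetric with a zero diagonal.
#' @param labels optional character vector of node labels; defaults to the
#'   matrix dimnames or `"ROI_001"`-style labels.
#' @param provenance optional list describing how the graph was built
#'   (scheme, threshold value, source).
#' @return An object of class `binary_graph`: a list with elements
#'   `adjacency` (integer matrix), `labels`, and `provenance`.
#' @examples
#' g <- binary_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' n_edges(g)
#' @export
binary_graph <- function(adjacency, labels = NULL, provenance = NULL) {
    adjacency <- as.matrix(adjacency)
    if (nrow(adjacency) != ncol(adjacency)) {
        stopf("adjacency must be square, got %d x %d", nrow(adjacency), ncol(adjacency))
    }
    a <- matrix(as.integer(adjacency != 0), nrow(adjacency), ncol(adjacency))
    diag(a) <- 0L
    if (!isTRUE(all.equal(a, t(a)))) stopf("adjacency must be symmetric")
    if (is.null(labels)) {
        labels <- rownames(adjacency)
        if (is.null(labels)) {
            labels <- sprintf("ROI_%03d", seq_len(nrow(a)))
        }
    }
    if (length(labels) != nrow(a)) stopf("labels length != node count")
    dimnames(a) <- list(labels, labels)
    structure(list(adjacency = a, labels = labels, provenance = provenance),
              class = "binary_graph")
}

#' @rdname binary_graph
#' @param g a `binary_graph`
#' @export
n_nodes <- function(g) nrow(g$adjacency)

#' @rdname binary_graph
#' @export
n_edges <- function(g) sum(g$adjacency) %/% 2L

#' @rdname binary_graph
#' @export
degrees <- function(g) {
    k <- rowSums(g$adjacency)
    names(k) <- g$labels
    k
}

#' @export
print.binary_graph <- function(x, ...) {
    cat(sprintf("<binary_graph> %d nodes, %d edges", n_nodes(x), n_edges(x)))
    if (!is.null(x$provenance$scheme)) {
        cat(sprintf(" [%s = %s]", x$provenance$scheme,
                    format(x$provenance$value, digits = 4)))
    }
    cat("\n")
    invisible(x)
}

# Build a graph from a 1-based E x 2 edge matrix.
graph_from_edges <- function(edges, n, labels = NULL, provenance = NULL) {
    a <- matrix(0L, n, n)
    if (NROW(edges) > 0) {
        edges <- as.matrix(edges)
        a[edges] <- 1L
        a[edges[, c(2, 1), drop = FALSE]] <- 1L
    }
    binary_graph(a, labels = labels, provenance = provenance)
}

edge_list <- function(g) {
    idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

check_connectivity_matrix <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) != ncol(M)) stopf("connectivity matrix must be square")
    if (any(!is.finite(M))) stopf("connectivity matrix has non-finite entries")
    if (max(abs(M - t(M))) > 1e-8) stopf("connectivity matrix must be symmetric")
    M
}

#' Threshold a connectivity matrix by correlation value
#'
#' Places an edge wherever the (off-diagonal) correlation strictly exceeds
#' `r`. Negative correlations never become edges at non-negative thresholds.
#'
#' @param M symmetric correlation matrix (diagonal ignored).
#' @param r correlation threshold in `[0, 1)`.
#' @return a [binary_graph()].
#' @export
threshold_by_r <- function(M, r) {
    M <- check_connectivity_matrix(M)
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1) {
        stopf("r must be a single value in [0, 1)")
    }
    a <- (M > r) * 1L
    binary_graph(a, labels = rownames(M),
                 provenance = list(scheme = "r", value = r))
}

#' Threshold a connectivity matrix at a fixed network cost
#'
#' Retains the `round(cost * N(N-1)/2)` strongest off-diagonal weights as
#' edges. Ranking uses the signed weight (largest positive first); ties at
#' the cutoff are broken by node-pair lexicographic order so the result is
#' platform independent.
#'
#' @inheritParams threshold_by_r
#' @param cost fraction of possible edges to retain, in `(0, 1]`.
#' @export
threshold_by_cost <- function(M, cost) {
    M <- check_connectivity_matrix(M)
    if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1) {
        stopf("cost must be a single value in (0, 1]")
    }
    n <- nrow(M)
    n_possible <- n * (n - 1) / 2
    e_target <- round(cost * n_possible)
    idx <- which(upper.tri(M), arr.ind = TRUE)
    w <- M[idx]
    ord <- order(-w, idx[, 1], idx[, 2])
    keep <- ord[seq_len(min(e_target, length(ord)))]
    graph_from_edges(idx[keep, , drop = FALSE], n, labels = rownames(M),
                     provenance = list(scheme = "cost", value = cost))
}

#' Threshold a connectivity matrix at a target mean degree
#'
#' Equivalent to cost thresholding with `cost = k_target / (N - 1)`:
#' the retained edge count is `round(N * k_target / 2)`, so the realized
#' mean degree is within `2/N` of the target.
#'
#' @inheritParams threshold_by_r
#' @param k_target target mean degree, in `[2, N - 1]`.
#' @export
threshold_by_degree <- function(M, k_target) {
    M <- check_connectivity_matrix(M)
    n <- nrow(M)
    if (!is.numeric(k_target) || length(k_target) != 1L ||
        k_target < 2 || k_target > n - 1) {
        stopf("k_target must be in [2, N-1]")
    }
    g <- threshold_by_cost(M, k_target / (n - 1))
    g$provenance <- list(scheme = "k", value = k_target)
    g
}

#' Largest connected component
#'
#' @param g a [binary_graph()].
#' @return list with `nodes` (integer indices of the component, ascending),
#'   `fraction` (component size relative to the full node count), and
#'   `graph` (the induced subgraph). For an edgeless graph the convention is
#'   a singleton component containing the lowest-index node (`fraction = 1/N`).
#' @export
largest_component <- function(g) {
    comp <- cpp_components(g$adjacency)
    sizes <- tabulate(comp)
    big <- which.max(sizes) # ties: lowest label, i.e. earliest-discovered
    nodes <- which(comp == big)
    sub <- g$adjacency[nodes, nodes, drop = FALSE]
    list(nodes = nodes,
         fraction = length(nodes) / n_nodes(g),
         graph = binary_graph(sub, labels = g$labels[nodes],
                              provenance = g$provenance))
}

#' Default threshold grids
#'
#' The default analysis grids: 19 correlation thresholds from 0 to 0.45 in
#' steps of 0.025; 15 cost thresholds from 0.02 to 0.58 in steps of 0.04;
#' and 13 mean-degree targets spanning (6, 42) — evenly spaced from 9 to 39.
#'
#' @return numeric vector of threshold values.
#' @export
r_grid <- function() seq(0, 0.45, by = 0.025)

#' @rdname r_grid
#' @export
cost_grid <- function() seq(0.02, 0.60, by = 0.04)

#' @rdname r_grid
#' @export
k_grid <- function() unique(round(seq(9, 39, length.out = 13)))
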