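# Independent brute-force oracles for the graph metrics. These deliberately
# share no code with the package internals: distances via Floyd-Warshall,
# triangles by triple loop, betweenness by recursive shortest-path counting.

oracle_dist <- function(a) {
    n <- nrow(a)
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    D[a == 1] <- 1
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
}

oracle_clustering_nodes <- function(a) {
    n <- nrow(a)
    vapply(seq_len(n), function(i) {
        nb <- which(a[i, ] == 1)
        k <- length(nb)
        if (k < 2) return(0)
        tri <- 0
        for (x in seq_along(nb))
            for (y in seq_len(x - 1))
                if (a[nb[x], nb[y]] == 1) tri <- tri + 1
        tri / (k * (k - 1) / 2)
    }, numeric(1))
}

oracle_components <- function(a) {
    n <- nrow(a)
    comp <- rep(0L, n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] > 0) next
        cur <- cur + 1L
        frontier <- s
        comp[s] <- cur
        while (length(frontier) > 0) {
            nxt <- integer(0)
            for (v in frontier) {
                nb <- which(a[v, ] == 1 & comp == 0L)
                comp[nb] <- cur
                nxt <- c(nxt, nb)
            }
            frontier <- nxt
        }
    }
    comp
}

oracle_lcc_nodes <- function(a) {
    comp <- oracle_components(a)
    which(comp == which.max(tabulate(comp)))
}

oracle_C <- function(a) {
    mean(oracle_clustering_nodes(a)[oracle_lcc_nodes(a)])
}

oracle_L <- function(a) {
    nodes <- oracle_lcc_nodes(a)
    if (length(nodes) < 2) return(NA_real_)
    D <- oracle_dist(a[nodes, nodes, drop = FALSE])
    mean(D[upper.tri(D)])
}

oracle_eglob <- function(a) {
    n <- nrow(a)
    if (n < 2) return(0)
    D <- oracle_dist(a)
    d <- D[upper.tri(D)]
    mean(ifelse(is.finite(d) & d > 0, 1 / d, 0))
}

oracle_eloc <- function(a) {
    n <- nrow(a)
    mean(vapply(seq_len(n), function(i) {
        nb <- which(a[i, ] == 1)
        if (length(nb) < 2) return(0)
        oracle_eglob(a[nb, nb, drop = FALSE])
    }, numeric(1)))
}

oracle_betweenness <- function(a) {
    n <- nrow(a)
    D <- oracle_dist(a)
    # number of shortest i-j paths by DP over increasing distance
    npaths <- function(s, t) {
        if (s == t) return(1)
        preds <- which(a[, t] == 1 & D[s, ] == D[s, t] - 1)
        sum(vapply(preds, function(p) npaths(s, p), numeric(1)))
    }
    bc <- numeric(n)
    for (s in seq_len(n - 1)) {
        for (t in (s + 1):n) {
            if (!is.finite(D[s, t]) || D[s, t] == 0) next
            tot <- npaths(s, t)
            for (v in seq_len(n)) {
                if (v == s || v == t) next
                if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
                    D[s, v] + D[v, t] == D[s, t]) {
                    bc[v] <- bc[v] + npaths(s, v) * npaths(v, t) / tot
                }
            }
        }
    }
    bc
}

# simple ER adjacency fixture, independent of the package generators
random_adjacency <- function(n, p, seed) {
    set.seed(seed)
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
    a + t(a)
}

# best node-label agreement between a partition and planted truth over all
# permutations of module labels (exact for small module counts)
label_agreement <- function(membership, truth) {
    ids <- sort(unique(c(membership, truth)))
    if (length(ids) > 6) return(NA_real_)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    best <- 0
    for (pm in perms(ids)) {
        best <- max(best, mean(pm[membership] == truth))
    }
    best
}

# small synthetic cohort -> group connectivity matrix (shared by several tests)
make_group_matrix <- function(seed, n_subjects = 8) {
    spec <- cohort_spec(seed = seed, n_subjects = n_subjects)
    mats <- lapply(generate_cohort(spec),
                   function(s) preprocess_subject(s$ts, s$motion)$M)
    group_average(mats)
}
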