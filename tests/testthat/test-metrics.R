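test_that("closed-form metric values on canonical graphs", {
    k4 <- generate_reference_graph("complete", 4)
    expect_equal(clustering_coefficient(k4)$mean, 1)
    expect_equal(characteristic_path_length(k4), 1)
    expect_equal(global_efficiency(k4), 1)
    expect_equal(local_efficiency(k4), 1)

    p4 <- generate_reference_graph("path", 4)
    expect_equal(clustering_coefficient(p4)$mean, 0)
    expect_equal(characteristic_path_length(p4), 5 / 3)

    p3 <- generate_reference_graph("path", 3)
    expect_equal(global_efficiency(p3), 5 / 6)
    expect_equal(unname(betweenness(p3)[2]), 1)

    star6 <- generate_reference_graph("star", 6)
    expect_equal(unname(betweenness(star6)[1]), choose(5, 2))
    expect_equal(local_efficiency(generate_reference_graph("star", 5)), 0)

    # empty graph
    g0 <- binary_graph(matrix(0L, 4, 4))
    expect_equal(global_efficiency(g0), 0)
    expect_equal(network_cost(g0), 0)

    # two disjoint triangles: L on one component only
    a <- matrix(0L, 6, 6); a[1:3, 1:3] <- 1L; a[4:6, 4:6] <- 1L; diag(a) <- 0L
    expect_equal(characteristic_path_length(binary_graph(a)), 1)
})

test_that("4-cycle with a chord matches triangle enumeration", {
    a <- matrix(0L, 4, 4)
    a[1, 2] <- a[2, 3] <- a[3, 4] <- a[4, 1] <- a[1, 3] <- 1L
    a <- a + t(a); a[a > 1] <- 1L
    g <- binary_graph(a)
    expect_equal(clustering_coefficient(g)$per_node,
                 oracle_clustering_nodes(a), ignore_attr = TRUE)
    expect_equal(clustering_coefficient(g)$mean, mean(oracle_clustering_nodes(a)))
})

test_that("all metrics match brute-force oracles on random graphs", {
    for (i in 1:30) {
        n <- sample(4:12, 1)
        a <- random_adjacency(n, runif(1, 0.2, 0.8), seed = 1000 + i)
        g <- binary_graph(a)
        expect_equal(clustering_coefficient(g)$mean, oracle_C(a), tolerance = 1e-12)
        expect_equal(characteristic_path_length(g), oracle_L(a), tolerance = 1e-12)
        expect_equal(global_efficiency(g), oracle_eglob(a), tolerance = 1e-12)
        expect_equal(local_efficiency(g), oracle_eloc(a), tolerance = 1e-12)
        expect_equal(unname(betweenness(g)), oracle_betweenness(a), tolerance = 1e-12)
    }
})

test_that("small_world_summary combines ratios and cost efficiency", {
    s <- small_world_summary(0.4, 2, 0.2, 2, 0.5, 0.1)
    expect_equal(s$gamma, 2)
    expect_equal(s$lambda, 1)
    expect_equal(s$sigma, 2)
    # printed operating point: 0.5637 - 0.2200
    s2 <- small_world_summary(0.4, 2, 0.2, 2, 0.5637, 0.2200)
    expect_equal(s2$cost_efficiency, 0.3437)
    # C = C_null, L = L_null -> sigma 1
    expect_equal(small_world_summary(0.3, 1.8, 0.3, 1.8, 0.5, 0.2)$sigma, 1)
    expect_error(small_world_summary(0.3, 1.8, 0, 1.8, 0.5, 0.2), "positive")
})

test_that("network cost is E over possible edges", {
    set.seed(3)
    M <- correlation_matrix(matrix(rnorm(200 * 90), 200, 90))
    g <- threshold_by_cost(M, 0.22)
    expect_equal(network_cost(g), 881 / 4005)
    expect_equal(network_cost(generate_reference_graph("complete", 10)), 1)
})

test_that("efficiency orderings hold for lattice / small-world / random at (90, 881)", {
    # Monte-Carlo property at the operating point: small-world graphs sit
    # between the ring lattice and degree-matched randomizations
    lat <- lattice_graph(90, 881)
    eg_lat <- global_efficiency(lat); el_lat <- local_efficiency(lat)
    ok <- 0
    n_seeds <- 10
    for (i in seq_len(n_seeds)) {
        ws <- with_seed(2000 + i, {
            # Watts-Strogatz-like: ring lattice with ~10% of edges rewired
            a <- lat$adjacency
            e <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
            for (r in sample(nrow(e), round(0.1 * nrow(e)))) {
                i0 <- e[r, 1]; j0 <- e[r, 2]
                open <- which(a[i0, ] == 0)
                open <- setdiff(open, i0)
                if (length(open) == 0) next
                j1 <- open[sample.int(length(open), 1)]
                a[i0, j0] <- a[j0, i0] <- 0L
                a[i0, j1] <- a[j1, i0] <- 1L
            }
            binary_graph(a)
        })
        rnd <- rewire_degree_preserving(ws, seed = 3000 + i)
        ord_glob <- eg_lat < global_efficiency(ws) &&
            global_efficiency(ws) < global_efficiency(rnd)
        ord_loc <- local_efficiency(rnd) < local_efficiency(ws) &&
            local_efficiency(ws) < el_lat
        ok <- ok + (ord_glob && ord_loc)
    }
    expect_gte(ok / n_seeds, 0.95)
})
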