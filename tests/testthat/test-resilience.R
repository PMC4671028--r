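test_that("targeted attack honors conventions on canonical graphs", {
    # star: removing the center isolates all leaves
    atk <- targeted_attack(generate_reference_graph("star", 10), "degree",
                           n_steps = 1)
    expect_equal(atk$lcc_fraction, c(1, 1 / 10))
    expect_equal(atk$eglob_pct[1], 100)
    # complete K10: any 5 removals leave a complete remainder
    atk2 <- targeted_attack(generate_reference_graph("complete", 10), "degree",
                            n_steps = 5)
    expect_equal(atk2$lcc_fraction[6], 5 / 10)
    expect_equal(atk2$eglob[6], 1)
    expect_equal(atk2$lcc_fraction_remaining[6], 1)
    # removal counts strictly increase; step 0 is always 100%
    expect_true(all(diff(atk2$n_removed) == 1))
})

test_that("ranking ties break by node index and strategies rank correctly", {
    # path graph: interior nodes tie on degree; node 2 must go first
    g <- generate_reference_graph("path", 5)
    atk <- targeted_attack(g, "degree", n_steps = 1)
    expect_equal(atk$lcc_fraction[2], 3 / 5) # removing node 2 leaves 3-4-5
    # betweenness strategy removes the P3 middle node first
    p3 <- generate_reference_graph("path", 3)
    ab <- targeted_attack(p3, "betweenness", n_steps = 1)
    expect_equal(ab$lcc_fraction[2], 1 / 3)
})

test_that("random failure on K10 gives the exact curve and reproduces", {
    g <- generate_reference_graph("complete", 10)
    rf <- random_failure(g, n_runs = 3, seed = 5)
    expect_equal(rf$lcc_fraction, (10 - 0:9) / 10)
    rf2 <- random_failure(g, n_runs = 3, seed = 5)
    expect_identical(rf$lcc_fraction, rf2$lcc_fraction)
    expect_identical(rf$eglob, rf2$eglob)
})

test_that("random-failure means match exhaustive enumeration at small N", {
    # N=5 ring: enumerate all removal orders exactly
    g <- lattice_graph(5, 5)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    all_orders <- perms(1:5)
    exact <- rowMeans(vapply(all_orders, function(ord) {
        vapply(1:4, function(s) {
            keep <- setdiff(1:5, ord[1:s])
            a <- g$adjacency[keep, keep, drop = FALSE]
            max(tabulate(oracle_components(a))) / 5
        }, numeric(1))
    }, numeric(4)))
    rf <- random_failure(g, n_runs = 400, n_steps = 4, seed = 9)
    expect_equal(rf$lcc_fraction[2:5], exact, tolerance = 0.05)
})

test_that("isolated removal table matches brute force and spec conventions", {
    st <- generate_reference_graph("star", 5)
    tab <- isolated_removal_sweep(st)
    expect_equal(tab$delta_eglob_pct[1], -100) # center removal
    expect_equal(tab$node[1], 1L)
    k5 <- generate_reference_graph("complete", 5)
    expect_true(all(isolated_removal_sweep(k5)$delta_eglob_pct == 0))
    # P4 against pairwise-distance enumeration
    p4 <- generate_reference_graph("path", 4)
    tab4 <- isolated_removal_sweep(p4)
    e0 <- oracle_eglob(p4$adjacency)
    manual <- vapply(1:4, function(i) {
        keep <- setdiff(1:4, i)
        100 * (oracle_eglob(p4$adjacency[keep, keep]) - e0) / e0
    }, numeric(1))
    expect_equal(tab4$delta_eglob_pct[order(tab4$node)], manual, tolerance = 1e-12)
    # sorted ascending: most harmful first
    expect_true(all(diff(tab4$delta_eglob_pct) >= 0))
})

test_that("hub-class comparison handles sets, vectors, and boundary ties", {
    g <- binary_graph(random_adjacency(30, 0.3, seed = 77))
    tab <- isolated_removal_sweep(g)
    # identical sets -> t = 0
    cmp0 <- compare_hub_classes(tab, 1:5, 1:5)
    expect_equal(cmp0$t, 0)
    expect_equal(cmp0$p_value, 1)
    # clearly separated synthetic values
    tab2 <- tab
    tab2$delta_eglob_pct <- rep(0, 30)
    tab2$delta_eglob_pct[tab2$node %in% 1:5] <- -1
    cmp <- compare_hub_classes(tab2, 1:5, 6:10)
    expect_lt(cmp$degree$mean, cmp$betweenness$mean)
    # centrality-vector form with a tie block at the boundary: 30 nodes,
    # top 20% = 6, but ranks 4..12 are tied -> 3 clear + 1 averaged entry
    cent <- c(10, 9, 8, rep(5, 9), rep(1, 18))
    cmpv <- compare_hub_classes(tab2, cent, rev(seq_len(30)) * 1.0,
                                top_fraction = 0.20)
    expect_equal(cmpv$degree$n, 4)
    expect_error(compare_hub_classes(tab, 1:2, 3), ">= 2")
})

test_that("attack curves expose both component-fraction conventions", {
    g <- binary_graph(random_adjacency(20, 0.3, seed = 3))
    atk <- targeted_attack(g, "degree", n_steps = 10)
    expect_true(all(atk$lcc_fraction <= atk$lcc_fraction_remaining + 1e-12))
    expect_equal(atk$lcc_fraction[1], 1)
})
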