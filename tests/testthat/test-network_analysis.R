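test_that("centrality indices match closed forms on canonical graphs", {
  # 5-node star, unit weights
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  ct <- suppressWarnings(centrality_suite(adjacency_to_popgraph_edges(star)))
  expect_equal(ct$betweenness[1], 6)           # (n-1)(n-2)/2
  expect_equal(ct$betweenness[2:5], rep(0, 4))
  expect_equal(ct$clustering[1], 0)
  expect_true(all(is.na(ct$clustering[2:5]))) # leaves have degree 1
  # triangle: all clustering 1
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  ct_tri <- centrality_suite(adjacency_to_popgraph_edges(tri))
  expect_equal(ct_tri$clustering, rep(1, 3))
  # K4 unit weights: eigenvector 1 and strength 3 everywhere
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  ct_k4 <- centrality_suite(adjacency_to_popgraph_edges(k4))
  expect_equal(ct_k4$eigenvector, rep(1, 4), tolerance = 1e-9)
  expect_equal(ct_k4$strength, rep(3, 4))
  expect_equal(ct_k4$degree, rep(3L, 4))
  # closeness = 1 / sum of weighted distances
  expect_equal(ct_k4$closeness, rep(1/3, 4))
})

test_that("betweenness and closeness match enumeration oracles on small graphs", {
  set.seed(14)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    adj <- random_adjacency(n, p = 0.55)
    pg <- adjacency_to_popgraph_edges(adj)
    ct <- suppressWarnings(centrality_suite(pg))
    expect_equal(ct$betweenness, oracle_betweenness(adj), tolerance = 1e-8)
    expect_equal(ct$closeness, unname(oracle_closeness(adj)),
                 tolerance = 1e-9)
    expect_equal(ct$clustering, oracle_clustering(adj))
    expect_equal(ct$strength, rowSums(adj), tolerance = 1e-12)
  }
})

test_that("eigenvector centrality agrees with a dense eigendecomposition", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    adj <- random_adjacency(n, p = 0.7)
    pg <- adjacency_to_popgraph_edges(adj)
    if (igraph::components(as_igraph(pg))$no > 1) next
    ct <- centrality_suite(pg)
    expect_equal(ct$eigenvector, oracle_eigenvector(adj), tolerance = 1e-6)
    expect_equal(max(ct$eigenvector), 1, tolerance = 1e-9)
  }
})

test_that("characteristic path length is the mean unweighted hop count", {
  # complete graph -> 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(characteristic_path_length(adjacency_to_popgraph_edges(k5)), 1)
  # 3-node path -> (1 + 1 + 2)/3
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 1; p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(characteristic_path_length(adjacency_to_popgraph_edges(p3)),
               4/3)
  # weights must not affect it
  p3w <- p3 * 7.3
  expect_equal(characteristic_path_length(adjacency_to_popgraph_edges(p3w)),
               4/3)
  # BFS oracle on random graphs
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    adj <- random_adjacency(n, p = 0.5)
    got <- suppressWarnings(
      characteristic_path_length(adjacency_to_popgraph_edges(adj)))
    expect_equal(got, oracle_cpl(adj), tolerance = 1e-12)
  }
})

test_that("null ensemble statistics and permutation floor behave as defined", {
  set.seed(17)
  gr <- igraph::sample_gnm(30, 90)
  igraph::E(gr)$weight <- runif(90, 1, 5)
  igraph::V(gr)$name <- sprintf("n%02d", 1:30)
  nc <- er_null_ensemble(gr, B = 99, seed = 101)
  expect_true(all(nc$p >= 1/100 & nc$p <= 1))
  expect_equal(nc$B, 99)
  # ER expectation: mean clustering ~ 2m / (k(k-1)); moderate-size check
  gr2 <- igraph::sample_gnm(100, 1000)
  igraph::E(gr2)$weight <- 1
  igraph::V(gr2)$name <- sprintf("n%03d", 1:100)
  nc2 <- er_null_ensemble(gr2, B = 60, seed = 55)
  expect_equal(mean(nc2$null[, "clustering"]), 2 * 1000 / (100 * 99),
               tolerance = 0.05)
  # impossible graph
  full <- matrix(1, 4, 4); diag(full) <- 0
  pg_full <- adjacency_to_popgraph_edges(full)
  expect_no_error(er_null_ensemble(pg_full, B = 3, seed = 1))
  # determinism
  nc_a <- er_null_ensemble(gr, B = 20, seed = 9)
  nc_b <- er_null_ensemble(gr, B = 20, seed = 9)
  expect_identical(nc_a$null, nc_b$null)
  expect_identical(nc_a$p, nc_b$p)
})

test_that("structure classification recovers canonical constructions", {
  set.seed(18)
  # Watts-Strogatz ring with 5% rewiring -> small_world
  sw_hits <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    ws <- igraph::sample_smallworld(1, 100, 5, 0.05)
    ws <- igraph::simplify(ws)
    igraph::V(ws)$name <- sprintf("n%03d", 1:100)
    igraph::E(ws)$weight <- 1
    nc <- er_null_ensemble(ws, B = 99, seed = 500 + s)
    cls <- classify_structure(nc)
    if (cls$class == "small_world") sw_hits <- sw_hits + 1
  }
  expect_gte(sw_hits, 4)
  # G(k, m) draw -> random
  rnd_hits <- 0
  for (s in 1:5) {
    set.seed(600 + s)
    gn <- igraph::sample_gnm(60, 180)
    igraph::V(gn)$name <- sprintf("n%03d", 1:60)
    igraph::E(gn)$weight <- 1
    nc <- er_null_ensemble(gn, B = 99, seed = 700 + s)
    cls <- classify_structure(nc)
    if (cls$class == "random") rnd_hits <- rnd_hits + 1
  }
  expect_gte(rnd_hits, 4)
  # ring lattice, constant degree -> regular
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- sprintf("n%02d", 1:20)
  igraph::E(ring)$weight <- 1
  nc_ring <- er_null_ensemble(ring, B = 49, seed = 2)
  expect_equal(classify_structure(nc_ring)$class, "regular")
})

test_that("bootstrap resampling sizes, determinism, and the f = 1 degenerate case", {
  set.seed(19)
  cfg <- sim_config(n_demes = 8L, seed = 808L)
  sim <- simulate_stepping_stone(cfg)
  nodes <- suppressMessages(cluster_leks_to_nodes(sim$genotypes))
  pg <- suppressMessages(build_popgraph(sim$genotypes, nodes))
  k <- nrow(nodes$nodes)
  bs <- suppressWarnings(bootstrap_centrality(sim$genotypes, nodes, pg,
                                              f = 0.75, B = 8, seed = 3))
  expect_equal(bs$n_resampled, ceiling(0.75 * k - 0.5))
  # paper-shaped arithmetic: 75% of 458 nodes resamples 343 (half rounds down)
  expect_equal(ceiling(0.75 * 458 - 0.5), 343)
  # determinism: same seed, same summaries
  bs2 <- suppressWarnings(bootstrap_centrality(sim$genotypes, nodes, pg,
                                               f = 0.75, B = 8, seed = 3))
  expect_identical(bs$summary, bs2$summary)
  # f = 1 subgraph mode: every replicate identical, SE = 0
  bs3 <- suppressWarnings(bootstrap_centrality(sim$genotypes, nodes, pg,
                                               f = 1, B = 5, seed = 4,
                                               mode = "subgraph"))
  # identical node sets per replicate; only eigen-solver noise remains
  expect_lt(max(bs3$summary$se, na.rm = TRUE), 1e-8)
})

test_that("spearman matrix matches cor.test and handles ties, signs, constants", {
  # strictly increasing / decreasing
  sp <- spearman_correlation_matrix(data.frame(a = 1:10, b = (1:10)^2,
                                               c = 10:1))
  expect_equal(sp$r["a", "b"], 1)
  expect_equal(sp$r["a", "c"], -1)
  expect_equal(diag(sp$r), c(a = 1, b = 1, c = 1))
  # oracle comparison on random columns with ties
  set.seed(20)
  for (rep in 1:10) {
    x <- sample(1:6, 25, replace = TRUE)
    y <- x + rnorm(25, 0, 2)
    sp2 <- spearman_correlation_matrix(data.frame(x = x, y = y))
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(sp2$r["x", "y"], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(cor(x, y, method = "spearman"), sp2$r["x", "y"],
                 tolerance = 1e-12)
  }
  # constant column -> NA with warning
  expect_warning(spc <- spearman_correlation_matrix(
    data.frame(u = rep(2, 5), v = 1:5)), "constant")
  expect_true(is.na(spc$r["u", "v"]))
})

test_that("strength equals degree times weight on uniform-weight graphs", {
  set.seed(24)
  for (rep in 1:5) {
    adj <- random_adjacency(6, p = 0.6, weighted = FALSE) * 2.5
    ct <- suppressWarnings(centrality_suite(adjacency_to_popgraph_edges(adj)))
    expect_equal(ct$strength, ct$degree * 2.5)
  }
})
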