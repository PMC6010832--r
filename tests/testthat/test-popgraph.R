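two_node_table <- function() {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:8),
    lek_id = rep(c("lekA", "lekB"), each = 4),
    lat = rep(c(41, 45), each = 4), lon = -110,
    stringsAsFactors = FALSE)
  a1 <- matrix(c(150L, 150L, 150L, 152L, 154L, 154L, 154L, 152L), 8, 1)
  a2 <- matrix(c(150L, 152L, 150L, 152L, 154L, 152L, 154L, 154L), 8, 1)
  genotype_table(samples, "L01", a1, a2)
}

test_that("multivariate encoding follows the 0/0.5/1 convention and imputes node frequencies", {
  g <- two_node_table()
  nodes <- cluster_leks_to_nodes(g, cut_km = 15, min_node_size = 1)
  enc <- encode_multivariate(g, nodes)
  # columns are the observed alleles 150, 152, 154
  expect_equal(enc$columns$allele, c(150L, 152L, 154L))
  # s01 is 150/150 homozygote -> (1, 0, 0)
  expect_equal(unname(enc$X["s01", ]), c(1, 0, 0))
  # s02 is 150/152 heterozygote -> (0.5, 0.5, 0)
  expect_equal(unname(enc$X["s02", ]), c(0.5, 0.5, 0))
  # every non-missing block sums to 1
  expect_true(all(abs(rowSums(enc$X) - 1) < 1e-12))
})

test_that("missing calls are imputed with the node allele-frequency vector", {
  samples <- data.frame(sample_id = sprintf("s%02d", 1:5),
                        lek_id = "lekA", lat = 41, lon = -110,
                        stringsAsFactors = FALSE)
  # node frequencies from s1-s4: alleles 150 x 6, 152 x 2 -> p = (.75, .25)
  a1 <- matrix(c(150L, 150L, 150L, 150L, NA), 5, 1)
  a2 <- matrix(c(150L, 152L, 150L, 152L, NA), 5, 1)
  g <- genotype_table(samples, "L01", a1, a2)
  nodes <- cluster_leks_to_nodes(g, cut_km = 15, min_node_size = 1)
  enc <- encode_multivariate(g, nodes)
  expect_equal(unname(enc$X["s05", ]), c(0.75, 0.25))
})

test_that("node distance matrix is squared Euclidean between node means", {
  g <- two_node_table()
  nodes <- cluster_leks_to_nodes(g, cut_km = 15, min_node_size = 1)
  enc <- encode_multivariate(g, nodes)
  D <- node_distance_matrix(enc, nodes)
  expect_equal(dim(D), c(2, 2))
  expect_equal(diag(D), setNames(c(0, 0), rownames(D)))
  mA <- colMeans(enc$X[enc$node_of == rownames(D)[1], ])
  mB <- colMeans(enc$X[enc$node_of == rownames(D)[2], ])
  expect_equal(D[1, 2], sum((mA - mB)^2), tolerance = 1e-12)
  # hand case: mean vectors (1,0) and (0,1) -> 2
  expect_equal(sum((c(1, 0) - c(0, 1))^2), 2)
})

test_that("Gower centering matches hand algebra and its identities", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  gw <- gower_covariance(D)
  expect_equal(unname(gw$C), matrix(c(3/4, -3/4, -3/4, 3/4), 2, 2),
               tolerance = 1e-12)
  expect_equal(unname(diag(gw$R)), c(1, 1))
  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(rnorm(6 * 4), 6, 4)
    D2 <- as.matrix(dist(M))^2
    gw2 <- gower_covariance(D2)
    expect_true(all(abs(rowSums(gw2$C)) < 1e-10))
    expect_equal(unname(diag(gw2$R)), rep(1, 6))
  }
  # zero-variance node errors with its name
  Dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(gower_covariance(Dz), "zero-variance")
})

test_that("identity correlation yields an empty graph", {
  R <- diag(5)
  dimnames(R) <- list(letters[1:5], letters[1:5])
  pg <- fit_conditional_graph(R)
  expect_equal(nrow(pg$edges), 0)
})

test_that("the 3-node chain excludes the A-C edge", {
  R <- matrix(c(1, .5, .25,
                .5, 1, .5,
                .25, .5, 1), 3, 3, dimnames = list(c("A", "B", "C"),
                                                   c("A", "B", "C")))
  pg <- fit_conditional_graph(R, n_eff = 100)
  expect_equal(unname(abs(pg$rho["A", "C"])) < 1e-10, TRUE)
  key <- paste(pg$edges$node_a, pg$edges$node_b)
  expect_setequal(key, c("A B", "B C"))
})

test_that("edge-exclusion deviance crosses the chi-squared threshold as derived", {
  expect_equal(edge_exclusion_deviance(0.196, 100), -100 * log(1 - 0.196^2),
               tolerance = 1e-12)
  expect_gt(edge_exclusion_deviance(0.196, 100), qchisq(0.95, 1))
  expect_lt(edge_exclusion_deviance(0.190, 100), qchisq(0.95, 1))
})

test_that("edge pruning is monotone in alpha", {
  set.seed(8)
  for (rep in 1:5) {
    M <- matrix(rnorm(10 * 40), 10, 40)
    R <- cor(t(M))
    dimnames(R) <- list(sprintf("n%02d", 1:10), sprintf("n%02d", 1:10))
    e05 <- fit_conditional_graph(R, alpha = 0.05, n_eff = 30)$edges
    e01 <- fit_conditional_graph(R, alpha = 0.01, n_eff = 30)$edges
    k05 <- paste(e05$node_a, e05$node_b)
    k01 <- paste(e01$node_a, e01$node_b)
    expect_true(all(k01 %in% k05))
  }
})

test_that("MST total weight equals the exhaustive spanning-tree minimum", {
  # triangle with weights 1, 2, 3 keeps {1, 2}
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 2
  adj[1, 3] <- adj[3, 1] <- 3
  pg <- adjacency_to_popgraph_edges(adj)
  mst <- minimum_spanning_tree(pg)
  expect_equal(sort(mst$weight), c(1, 2))
  # tree input returned unchanged
  adj_tree <- matrix(0, 4, 4)
  adj_tree[1, 2] <- adj_tree[2, 1] <- 1.5
  adj_tree[2, 3] <- adj_tree[3, 2] <- 2.5
  adj_tree[2, 4] <- adj_tree[4, 2] <- 0.5
  pg_tree <- adjacency_to_popgraph_edges(adj_tree)
  mst_tree <- minimum_spanning_tree(pg_tree)
  expect_equal(sort(mst_tree$weight), c(0.5, 1.5, 2.5))
  # brute force on random graphs with k <= 6
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    adj <- random_adjacency(n, p = 0.8)
    pg <- adjacency_to_popgraph_edges(adj)
    if (igraph::components(as_igraph(pg))$no > 1) next
    mst <- minimum_spanning_tree(pg)
    expect_equal(sum(mst$weight), oracle_mst_weight(adj), tolerance = 1e-9)
    expect_equal(nrow(mst), n - 1)
  }
})

test_that("conditional genetic distance is a shortest-path metric", {
  # path A-B-C with lengths 2, 3 -> cGD(A, C) = 5
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 2
  adj[2, 3] <- adj[3, 2] <- 3
  pg <- adjacency_to_popgraph_edges(adj)
  cgd <- conditional_genetic_distance(pg)
  expect_equal(cgd["n01", "n03"], 5)
  # disconnected pair -> NA
  adj4 <- matrix(0, 4, 4)
  adj4[1, 2] <- adj4[2, 1] <- 1
  cgd4 <- conditional_genetic_distance(adjacency_to_popgraph_edges(adj4))
  expect_true(is.na(cgd4["n01", "n03"]))
  # matches the enumeration oracle on random graphs; triangle inequality
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    adj <- random_adjacency(n, p = 0.6)
    pg <- adjacency_to_popgraph_edges(adj)
    cgd <- conditional_genetic_distance(pg)
    od <- oracle_distances(adj, weighted = TRUE)
    od[is.infinite(od)] <- NA
    expect_equal(unname(cgd), od, tolerance = 1e-9)
    expect_true(all(diag(cgd) == 0))
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      if (!anyNA(c(cgd[i, j], cgd[i, k], cgd[k, j])))
        expect_lte(cgd[i, j], cgd[i, k] + cgd[k, j] + 1e-9)
    }
  }
})

test_that("panmictic data keep roughly the alpha fraction of edges", {
  # under no structure the edge test should fire at ~ alpha; Monte-Carlo
  # band derived from 12 runs of a 12-node world (binomial-ish spread)
  set.seed(1234)
  frac <- vapply(1:12, function(s) {
    cfg <- sim_config(n_demes = 12L, migration_rate = 0, generations = 0L,
                      leks_per_deme = 2L, samples_per_lek = 8L,
                      seed = 5000L + s)
    sim <- simulate_stepping_stone(cfg)
    nodes <- suppressMessages(cluster_leks_to_nodes(sim$genotypes))
    pg <- suppressMessages(build_popgraph(sim$genotypes, nodes))
    k <- length(pg$node_ids)
    nrow(pg$edges) / (k * (k - 1) / 2)
  }, numeric(1))
  expect_gt(mean(frac), 0.05 - 0.04)
  expect_lt(mean(frac), 0.05 + 0.05)
})

test_that("MST distances track geography under stepping-stone structure", {
  set.seed(77)
  rs <- vapply(1:6, function(s) {
    cfg <- sim_config(n_demes = 12L, seed = 7000L + s)
    sim <- simulate_stepping_stone(cfg)
    nodes <- suppressMessages(cluster_leks_to_nodes(sim$genotypes))
    pg <- suppressMessages(build_popgraph(sim$genotypes, nodes))
    mst <- suppressWarnings(minimum_spanning_tree(pg))
    geo <- great_circle_distance_matrix(nodes$nodes$lat, nodes$nodes$lon)
    cgd <- conditional_genetic_distance(pg, mst)
    ut <- upper.tri(geo)
    ok <- !is.na(cgd[ut])
    cor(cgd[ut][ok], geo[ut][ok], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rs), 0.2)
  expect_true(all(rs > 0))
})
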