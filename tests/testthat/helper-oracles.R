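# Brute-force graph oracles, independent of igraph, for graphs small enough
# to enumerate. Graphs are given as symmetric weighted adjacency matrices
# with 0 = no edge.

# all simple paths between s and t as integer vectors (recursive enumeration)
oracle_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (u in seq_len(n)) {
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

# weighted shortest-path distance matrix by simple-path enumeration
oracle_distances <- function(adj, weighted = TRUE) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      ps <- oracle_simple_paths(adj, s, t)
      if (!length(ps)) next
      lens <- vapply(ps, function(p) {
        if (weighted) sum(adj[cbind(p[-length(p)], p[-1])])
        else length(p) - 1
      }, numeric(1))
      d[s, t] <- d[t, s] <- min(lens)
    }
  }
  d
}

# weighted betweenness by shortest-path counting over enumerated paths
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      ps <- oracle_simple_paths(adj, s, t)
      if (!length(ps)) next
      lens <- vapply(ps, function(p) sum(adj[cbind(p[-length(p)], p[-1])]),
                     numeric(1))
      shortest <- ps[abs(lens - min(lens)) < 1e-9]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        on_path <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + on_path / length(shortest)
      }
    }
  }
  btw
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj, weighted = TRUE)
  apply(d, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (!length(r)) NA_real_ else 1 / sum(r)
  })
}

oracle_clustering <- function(adj) {
  A <- (adj > 0) * 1
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_cpl <- function(adj) {
  d <- oracle_distances(adj, weighted = FALSE)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

oracle_eigenvector <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  v <- abs(v)
  v / max(v)
}

# exhaustive minimum spanning tree: minimum total weight over all spanning
# edge subsets of size n-1 (n <= 6)
oracle_mst_weight <- function(adj) {
  n <- nrow(adj)
  el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(el)
  if (m < n - 1) return(NA_real_)
  best <- Inf
  for (sel in utils::combn(m, n - 1, simplify = FALSE)) {
    sub <- matrix(0, n, n)
    for (e in sel) {
      sub[el[e, 1], el[e, 2]] <- adj[el[e, 1], el[e, 2]]
      sub[el[e, 2], el[e, 1]] <- adj[el[e, 1], el[e, 2]]
    }
    # connected check by reachability
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(colSums(sub[frontier, , drop = FALSE] > 0) > 0),
                     seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) == n) {
      w <- sum(sub[upper.tri(sub)])
      if (w < best) best <- w
    }
  }
  best
}

# random connected-ish weighted graph as adjacency matrix
random_adjacency <- function(n, p = 0.5, weighted = TRUE) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) {
        w <- if (weighted) stats::runif(1, 0.5, 3) else 1
        adj[i, j] <- adj[j, i] <- w
      }
    }
  }
  adj
}

adjacency_to_popgraph_edges <- function(adj) {
  ids <- sprintf("n%02d", seq_len(nrow(adj)))
  el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(node_a = ids[el[, 1]], node_b = ids[el[, 2]],
                      weight = adj[el], rho = NA_real_, deviance = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(node_ids = ids, edges = edges,
                 params = list(alpha = 0.05, tolerance = 1e-4, n_eff = nrow(adj))),
            class = "popgraph")
}
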