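#' Multivariate allele encoding of genotypes
#'
#' Each individual becomes a concatenated vector over loci with one column
#' per observed (locus, allele) combination: a heterozygote contributes 0.5
#' to each of its two allele columns, a homozygote 1.0 to one, so every
#' non-missing locus block sums to 1. Missing loci are imputed with the
#' allele-frequency vector of the individual's node (global frequencies when
#' the node has no call at that locus), preserving the block-sum invariant.
#'
#' @param g genotype_table
#' @param nodes node_assignment
#' @return list of class `mv_encoding`: `X` (individuals x columns matrix,
#'   rows restricted to clustered samples), `columns` data.frame (locus,
#'   allele), `sample_ids`, `node_of` (node id per row).
#' @export
encode_multivariate <- function(g, nodes) {
  keep <- names(nodes$sample2node)
  idx <- match(keep, g$samples$sample_id)
  stopifnot(!anyNA(idx))
  node_of <- unname(nodes$sample2node[keep])
  cols <- list()
  for (j in seq_along(g$loci)) {
    alleles <- sort(unique(c(g$a1[idx, j], g$a2[idx, j])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles))
      cols[[length(cols) + 1]] <- data.frame(locus = g$loci[j],
                                             allele = alleles,
                                             stringsAsFactors = FALSE)
  }
  columns <- do.call(rbind, cols)
  X <- matrix(0, length(idx), nrow(columns),
              dimnames = list(keep, paste(columns$locus, columns$allele,
                                          sep = ".")))
  for (j in seq_along(g$loci)) {
    block <- which(columns$locus == g$loci[j])
    if (!length(block)) next
    allele_col <- stats::setNames(block, columns$allele[block])
    a1 <- g$a1[idx, j]; a2 <- g$a2[idx, j]
    pres <- which(!is.na(a1))
    for (i in pres) {
      X[i, allele_col[as.character(a1[i])]] <-
        X[i, allele_col[as.character(a1[i])]] + 0.5
      X[i, allele_col[as.character(a2[i])]] <-
        X[i, allele_col[as.character(a2[i])]] + 0.5
    }
    mis <- which(is.na(a1))
    if (length(mis)) {
      # global fallback frequencies over the clustered samples
      gl <- c(a1[pres], a2[pres])
      gtab <- table(gl)
      gfreq <- stats::setNames(rep(0, length(block)), names(allele_col))
      gfreq[names(gtab)] <- as.numeric(gtab) / sum(gtab)
      for (i in mis) {
        same_node <- which(node_of == node_of[i])
        nd_copies <- c(a1[same_node], a2[same_node])
        nd_copies <- nd_copies[!is.na(nd_copies)]
        f <- if (length(nd_copies)) {
          tb <- table(nd_copies)
          v <- stats::setNames(rep(0, length(block)), names(allele_col))
          v[names(tb)] <- as.numeric(tb) / sum(tb)
          v
        } else gfreq
        X[i, block] <- f
      }
    }
  }
  structure(list(X = X, columns = columns, sample_ids = keep,
                 node_of = node_of),
            class = "mv_encoding")
}

#' Squared Euclidean distances between node mean genotype vectors
#' @param enc mv_encoding
#' @param nodes node_assignment (defines node order)
#' @return symmetric non-negative matrix, zero diagonal, dimnames = node ids
#' @export
node_distance_matrix <- function(enc, nodes) {
  node_ids <- nodes$nodes$node_id
  stopifnot(length(node_ids) >= 2)
  M <- t(vapply(node_ids, function(nd)
    colMeans(enc$X[enc$node_of == nd, , drop = FALSE]),
    numeric(ncol(enc$X))))
  D <- as.matrix(stats::dist(M))^2
  dimnames(D) <- list(node_ids, node_ids)
  D
}

#' Gower double-centering of a squared-distance matrix
#'
#' \eqn{C = -\tfrac12 J D J} with \eqn{J = I - 11^T/k}: converts among-node
#' squared distances into an among-node covariance matrix whose rows and
#' columns sum to zero. `R` is `C` rescaled to unit diagonal.
#'
#' @param D symmetric squared-distance matrix with zero diagonal
#' @return list with `C` (covariance) and `R` (correlation)
#' @export
gower_covariance <- function(D) {
  stopifnot(is.matrix(D), isTRUE(all.equal(D, t(D), tolerance = 1e-8)),
            all(abs(diag(D)) < 1e-12))
  k <- nrow(D)
  J <- diag(k) - matrix(1 / k, k, k)
  C <- -0.5 * J %*% D %*% J
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(D)
  v <- diag(C)
  if (any(v <= 1e-12)) {
    nm <- rownames(D)[v <= 1e-12]
    stop("zero-variance node(s): ", paste(nm, collapse = ", "),
         " (node indistinguishable from the centroid)")
  }
  R <- C / sqrt(outer(v, v))
  diag(R) <- 1
  list(C = C, R = R)
}

#' Edge-exclusion deviance
#'
#' Likelihood-ratio statistic \eqn{-n \ln(1-\rho^2)} testing whether a
#' partial correlation differs from zero; compared against the chi-squared
#' critical value with 1 df.
#' @param rho partial correlation(s)
#' @param n_eff effective sample size
#' @return deviance value(s)
#' @export
edge_exclusion_deviance <- function(rho, n_eff) {
  -n_eff * log(1 - rho^2)
}

#' Fit the conditional genetic covariance graph
#'
#' Inverts the among-node correlation matrix to obtain partial correlations
#' \eqn{\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}. A Gower
#' double-centered covariance is exactly singular (rows sum to zero), so the
#' inverse is taken on the orthogonal complement of the near-null eigenspace:
#' eigenvalues below `eig_tol` times the largest are treated as structural
#' zeros (the centering constraint and any compositional redundancy of the
#' allele encoding) and dropped; if the retained spectrum is still
#' ill-conditioned a ridge lambda escalating through 0, 1e-8, 1e-6, ... is
#' added to it. An edge i-j is retained when \eqn{|\rho_{ij}|} exceeds
#' `tolerance` AND its edge-exclusion deviance exceeds the chi-squared(1)
#' critical value at `alpha`. The retained edge's weight is the Gower
#' distance \eqn{\sqrt{C_{ii}+C_{jj}-2C_{ij}}} between the two nodes, the
#' length used by all shortest-path statistics.
#'
#' @param R correlation matrix (unit diagonal)
#' @param alpha significance level for edge exclusion (default 0.05)
#' @param tolerance minimum absolute partial correlation (default 1e-4)
#' @param n_eff sample size in the deviance; defaults to the node count
#' @param C optional covariance matrix for edge weights (defaults to `R`)
#' @param eig_tol relative eigenvalue cutoff for the structural null space
#' @return object of class `popgraph`: node ids, `D`/`C`/`R`/`Omega`/`rho`
#'   matrices, `edges` data.frame (node_a, node_b, weight, rho, deviance),
#'   ridge `lambda`, retained `rank`, fit parameters.
#' @export
fit_conditional_graph <- function(R, alpha = 0.05, tolerance = 1e-4,
                                  n_eff = nrow(R), C = NULL,
                                  eig_tol = 1e-10) {
  stopifnot(alpha > 0, alpha < 1, tolerance >= 0, nrow(R) == ncol(R))
  if (is.null(C)) C <- R
  k <- nrow(R)
  node_ids <- rownames(R)
  if (is.null(node_ids)) node_ids <- sprintf("node_%03d", seq_len(k))
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("correlation matrix is not positive semi-definite; ",
         "more samples per node are needed")
  keep <- eg$values > eig_tol * max(eg$values)
  if (sum(keep) < 2)
    stop("correlation matrix has rank < 2 after dropping the null space; ",
         "more samples per node (or fewer nodes) are needed")
  vals <- eg$values[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  lambda_used <- 0
  if (max(vals) / min(vals) > 1e12) {
    for (lam in 10^seq(-8, 2)) {
      if (max(vals + lam) / min(vals + lam) < 1e12) { lambda_used <- lam; break }
    }
    vals <- vals + lambda_used
  }
  Omega <- V %*% (t(V) / vals)
  Omega <- (Omega + t(Omega)) / 2
  s <- sqrt(diag(Omega))
  rho <- -Omega / outer(s, s)
  diag(rho) <- 0
  dimnames(Omega) <- dimnames(rho) <- list(node_ids, node_ids)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  # Gower centering leaves a rank-one constraint in the dropped null space;
  # pseudo-inverting around it shifts every null partial correlation to a
  # common positive offset of 1/(k-1). The edge test is applied to partials
  # re-centered for that offset; a full-rank R gets no correction.
  n_dropped <- k - sum(keep)
  null_centered <- FALSE
  if (n_dropped >= 1) {
    null_vecs <- eg$vectors[, !keep, drop = FALSE]
    ones <- rep(1 / sqrt(k), k)
    null_centered <- any(abs(crossprod(null_vecs, ones)) > 0.9)
  }
  m0 <- if (null_centered) 1 / (k - 1) else 0
  rho_test <- (rho - m0) / (1 - m0)
  diag(rho_test) <- 0
  crit <- stats::qchisq(1 - alpha, df = 1)
  edges <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- rho_test[i, j]
      dev <- edge_exclusion_deviance(r, n_eff)
      if (abs(r) > tolerance && dev > crit) {
        w <- sqrt(max(C[i, i] + C[j, j] - 2 * C[i, j], 0))
        edges[[length(edges) + 1]] <-
          data.frame(node_a = node_ids[i], node_b = node_ids[j],
                     weight = w, rho = r, deviance = dev,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(node_a = character(0), node_b = character(0),
                           weight = numeric(0), rho = numeric(0),
                           deviance = numeric(0), stringsAsFactors = FALSE)
  structure(list(node_ids = node_ids, C = C, R = R, Omega = Omega,
                 rho = rho, edges = edges, lambda = lambda_used,
                 rank = sum(keep),
                 params = list(alpha = alpha, tolerance = tolerance,
                               n_eff = n_eff, null_offset = m0)),
            class = "popgraph")
}

#' @export
print.popgraph <- function(x, ...) {
  cat(sprintf("popgraph: %d nodes, %d edges (alpha=%g, tol=%g, n_eff=%g, ridge=%g)\n",
              length(x$node_ids), nrow(x$edges), x$params$alpha,
              x$params$tolerance, x$params$n_eff, x$lambda))
  invisible(x)
}

#' Build a population graph from genotypes and a node assignment
#'
#' Convenience wrapper: encode, node mean distances, Gower centering,
#' conditional-graph fit. The default `n_eff = "auto"` uses the residual
#' degrees of freedom of a partial correlation estimated from the encoding:
#' the among-node covariance is an outer product over allele columns, so the
#' columns play the role of observations, and their effective count is the
#' Satterthwaite ratio \eqn{(\sum_c v_c)^2 / \sum_c v_c^2} of the column
#' variances across node means (columns are unequal-variance and correlated,
#' so the raw column count badly overstates the information). The residual
#' dof is that count minus (node count - 1). This is the sample-size
#' convention under which the edge-exclusion deviance is approximately
#' chi-squared(1) under panmixia; pass a number to override. The choice is
#' logged.
#' @param g genotype_table
#' @param nodes node_assignment
#' @param n_eff `"auto"` (see above), or a number
#' @inheritParams fit_conditional_graph
#' @return popgraph (with `D` attached)
#' @export
build_popgraph <- function(g, nodes, alpha = 0.05, tolerance = 1e-4,
                           n_eff = "auto") {
  enc <- encode_multivariate(g, nodes)
  D <- node_distance_matrix(enc, nodes)
  gw <- gower_covariance(D)
  if (is.null(n_eff) || identical(n_eff, "auto")) {
    M <- t(vapply(nodes$nodes$node_id, function(nd)
      colMeans(enc$X[enc$node_of == nd, , drop = FALSE]),
      numeric(ncol(enc$X))))
    v <- apply(M, 2, stats::var)
    satt <- sum(v)^2 / sum(v^2)
    n_eff <- max(round(satt) - nrow(D) + 1, 3)
    message("build_popgraph: n_eff = ", n_eff, " (", round(satt, 1),
            " effective encoding columns - ", nrow(D), " nodes + 1)")
  }
  pg <- fit_conditional_graph(gw$R, alpha = alpha, tolerance = tolerance,
                              n_eff = n_eff, C = gw$C)
  pg$D <- D
  pg
}

#' Convert a popgraph to an igraph object (weighted, undirected)
#' @param pg popgraph
#' @return igraph graph with `weight` edge attribute and `name` vertices
#' @export
as_igraph <- function(pg) {
  gr <- igraph::graph_from_data_frame(
    pg$edges[, c("node_a", "node_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = pg$node_ids, stringsAsFactors = FALSE))
  gr
}

#' Minimum spanning tree of the population graph
#'
#' The acyclic edge subset connecting all nodes with minimum total edge
#' length, i.e. maximum retained genetic covariance. On a disconnected graph
#' a spanning forest is returned with a warning.
#' @param pg popgraph
#' @return data.frame of MST edges (same columns as `pg$edges`)
#' @export
minimum_spanning_tree <- function(pg) {
  gr <- as_igraph(pg)
  if (igraph::components(gr)$no > 1)
    warning("graph is disconnected; returning a spanning forest")
  mst <- igraph::mst(gr, weights = igraph::E(gr)$weight)
  el <- igraph::as_data_frame(mst, what = "edges")
  out <- data.frame(node_a = el$from, node_b = el$to, weight = el$weight,
                    stringsAsFactors = FALSE)
  # carry rho/deviance back from the parent edge table
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(out$node_a, out$node_b), key(pg$edges$node_a, pg$edges$node_b))
  out$rho <- pg$edges$rho[m]
  out$deviance <- pg$edges$deviance[m]
  out
}

#' All-pairs conditional genetic distance (cGD)
#'
#' Shortest-path distance between every node pair through the retained
#' weighted edges; unreachable pairs are `NA`.
#' @param pg popgraph
#' @param edges optional edge subset (e.g. the MST) to condition on instead
#'   of the full retained edge set
#' @return symmetric matrix, zero diagonal
#' @export
conditional_genetic_distance <- function(pg, edges = NULL) {
  gr <- if (is.null(edges)) as_igraph(pg)
        else igraph::graph_from_data_frame(
          edges[, c("node_a", "node_b", "weight")], directed = FALSE,
          vertices = data.frame(name = pg$node_ids))
  d <- igraph::distances(gr, weights = igraph::E(gr)$weight)
  d[is.infinite(d)] <- NA
  d <- d[pg$node_ids, pg$node_ids]
  d
}
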