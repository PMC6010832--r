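.popgraph_or_igraph <- function(x) {
  if (inherits(x, "popgraph")) as_igraph(x)
  else if (igraph::is_igraph(x)) x
  else stop("expected a popgraph or igraph object")
}

# replicate seeds: a prefix-stable stream so growing B never reshuffles
# earlier replicates
.replicate_seeds <- function(seed, B) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Six node centrality indices
#'
#' Degree, strength (sum of adjacent edge weights), weighted betweenness and
#' closeness (edge weight treated as path length), unweighted local
#' clustering coefficient (`NA` for degree < 2), and weighted eigenvector
#' centrality scaled to a maximum of 1. Closeness is the reciprocal of the
#' summed shortest-path distance to all reachable nodes (larger = more
#' central); on a disconnected graph it is computed per component with a
#' warning.
#'
#' @param pg popgraph or weighted igraph
#' @return data.frame of class `centrality_table`: node_id plus the six
#'   indices
#' @export
centrality_suite <- function(pg) {
  gr <- .popgraph_or_igraph(pg)
  if (igraph::vcount(gr) == 0) stop("empty graph")
  w <- igraph::E(gr)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(gr))
  if (igraph::components(gr)$no > 1)
    warning("graph is disconnected; closeness computed within components")
  deg <- igraph::degree(gr)
  strength <- igraph::strength(gr, weights = w)
  btw <- igraph::betweenness(gr, weights = w, directed = FALSE)
  dm <- igraph::distances(gr, weights = w)
  clo <- apply(dm, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (!length(r)) NA_real_ else 1 / sum(r)
  })
  cc <- suppressWarnings(igraph::transitivity(gr, type = "local",
                                              isolates = "NaN"))
  cc[deg < 2] <- NA_real_
  cc[is.nan(cc)] <- NA_real_
  eig <- if (igraph::ecount(gr) == 0) rep(0, igraph::vcount(gr))
         else igraph::eigen_centrality(gr, weights = w)$vector
  structure(data.frame(node_id = igraph::V(gr)$name,
                       degree = as.integer(deg), strength = strength,
                       betweenness = btw, closeness = clo,
                       clustering = cc, eigenvector = eig,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("centrality_table", "data.frame"))
}

#' Characteristic path length (unweighted hops)
#'
#' Mean shortest-path length over all connected unordered node pairs, on
#' unweighted hops: how many edges, on average, separate two nodes.
#' Unreachable pairs are excluded with a warning.
#' @param pg popgraph or igraph
#' @return numeric scalar (`NaN` for a graph with < 2 nodes)
#' @export
characteristic_path_length <- function(pg) {
  gr <- .popgraph_or_igraph(pg)
  d <- igraph::distances(gr, weights = NA)
  v <- d[upper.tri(d)]
  if (any(is.infinite(v))) {
    warning("disconnected pairs excluded from characteristic path length")
    v <- v[is.finite(v)]
  }
  mean(v)
}

# two-sample Kolmogorov-Smirnov statistic (no p-value machinery needed)
.ks_stat <- function(x, y) {
  g <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(g)
  Fy <- stats::ecdf(y)(g)
  max(abs(Fx - Fy))
}

.graph_stats <- function(gr) {
  cc <- suppressWarnings(igraph::transitivity(gr, type = "local",
                                              isolates = "NaN"))
  cc <- cc[!is.nan(cc) & !is.na(cc)]
  c(clustering = if (length(cc)) mean(cc) else NA_real_,
    cpl = characteristic_path_length(gr))
}

#' Erdos-Renyi null ensemble comparison
#'
#' Draws `B` uniform random graphs G(k, m) with the observed node and edge
#' counts, assigns each a permutation of the observed edge weights, and
#' compares the observed mean clustering coefficient and characteristic path
#' length against the ensemble with one-sided permutation p-values
#' \eqn{p = (1 + \#\{null \ge obs\})/(B+1)}. The degree distribution is
#' compared by a leave-one-out Kolmogorov-Smirnov scheme: the observed
#' statistic is KS(observed degrees, pooled null degrees) and the reference
#' distribution is KS(replicate degrees, pooled remaining-null degrees).
#'
#' @param pg popgraph or igraph
#' @param B number of null replicates (default 1000)
#' @param seed RNG seed (mandatory for reproducibility)
#' @return list of class `null_comparison`: observed stats, null matrices,
#'   p-values, seed
#' @export
er_null_ensemble <- function(pg, B = 1000L, seed) {
  stopifnot(B >= 1, !missing(seed))
  gr <- .popgraph_or_igraph(pg)
  k <- igraph::vcount(gr); m <- igraph::ecount(gr)
  if (m > k * (k - 1) / 2)
    stop("impossible graph: more edges than node pairs")
  w <- igraph::E(gr)$weight
  if (is.null(w)) w <- rep(1, m)
  obs <- .graph_stats(gr)
  obs_deg <- igraph::degree(gr)
  seeds <- .replicate_seeds(seed, B)
  null_stats <- matrix(NA_real_, B, 2,
                       dimnames = list(NULL, c("clustering", "cpl")))
  null_deg <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    gnull <- igraph::sample_gnm(k, m)
    igraph::E(gnull)$weight <- sample(w)
    null_stats[b, ] <- suppressWarnings(.graph_stats(gnull))
    null_deg[[b]] <- igraph::degree(gnull)
  }
  perm_p <- function(null, observed) {
    if (is.na(observed)) return(NA_real_)
    (1 + sum(null >= observed, na.rm = TRUE)) / (B + 1)
  }
  p_clustering <- perm_p(null_stats[, "clustering"], obs[["clustering"]])
  p_cpl <- perm_p(null_stats[, "cpl"], obs[["cpl"]])
  all_deg <- unlist(null_deg)
  nrep <- lengths(null_deg)
  ks_obs <- .ks_stat(obs_deg, all_deg)
  ks_null <- vapply(seq_len(B), function(b) {
    pool <- unlist(null_deg[-b])
    .ks_stat(null_deg[[b]], pool)
  }, numeric(1))
  p_degree <- (1 + sum(ks_null >= ks_obs)) / (B + 1)
  structure(list(observed = c(obs, ks_degree = ks_obs),
                 observed_degrees = obs_deg,
                 null = null_stats, null_ks = ks_null,
                 p = c(clustering = p_clustering, cpl = p_cpl,
                       degree = p_degree),
                 B = B, seed = seed),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("null_comparison (B=%d): clustering %.4g (p=%.4g), CPL %.4g (p=%.4g), degree KS %.4g (p=%.4g)\n",
              x$B, x$observed["clustering"], x$p["clustering"],
              x$observed["cpl"], x$p["cpl"],
              x$observed["ks_degree"], x$p["degree"]))
  invisible(x)
}

#' Classify network structure against the null ensemble
#'
#' Decision cascade: `regular` when the degree variance is (near) zero;
#' otherwise `small_world` when the clustering coefficient significantly
#' exceeds the Erdos-Renyi null (permutation p < `alpha`) while the
#' characteristic path length stays short (observed <= null 97.5th
#' percentile x `path_factor`), refined to `scale_free` only when a discrete
#' power law fit to the degree distribution is not rejected; `random` when
#' neither clustering nor the degree distribution deviates. All
#' sub-decisions are returned in the evidence record.
#'
#' @param nc null_comparison from [er_null_ensemble()]
#' @param alpha significance level (default 0.05)
#' @param path_factor slack multiplier on the null path-length percentile
#'   (default 2: "short" means within twice the random expectation)
#' @return list of class `structure_class`: `class` and `evidence`
#' @export
classify_structure <- function(nc, alpha = 0.05, path_factor = 2) {
  deg <- nc$observed_degrees
  ev <- list(degree_variance = stats::var(deg),
             p_clustering = unname(nc$p["clustering"]),
             p_degree = unname(nc$p["degree"]),
             cpl_observed = unname(nc$observed["cpl"]),
             cpl_null_q975 = unname(stats::quantile(nc$null[, "cpl"], 0.975,
                                                    na.rm = TRUE)),
             path_factor = path_factor, alpha = alpha)
  ev$clustering_elevated <- !is.na(ev$p_clustering) &&
    ev$p_clustering < alpha
  ev$path_short <- is.finite(ev$cpl_observed) && !is.na(ev$cpl_null_q975) &&
    ev$cpl_observed <= ev$cpl_null_q975 * path_factor
  ev$powerlaw_ok <- FALSE
  if (length(unique(deg)) > 2 && max(deg) > min(deg)) {
    fit <- tryCatch(igraph::fit_power_law(deg[deg > 0] ,
                                          implementation = "plfit"),
                    error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$KS.p))
      ev$powerlaw_ok <- fit$KS.p >= alpha
  }
  cls <- if (ev$degree_variance < 1e-12 && min(deg) >= 2) {
    # constant degree >= 2: a lattice; constant degree 0/1 is just sparse
    "regular"
  } else if (ev$clustering_elevated && ev$path_short) {
    if (ev$powerlaw_ok) "scale_free" else "small_world"
  } else if (!ev$clustering_elevated &&
             (is.na(ev$p_degree) || ev$p_degree >= alpha)) {
    "random"
  } else if (ev$powerlaw_ok) {
    "scale_free"
  } else if (ev$clustering_elevated) {
    "small_world"
  } else {
    "random"
  }
  structure(list(class = cls, evidence = ev), class = "structure_class")
}

#' Bootstrap uncertainty of centrality indices
#'
#' `B` replicates, each on `round(f * k)` nodes sampled without replacement.
#' `mode = "rebuild"` (default) refits the conditional graph on the node
#' subset from the encoded genotypes; `mode = "subgraph"` takes the induced
#' subgraph of the fitted graph. Reported per index: mean and median of the
#' per-replicate node means/medians, their SE, and percentile 95% CIs.
#'
#' @param g genotype_table
#' @param nodes node_assignment
#' @param pg fitted popgraph (required for `mode = "subgraph"`; also supplies
#'   fit parameters for rebuilds)
#' @param f node fraction per replicate (default 0.75)
#' @param B replicates (default 1000)
#' @param seed RNG seed
#' @param mode `"rebuild"` or `"subgraph"`
#' @return list of class `bootstrap_summary`: `summary` data.frame and the
#'   per-replicate statistic matrices
#' @export
bootstrap_centrality <- function(g, nodes, pg = NULL, f = 0.75, B = 1000L,
                                 seed, mode = c("rebuild", "subgraph")) {
  mode <- match.arg(mode)
  stopifnot(f > 0, f <= 1, B >= 1, !missing(seed))
  node_ids <- nodes$nodes$node_id
  k <- length(node_ids)
  # round half down: 75% of 458 nodes resamples 343, matching the field's
  # published usage (R's round() would give 344 at the .5 boundary)
  nsub <- ceiling(f * k - 0.5)
  if (nsub < 2) stop("resample size < 2; increase f")
  params <- if (!is.null(pg)) pg$params
            else list(alpha = 0.05, tolerance = 1e-4, n_eff = NULL)
  D <- NULL
  if (mode == "rebuild") {
    enc <- encode_multivariate(g, nodes)
    D <- node_distance_matrix(enc, nodes)
  } else if (is.null(pg)) {
    stop("mode='subgraph' needs the fitted popgraph")
  }
  idx_names <- c("degree", "strength", "betweenness", "closeness",
                 "clustering", "eigenvector")
  means <- medians <- matrix(NA_real_, B, length(idx_names),
                             dimnames = list(NULL, idx_names))
  seeds <- .replicate_seeds(seed, B)
  disconnected <- logical(B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    sub <- sort(sample(node_ids, nsub))
    ct <- if (mode == "rebuild") {
      Ds <- D[sub, sub]
      gw <- gower_covariance(Ds)
      n_eff <- if (is.null(params$n_eff)) length(sub) else params$n_eff
      pgb <- fit_conditional_graph(gw$R, alpha = params$alpha,
                                   tolerance = params$tolerance,
                                   n_eff = n_eff, C = gw$C)
      suppressWarnings(centrality_suite(pgb))
    } else {
      gr <- igraph::induced_subgraph(as_igraph(pg), sub)
      suppressWarnings(centrality_suite(gr))
    }
    disconnected[b] <- anyNA(ct$closeness)
    means[b, ] <- vapply(idx_names, function(nm) mean(ct[[nm]], na.rm = TRUE),
                         numeric(1))
    medians[b, ] <- vapply(idx_names, function(nm)
      stats::median(ct[[nm]], na.rm = TRUE), numeric(1))
  }
  summarize <- function(M, what) {
    do.call(rbind, lapply(colnames(M), function(nm) {
      v <- M[, nm]
      q <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE)
      data.frame(index = nm, statistic = what,
                 estimate = mean(v, na.rm = TRUE),
                 se = stats::sd(v, na.rm = TRUE),
                 ci_lo = q[1], ci_hi = q[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  structure(list(summary = rbind(summarize(means, "mean"),
                                 summarize(medians, "median")),
                 means = means, medians = medians,
                 n_resampled = nsub, f = f, B = B, mode = mode, seed = seed,
                 any_disconnected = any(disconnected)),
            class = "bootstrap_summary")
}

#' Spearman rank correlation matrix with p-values
#'
#' Pairwise-complete Spearman correlations (average ranks for ties) with
#' two-sided p-values from the t approximation
#' \eqn{t = r_s \sqrt{(n-2)/(1-r_s^2)}}. Constant columns give `NA` with a
#' warning.
#'
#' @param columns data.frame or named list of numeric vectors of equal length
#' @return list with `r` (correlation matrix, unit diagonal) and `p`
#' @export
spearman_correlation_matrix <- function(columns) {
  df <- as.data.frame(columns)
  v <- names(df)
  p <- r <- matrix(NA_real_, length(v), length(v), dimnames = list(v, v))
  diag(r) <- 1
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (j <= i) next
      x <- df[[i]]; y <- df[[j]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 3) { warning("fewer than 3 complete pairs: ", v[i], " vs ", v[j]); next }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("constant column in pair ", v[i], " vs ", v[j]); next
      }
      rs <- stats::cor(rank(x[ok]), rank(y[ok]))
      r[i, j] <- r[j, i] <- rs
      if (abs(rs) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tt <- rs * sqrt((n - 2) / (1 - rs^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
  }
  list(r = r, p = p)
}
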