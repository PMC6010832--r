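#' Great-circle distance matrix (haversine)
#'
#' Pairwise great-circle distances in kilometres between WGS84 points,
#' computed on a sphere. The default radius 6378.388 km matches the classic
#' geographic-distance routines used in landscape genetics.
#'
#' @param lat,lon numeric degree vectors of equal length
#' @param radius_km sphere radius (km)
#' @return symmetric matrix of km distances, zero diagonal
#' @export
great_circle_distance_matrix <- function(lat, lon, radius_km = 6378.388) {
  stopifnot(length(lat) == length(lon))
  if (any(lat < -90 | lat > 90 | lon < -180 | lon > 180, na.rm = TRUE) ||
      anyNA(lat) || anyNA(lon))
    stop("invalid coordinates")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a[a > 1] <- 1; a[a < 0] <- 0
  d <- 2 * radius_km * asin(sqrt(a))
  diag(d) <- 0
  d
}

#' Cluster leks into network nodes by geographic distance
#'
#' Agglomerative hierarchical clustering (complete linkage by default) on the
#' great-circle distance matrix among lek locations, cut at `cut_km` (default
#' 15 km, the median breeding dispersal distance among leks for sage-grouse).
#' Clusters holding fewer than `min_node_size` sampled individuals are
#' dropped; the affected samples are logged and recorded.
#'
#' @param g genotype_table
#' @param cut_km tree cut height in km (> 0)
#' @param min_node_size minimum individuals (samples, not leks) per retained
#'   node
#' @param linkage hclust method (default `"complete"`, which bounds the
#'   within-node lek diameter by `cut_km`)
#' @param radius_km sphere radius for distances
#' @return object of class `node_assignment`: `nodes` data.frame (node_id,
#'   lat, lon centroid, n_leks, n_samples), `lek2node` and `sample2node`
#'   named character vectors, `removed_samples`.
#' @export
cluster_leks_to_nodes <- function(g, cut_km = 15, min_node_size = 4L,
                                  linkage = "complete",
                                  radius_km = 6378.388) {
  stopifnot(cut_km > 0, min_node_size >= 1)
  leks <- unique(g$samples[, c("lek_id", "lat", "lon")])
  leks <- leks[!duplicated(leks$lek_id), , drop = FALSE]
  leks <- leks[order(leks$lek_id), , drop = FALSE]  # input-order invariance
  if (nrow(leks) == 1) {
    memb <- stats::setNames(1L, leks$lek_id)
  } else {
    d <- great_circle_distance_matrix(leks$lat, leks$lon, radius_km)
    dimnames(d) <- list(leks$lek_id, leks$lek_id)
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    memb <- stats::cutree(hc, h = cut_km)
  }
  sample_cluster <- memb[g$samples$lek_id]
  n_per_cluster <- table(sample_cluster)
  keep_clusters <- as.integer(names(n_per_cluster)[n_per_cluster >= min_node_size])
  if (!length(keep_clusters))
    stop("no lek cluster holds >= ", min_node_size, " samples")
  removed <- g$samples$sample_id[!sample_cluster %in% keep_clusters]
  if (length(removed))
    message("cluster_leks_to_nodes: dropped ", length(removed),
            " sample(s) in clusters below ", min_node_size, " individuals")
  # stable node ids by cluster index
  node_of_cluster <- stats::setNames(sprintf("node_%03d", seq_along(keep_clusters)),
                                     keep_clusters)
  keep_mask <- sample_cluster %in% keep_clusters
  sample2node <- stats::setNames(node_of_cluster[as.character(sample_cluster[keep_mask])],
                                 g$samples$sample_id[keep_mask])
  lek_keep <- memb %in% keep_clusters
  lek2node <- stats::setNames(node_of_cluster[as.character(memb[lek_keep])],
                              names(memb)[lek_keep])
  nodes <- do.call(rbind, lapply(seq_along(keep_clusters), function(i) {
    cl <- keep_clusters[i]
    lk <- leks[memb[leks$lek_id] == cl, , drop = FALSE]
    data.frame(node_id = node_of_cluster[as.character(cl)],
               lat = mean(lk$lat), lon = mean(lk$lon),
               n_leks = nrow(lk),
               n_samples = as.integer(n_per_cluster[as.character(cl)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(nodes = nodes, lek2node = lek2node,
                 sample2node = sample2node, removed_samples = removed,
                 cut_km = cut_km, min_node_size = min_node_size,
                 linkage = linkage),
            class = "node_assignment")
}

#' @export
print.node_assignment <- function(x, ...) {
  cat(sprintf("node_assignment: %d nodes (%d leks, %d samples; cut %g km, min %d, %s linkage)\n",
              nrow(x$nodes), length(x$lek2node), length(x$sample2node),
              x$cut_km, x$min_node_size, x$linkage))
  invisible(x)
}

#' Mean peak male count per node
#'
#' Lek attendance as an abundance index. Each (lek, year) record is that
#' lek's peak male count for the year; the default node value is the flat
#' mean over all member-lek-by-year records. `per_lek = TRUE` first averages
#' within lek across years, then across member leks (equal lek weighting).
#'
#' @param nodes node_assignment
#' @param counts lek_count_table
#' @param per_lek weight leks equally regardless of years counted
#' @return named numeric per node (`NA` when no member lek has counts)
#' @export
mean_peak_male_count <- function(nodes, counts, per_lek = FALSE) {
  node_of <- nodes$lek2node[counts$lek_id]
  vapply(nodes$nodes$node_id, function(nd) {
    rec <- counts[!is.na(node_of) & node_of == nd, , drop = FALSE]
    if (!nrow(rec)) return(NA_real_)
    if (per_lek)
      mean(tapply(rec$high_male_count, rec$lek_id, mean))
    else mean(rec$high_male_count)
  }, numeric(1))
}

.polygon_centroid <- function(x, y) {
  # shoelace centroid; degenerate (zero-area) polygons fall back to the
  # vertex mean
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Distance of each node from the range centroid (inverse range centrality)
#'
#' Convex hull of the node centroids (planar, on lon/lat), centroid of the
#' hull polygon, then great-circle distance from every node to that centroid.
#' Larger distance = more peripheral = lower range centrality.
#'
#' @param nodes node_assignment
#' @param radius_km sphere radius for the final distances
#' @return named numeric km per node; hull centroid in attribute `centroid`
#'   (lon, lat)
#' @export
range_centrality <- function(nodes, radius_km = 6378.388) {
  nd <- nodes$nodes
  if (nrow(nd) < 3) stop("need >= 3 node centroids for a convex hull")
  h <- grDevices::chull(nd$lon, nd$lat)
  if (length(h) < 3) stop("node centroids are collinear; hull is degenerate")
  cen <- .polygon_centroid(nd$lon[h], nd$lat[h])
  m <- great_circle_distance_matrix(c(cen[2], nd$lat), c(cen[1], nd$lon),
                                    radius_km)
  structure(stats::setNames(m[1, -1], nd$node_id),
            centroid = c(lon = cen[1], lat = cen[2]))
}

#' Write the node table CSV
#' @param nodes node_assignment
#' @param counts optional lek_count_table for mean peak male counts
#' @param path output path
#' @return `path`, invisibly
#' @export
write_node_table <- function(nodes, counts = NULL, path) {
  out <- nodes$nodes
  if (!is.null(counts))
    out$mean_peak_male_count <- mean_peak_male_count(nodes, counts)
  if (nrow(out) >= 3)
    out$range_distance_km <- as.numeric(range_centrality(nodes))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
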