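.index_names <- c("degree", "strength", "betweenness", "closeness",
                  "clustering", "eigenvector")

#' Top-fraction hub nodes per centrality index
#'
#' Per index, the `ceiling(fraction * k)` highest-valued nodes (closeness is
#' already oriented larger = more central); ties at the boundary value are
#' all included and flagged. `NA` index values never rank.
#'
#' @param ct centrality_table
#' @param fraction top fraction (default 0.01)
#' @return named list per index: data.frame (node_id, value, tied)
#' @export
top_hubs <- function(ct, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  k <- nrow(ct)
  n_top <- ceiling(fraction * k)
  out <- lapply(.index_names, function(nm) {
    v <- ct[[nm]]
    ok <- which(!is.na(v))
    ord <- ok[order(v[ok], decreasing = TRUE)]
    if (length(ord) <= n_top) {
      sel <- ord
      tied <- FALSE
    } else {
      cutoff <- v[ord[n_top]]
      sel <- ok[v[ok] >= cutoff]
      sel <- sel[order(v[sel], decreasing = TRUE)]
      tied <- length(sel) > n_top
    }
    data.frame(node_id = ct$node_id[sel], value = v[sel],
               tied = rep(tied, length(sel)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- .index_names
  out
}

# within-index percentile of each value (fraction of non-NA values <= v)
.percentile <- function(v) {
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  out[ok] <- rank(v[ok], ties.method = "average") / sum(ok)
  out
}

#' Nodes above a percentile in every centrality index simultaneously
#'
#' The cross-index hub screen: a node qualifies when it sits at or above the
#' given within-index percentile for all six indices at once (boundary
#' inclusive). With the default 0.5 this is "top 50% of all indices
#' combined".
#'
#' @param ct centrality_table
#' @param percentile within-index percentile threshold (default 0.5)
#' @return character vector of node ids
#' @export
cross_index_hubs <- function(ct, percentile = 0.5) {
  stopifnot(percentile > 0, percentile < 1)
  qual <- rep(TRUE, nrow(ct))
  for (nm in .index_names) {
    pct <- .percentile(ct[[nm]])
    qual <- qual & !is.na(pct) & pct >= percentile
  }
  ct$node_id[qual]
}

#' Spoke nodes: per-index minima and the zero-betweenness set
#'
#' @param ct centrality_table
#' @return list with `minima` (named list per index of minimum-valued node
#'   ids) and `zero_betweenness` (all nodes with betweenness 0)
#' @export
identify_spokes <- function(ct) {
  minima <- lapply(.index_names, function(nm) {
    v <- ct[[nm]]
    ok <- !is.na(v)
    ct$node_id[ok & v == min(v[ok])]
  })
  names(minima) <- .index_names
  list(minima = minima,
       zero_betweenness = ct$node_id[!is.na(ct$betweenness) &
                                     ct$betweenness == 0])
}

#' Keystone nodes: high centrality despite low abundance or peripheral range
#' position
#'
#' A node is keystone for an index when its centrality reaches the
#' `cent_pct` within-index percentile AND its mean peak male count is at or
#' below the `attr_pct` percentile OR its range distance is at or above the
#' `(1 - attr_pct)` percentile. Degenerate attributes (all values equal)
#' trigger nothing. Per-index linear regressions of centrality on count with
#' studentized residuals are returned as diagnostics.
#'
#' @param ct centrality_table
#' @param counts named numeric per node (mean peak male count; `NA` allowed)
#' @param range_km named numeric per node (distance from range centroid)
#' @param cent_pct centrality percentile threshold (default 0.90)
#' @param attr_pct attribute percentile threshold (default 0.50)
#' @return list with `keystones` data.frame (node_id, indices, trigger,
#'   centrality percentiles, count/range percentiles) and `diagnostics`
#'   (per-index lm fits with studentized residuals)
#' @export
identify_keystones <- function(ct, counts, range_km = NULL,
                               cent_pct = 0.90, attr_pct = 0.50) {
  counts <- counts[ct$node_id]
  if (all(is.na(counts)) && is.null(range_km)) {
    warning("all attribute values missing; no keystones identifiable")
    return(list(keystones = data.frame(node_id = character(0),
                                       indices = character(0),
                                       trigger = character(0)),
                diagnostics = list()))
  }
  cnt_pct <- .percentile(counts)
  cnt_degenerate <- length(unique(counts[!is.na(counts)])) <= 1
  rng_pct <- NULL; rng_degenerate <- TRUE
  if (!is.null(range_km)) {
    range_km <- range_km[ct$node_id]
    rng_pct <- .percentile(range_km)
    rng_degenerate <- length(unique(range_km[!is.na(range_km)])) <= 1
  }
  hits <- list()
  diagnostics <- list()
  for (nm in .index_names) {
    v <- ct[[nm]]
    vp <- .percentile(v)
    central <- !is.na(vp) & vp >= cent_pct
    low_count <- if (cnt_degenerate) rep(FALSE, nrow(ct))
                 else !is.na(cnt_pct) & cnt_pct <= attr_pct
    peripheral <- if (is.null(rng_pct) || rng_degenerate) rep(FALSE, nrow(ct))
                  else !is.na(rng_pct) & rng_pct >= 1 - attr_pct
    key <- central & (low_count | peripheral)
    if (any(key)) {
      trig <- ifelse(low_count[key] & peripheral[key], "count+range",
                     ifelse(low_count[key], "count", "range"))
      hits[[nm]] <- data.frame(node_id = ct$node_id[key], index = nm,
                               trigger = trig,
                               centrality_pct = vp[key],
                               count_pct = cnt_pct[key],
                               range_pct = if (is.null(rng_pct)) NA_real_
                                           else rng_pct[key],
                               stringsAsFactors = FALSE, row.names = NULL)
    }
    ok <- !is.na(v) & !is.na(counts)
    if (sum(ok) >= 3 && stats::sd(counts[ok]) > 0) {
      fit <- stats::lm(v[ok] ~ counts[ok])
      diagnostics[[nm]] <- data.frame(
        node_id = ct$node_id[ok],
        fitted = stats::fitted(fit),
        studentized = stats::rstudent(fit),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(hits))
    return(list(keystones = data.frame(node_id = character(0),
                                       indices = character(0),
                                       trigger = character(0)),
                diagnostics = diagnostics))
  all_hits <- do.call(rbind, hits)
  agg <- lapply(split(all_hits, all_hits$node_id), function(d) {
    data.frame(node_id = d$node_id[1],
               indices = paste(sort(unique(d$index)), collapse = "+"),
               trigger = paste(sort(unique(d$trigger)), collapse = "+"),
               count_pct = d$count_pct[1],
               range_pct = d$range_pct[1],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  list(keystones = do.call(rbind, c(agg, list(make.row.names = FALSE))),
       per_index = all_hits, diagnostics = diagnostics)
}

#' Assemble and write the full prioritization report
#'
#' @param ct centrality_table
#' @param counts named numeric per node or NULL
#' @param range_km named numeric per node or NULL
#' @param top_fraction top-hub fraction (default 0.01)
#' @param cross_percentile cross-index percentile (default 0.5)
#' @param cent_pct,attr_pct keystone thresholds
#' @param path optional CSV path; when given the per-node report is written
#' @return list with `per_node` data.frame and the component results
#' @export
prioritization_report <- function(ct, counts = NULL, range_km = NULL,
                                  top_fraction = 0.01,
                                  cross_percentile = 0.5,
                                  cent_pct = 0.90, attr_pct = 0.50,
                                  path = NULL) {
  hubs <- top_hubs(ct, top_fraction)
  cross <- cross_index_hubs(ct, cross_percentile)
  spokes <- identify_spokes(ct)
  keys <- if (!is.null(counts) || !is.null(range_km)) {
    if (is.null(counts))
      counts <- stats::setNames(rep(NA_real_, nrow(ct)), ct$node_id)
    identify_keystones(ct, counts, range_km, cent_pct, attr_pct)
  } else NULL
  per_node <- data.frame(node_id = ct$node_id, stringsAsFactors = FALSE)
  for (nm in .index_names) {
    per_node[[nm]] <- ct[[nm]]
    per_node[[paste0(nm, "_rank")]] <-
      rank(-ct[[nm]], ties.method = "min", na.last = "keep")
    per_node[[paste0(nm, "_tophub")]] <-
      per_node$node_id %in% hubs[[nm]]$node_id
  }
  per_node$cross_index_hub <- per_node$node_id %in% cross
  per_node$zero_betweenness <- per_node$node_id %in% spokes$zero_betweenness
  per_node$keystone <- if (is.null(keys)) FALSE
                       else per_node$node_id %in% keys$keystones$node_id
  if (!is.null(path))
    utils::write.csv(per_node, path, row.names = FALSE, quote = FALSE)
  list(per_node = per_node, top_hubs = hubs, cross_index_hubs = cross,
       spokes = spokes, keystones = keys)
}
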