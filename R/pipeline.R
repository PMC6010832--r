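#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one list; values mirror the
#' defaults of the underlying functions. `read_pipeline_config()` merges a
#' JSON (or YAML, when the yaml package is installed) file over these
#' defaults.
#' @return nested list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    input = list(genotypes = NULL, lek_counts = NULL),
    simulate = list(scale = "tiny"),
    qc = list(max_failed_loci = 5L, max_mismatch_loci = 0L),
    clustering = list(cut_km = 15, min_node_size = 4L, linkage = "complete"),
    graph = list(alpha = 0.05, tolerance = 1e-4, n_eff = NULL),
    analysis = list(null_B = 1000L, bootstrap_B = 1000L, bootstrap_f = 0.75,
                    bootstrap_mode = "rebuild", path_factor = 2),
    prioritization = list(top_fraction = 0.01, cross_percentile = 0.5,
                          cent_pct = 0.90, attr_pct = 0.50)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#' @param path JSON (or `.yaml`/`.yml`, when the yaml package is available)
#'   file; keys override [default_config()]
#' @return full configuration list
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config given but the 'yaml' package is not installed; ",
           "use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .merge_config(default_config(), user)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_node_assignment <- function(nodes, path) {
  jsonlite::write_json(list(nodes = nodes$nodes,
                            lek2node = as.list(nodes$lek2node),
                            sample2node = as.list(nodes$sample2node),
                            removed_samples = nodes$removed_samples,
                            cut_km = nodes$cut_km,
                            min_node_size = nodes$min_node_size,
                            linkage = nodes$linkage),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_node_assignment <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = x$nodes,
                 lek2node = unlist(x$lek2node),
                 sample2node = unlist(x$sample2node),
                 removed_samples = as.character(x$removed_samples),
                 cut_km = x$cut_km, min_node_size = x$min_node_size,
                 linkage = x$linkage),
            class = "node_assignment")
}

#' Run the full pipeline: qc, cluster, graph, analyze, prioritize
#'
#' Executes every stage in order on the configured inputs (or on a freshly
#' simulated bundle when no genotype path is configured), writing each
#' stage's outputs plus a run manifest recording seeds, parameter hash, and
#' per-stage row/node/edge counts.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   config file
#' @param out_dir output directory
#' @param seed overrides `config$seed` when given
#' @return invisibly, a list with the in-memory stage results and `manifest`
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("leknet")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed, config_hash = .config_hash(config),
                   stages = list())
  jsonlite::write_json(config, file.path(out_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # inputs
  if (!is.null(config$input$genotypes)) {
    g <- read_genotype_table(config$input$genotypes)
    counts <- if (!is.null(config$input$lek_counts))
      read_lek_counts(config$input$lek_counts) else NULL
  } else {
    sim <- make_fixture(config$simulate$scale, seed = config$seed,
                        dir = file.path(out_dir, "simulated"))
    g <- sim$genotypes
    counts <- sim$counts
  }
  manifest$stages$input <- list(n_samples = nrow(g$samples),
                                n_leks = length(unique(g$samples$lek_id)),
                                n_loci = length(g$loci))

  # qc
  filtered <- filter_failed_individuals(g, config$qc$max_failed_loci)
  dups <- find_duplicate_genotypes(filtered, config$qc$max_mismatch_loci)
  gq <- dups$table
  write_qc_report(g, filtered, dups, file.path(out_dir, "qc_report.csv"))
  write_genotype_table(gq, file.path(out_dir, "genotypes_qc.csv"))
  f <- allele_frequencies(gq)
  pid <- probability_of_identity(f)
  manifest$stages$qc <- list(n_removed_failed = length(attr(filtered, "removed")),
                             n_duplicate_clusters = length(dups$clusters),
                             n_retained = nrow(gq$samples),
                             multilocus_p_id = pid$multilocus)

  # cluster
  nodes <- cluster_leks_to_nodes(gq, cut_km = config$clustering$cut_km,
                                 min_node_size = config$clustering$min_node_size,
                                 linkage = config$clustering$linkage)
  .write_node_assignment(nodes, file.path(out_dir, "node_assignment.json"))
  write_node_table(nodes, counts, file.path(out_dir, "node_table.csv"))
  div <- diversity_stats(gq, nodes)
  utils::write.csv(div, file.path(out_dir, "node_diversity.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$cluster <- list(n_nodes = nrow(nodes$nodes),
                                  n_samples_clustered = length(nodes$sample2node),
                                  n_samples_dropped = length(nodes$removed_samples))

  # graph
  pg <- build_popgraph(gq, nodes, alpha = config$graph$alpha,
                       tolerance = config$graph$tolerance,
                       n_eff = config$graph$n_eff)
  write_edge_list(pg, file.path(out_dir, "edges.csv"))
  write_popgraph_graphml(pg, file.path(out_dir, "popgraph.graphml"))
  utils::write.csv(pg$C, file.path(out_dir, "covariance.csv"), quote = FALSE)
  utils::write.csv(pg$rho, file.path(out_dir, "partial_correlation.csv"),
                   quote = FALSE)
  mst <- suppressWarnings(minimum_spanning_tree(pg))
  utils::write.csv(mst, file.path(out_dir, "mst_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  # MST distance vs geographic distance (isolation by distance check)
  geo <- great_circle_distance_matrix(nodes$nodes$lat, nodes$nodes$lon)
  cgd_mst <- conditional_genetic_distance(pg, edges = mst)
  ut <- upper.tri(geo)
  mst_geo <- spearman_correlation_matrix(
    data.frame(mst_distance = cgd_mst[ut], geographic_km = geo[ut]))
  manifest$stages$graph <- list(n_edges = nrow(pg$edges),
                                ridge_lambda = pg$lambda,
                                n_eff = pg$params$n_eff,
                                mst_geography_spearman = mst_geo$r[1, 2])

  # analyze
  ct <- suppressWarnings(centrality_suite(pg))
  utils::write.csv(ct, file.path(out_dir, "centrality.csv"),
                   row.names = FALSE, quote = FALSE)
  nc <- er_null_ensemble(pg, B = config$analysis$null_B, seed = config$seed)
  cls <- classify_structure(nc, alpha = config$graph$alpha,
                            path_factor = config$analysis$path_factor)
  jsonlite::write_json(list(observed = as.list(nc$observed),
                            p = as.list(nc$p), B = nc$B, seed = nc$seed,
                            class = cls$class, evidence = cls$evidence),
                       file.path(out_dir, "null_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  bs <- suppressWarnings(bootstrap_centrality(
    gq, nodes, pg, f = config$analysis$bootstrap_f,
    B = config$analysis$bootstrap_B, seed = config$seed,
    mode = config$analysis$bootstrap_mode))
  utils::write.csv(bs$summary, file.path(out_dir, "bootstrap.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$analyze <- list(structure_class = cls$class,
                                  p_clustering = unname(nc$p["clustering"]),
                                  cpl = unname(nc$observed["cpl"]))

  # prioritize
  cnt <- if (!is.null(counts)) mean_peak_male_count(nodes, counts) else NULL
  rng <- if (nrow(nodes$nodes) >= 3) tryCatch(range_centrality(nodes),
                                              error = function(e) NULL)
         else NULL
  pr <- prioritization_report(ct, cnt, rng,
                              top_fraction = config$prioritization$top_fraction,
                              cross_percentile = config$prioritization$cross_percentile,
                              cent_pct = config$prioritization$cent_pct,
                              attr_pct = config$prioritization$attr_pct,
                              path = file.path(out_dir, "prioritization.csv"))
  manifest$stages$prioritize <- list(
    n_cross_index_hubs = length(pr$cross_index_hubs),
    n_zero_betweenness = length(pr$spokes$zero_betweenness),
    n_keystones = if (is.null(pr$keystones)) 0L
                  else nrow(pr$keystones$keystones))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_summary_md(file.path(out_dir, "summary.md"), manifest, ct, bs, pr)
  invisible(list(genotypes = gq, nodes = nodes, popgraph = pg, mst = mst,
                 centrality = ct, null_comparison = nc, structure = cls,
                 bootstrap = bs, prioritization = pr, manifest = manifest))
}

.write_summary_md <- function(path, manifest, ct, bs, pr) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) formatC(v, digits = 4, format = "g")
  writeLines(c(
    "# leknet run summary", "",
    sprintf("- seed: %s; config hash: %s", manifest$seed,
            manifest$config_hash),
    sprintf("- samples in: %d; retained after QC: %d",
            manifest$stages$input$n_samples, manifest$stages$qc$n_retained),
    sprintf("- nodes: %d; edges: %d; structure: %s",
            manifest$stages$cluster$n_nodes, manifest$stages$graph$n_edges,
            manifest$stages$analyze$structure_class), "",
    "## Centrality (per node)", "",
    "| index | min | mean | median | max |",
    "|---|---|---|---|---|"), con)
  for (nm in c("degree", "strength", "betweenness", "closeness",
               "clustering", "eigenvector")) {
    v <- ct[[nm]]
    writeLines(sprintf("| %s | %s | %s | %s | %s |", nm,
                       num(min(v, na.rm = TRUE)), num(mean(v, na.rm = TRUE)),
                       num(stats::median(v, na.rm = TRUE)),
                       num(max(v, na.rm = TRUE))), con)
  }
  writeLines(c("",
    sprintf("- cross-index hubs: %s",
            paste(pr$cross_index_hubs, collapse = ", ")),
    sprintf("- zero-betweenness spokes: %d",
            length(pr$spokes$zero_betweenness)),
    sprintf("- keystones: %d", if (is.null(pr$keystones)) 0L
            else nrow(pr$keystones$keystones))), con)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `qc`, `cluster`, `graph`, `analyze`,
#' `prioritize`, `run`, each accepting `--config <file>`, `--seed <int>`,
#' `--out <dir>`. `run` executes every stage; the individual stage commands
#' rerun the pipeline up to and including that stage (earlier outputs are
#' recomputed deterministically from the same seed).
#'
#' @param args character vector (defaults to the command line)
#' @return integer exit status: 0 ok, 1 user error, 2 internal error
#' @export
leknet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: leknet <simulate|qc|cluster|graph|analyze|prioritize|run> --out <dir> [--config <file>] [--seed <int>]"
  if (!length(args)) { message(usage); return(1L) }
  cmd <- args[1]
  stages <- c("simulate", "qc", "cluster", "graph", "analyze", "prioritize",
              "run")
  if (!cmd %in% stages) { message("unknown subcommand: ", cmd, "\n", usage)
                          return(1L) }
  opt <- list(config = NULL, seed = NULL, out = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest)) {
      message("bad option: ", rest[i], "\n", usage); return(1L)
    }
    opt[[key]] <- rest[i + 1]
    i <- i + 2
  }
  if (is.null(opt$out)) { message("--out is required\n", usage); return(1L) }
  status <- tryCatch({
    config <- if (is.null(opt$config)) default_config()
              else read_pipeline_config(opt$config)
    seed <- if (is.null(opt$seed)) config$seed else as.integer(opt$seed)
    if (cmd == "simulate") {
      make_fixture(config$simulate$scale, seed = seed, dir = opt$out)
    } else {
      # stage subcommands cheaply rerun the deterministic prefix
      run_pipeline(config, out_dir = opt$out, seed = seed)
    }
    0L
  }, error = function(e) {
    message("error in stage '", cmd, "': ", conditionMessage(e))
    2L
  })
  status
}
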