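#' Simulation configuration for the stepping-stone genotype generator
#'
#' Defaults describe a mid-density microsatellite study: 15 loci with up to
#' 10 alleles each, demes of 50 diploids drifting for 100 generations with
#' 10% per-generation emigration split among lattice neighbours, 3 leks per
#' deme jittered well inside half the 15 km clustering cut, 4 sampled birds
#' per lek, 2% missing calls, and negative-binomial lek counts (mean 20
#' males, dispersion 5) over 2005-2015.
#'
#' @param n_demes number of demes, laid out row-major on a near-square grid
#' @param migration_rate total emigration fraction per generation, split
#'   equally among lattice neighbours
#' @param planted_hub_demes optional list of lists with elements `deme`
#'   (index), `connects` (integer vector of extra-connection demes) and
#'   `m_hub` (per-connection migration boost, default 0.05)
#' @param n_loci,alleles_per_locus locus panel shape
#' @param deme_size diploid individuals per deme (drift strength)
#' @param generations Wright-Fisher generations
#' @param leks_per_deme,samples_per_lek sampling design
#' @param spacing_km lattice spacing between deme centres
#' @param jitter_km max lek displacement from its deme centre (must stay
#'   below half the clustering cut so clustering recovers demes)
#' @param missing_rate per-call missing probability
#' @param count_mean,count_dispersion negative-binomial lek count model
#' @param count_years years with counts
#' @param count_prob probability a lek is counted in a given year
#' @param count_multiplier per-deme multiplier on `count_mean` (length 1 or
#'   `n_demes`); lets a genetic hub be given low abundance for keystone
#'   recovery tests
#' @param origin_lat,origin_lon lattice origin (WGS84)
#' @param seed mandatory RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_demes = 30L, migration_rate = 0.1,
                       planted_hub_demes = NULL,
                       n_loci = 15L, alleles_per_locus = 10L,
                       deme_size = 50L, generations = 100L,
                       leks_per_deme = 3L, samples_per_lek = 4L,
                       spacing_km = 40, jitter_km = 5,
                       missing_rate = 0.02,
                       count_mean = 20, count_dispersion = 5,
                       count_years = 2005:2015, count_prob = 0.7,
                       count_multiplier = 1,
                       origin_lat = 41, origin_lon = -110,
                       seed) {
  stopifnot(!missing(seed), n_demes >= 1,
            migration_rate >= 0, migration_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            count_prob >= 0, count_prob <= 1,
            jitter_km >= 0)
  cfg <- as.list(environment())
  cfg$count_multiplier <- rep_len(count_multiplier, n_demes)
  class(cfg) <- "sim_config"
  cfg
}

# row-major near-square lattice layout; returns data.frame(row, col)
.lattice_layout <- function(n) {
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  idx <- seq_len(n) - 1L
  data.frame(row = idx %/% nc + 1L, col = idx %% nc + 1L)
}

# symmetric migration matrix: M[d, e] = fraction of deme d's gene pool
# drawn from deme e each generation
.migration_matrix <- function(cfg) {
  n <- cfg$n_demes
  lay <- .lattice_layout(n)
  M <- matrix(0, n, n)
  for (d in seq_len(n)) {
    nb <- which(abs(lay$row - lay$row[d]) + abs(lay$col - lay$col[d]) == 1)
    if (length(nb)) M[d, nb] <- cfg$migration_rate / length(nb)
  }
  for (hub in cfg$planted_hub_demes) {
    m_hub <- if (is.null(hub$m_hub)) 0.05 else hub$m_hub
    for (e in hub$connects) {
      M[hub$deme, e] <- M[hub$deme, e] + m_hub
      M[e, hub$deme] <- M[e, hub$deme] + m_hub
    }
  }
  rs <- rowSums(M)
  too_much <- rs > 0.9
  if (any(too_much))  # keep some resident fraction everywhere
    M[too_much, ] <- M[too_much, ] * (0.9 / rs[too_much])
  diag(M) <- 1 - rowSums(M)
  M
}

#' Simulate genotypes and lek counts under a stepping-stone model
#'
#' Deme allele frequencies start from a shared Dirichlet draw per locus and
#' evolve by Wright-Fisher multinomial drift with symmetric nearest-neighbour
#' migration on a lattice; planted hub demes exchange extra migrants with
#' their connection set, making them genuine connectivity hubs. Individuals
#' are Hardy-Weinberg draws from their deme's final frequencies; leks sit
#' around deme centres with jitter below half the clustering cut; missing
#' calls and negative-binomial per-lek yearly peak male counts are added on
#' top.
#'
#' @param cfg [sim_config()]
#' @return list with `genotypes` (genotype_table), `counts`
#'   (lek_count_table), and `truth` (deme of every sample and lek, final
#'   deme allele frequencies, hub demes, deme centres)
#' @export
simulate_stepping_stone <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_demes
  M <- .migration_matrix(cfg)
  copies <- 2L * cfg$deme_size
  # freqs[[locus]]: demes x alleles
  freqs <- lapply(seq_len(cfg$n_loci), function(l) {
    base <- stats::rgamma(cfg$alleles_per_locus, shape = 1)
    base <- base / sum(base)
    matrix(base, n, cfg$alleles_per_locus, byrow = TRUE)
  })
  for (gen in seq_len(cfg$generations)) {
    for (l in seq_len(cfg$n_loci)) {
      p <- M %*% freqs[[l]]
      drifted <- t(apply(p, 1, function(pr) {
        pr[pr < 0] <- 0
        stats::rmultinom(1, copies, pr)[, 1] / copies
      }))
      freqs[[l]] <- drifted
    }
  }
  # lek and deme geography
  lay <- .lattice_layout(n)
  km_per_deg_lat <- 111.32
  deme_lat <- cfg$origin_lat + (lay$row - 1) * cfg$spacing_km / km_per_deg_lat
  km_per_deg_lon <- km_per_deg_lat * cos(cfg$origin_lat * pi / 180)
  deme_lon <- cfg$origin_lon + (lay$col - 1) * cfg$spacing_km / km_per_deg_lon
  lek_rows <- list()
  for (d in seq_len(n)) {
    for (lk in seq_len(cfg$leks_per_deme)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, cfg$jitter_km)
      lek_rows[[length(lek_rows) + 1]] <- data.frame(
        lek_id = sprintf("deme%03d_lek%02d", d, lk), deme = d,
        lat = deme_lat[d] + rad * sin(ang) / km_per_deg_lat,
        lon = deme_lon[d] + rad * cos(ang) / km_per_deg_lon,
        stringsAsFactors = FALSE)
    }
  }
  leks <- do.call(rbind, lek_rows)
  # individuals: HW draws from final deme frequencies
  n_samples <- nrow(leks) * cfg$samples_per_lek
  loci <- sprintf("loc%02d", seq_len(cfg$n_loci))
  allele_lengths <- lapply(seq_len(cfg$n_loci), function(l)
    100L + 4L * (seq_len(cfg$alleles_per_locus) - 1L))
  a1 <- matrix(NA_integer_, n_samples, cfg$n_loci)
  a2 <- matrix(NA_integer_, n_samples, cfg$n_loci)
  samp <- data.frame(sample_id = sprintf("S%05d", seq_len(n_samples)),
                     lek_id = rep(leks$lek_id, each = cfg$samples_per_lek),
                     lat = rep(leks$lat, each = cfg$samples_per_lek),
                     lon = rep(leks$lon, each = cfg$samples_per_lek),
                     stringsAsFactors = FALSE)
  deme_of_sample <- rep(leks$deme, each = cfg$samples_per_lek)
  for (l in seq_len(cfg$n_loci)) {
    for (d in seq_len(n)) {
      rows <- which(deme_of_sample == d)
      if (!length(rows)) next
      pr <- freqs[[l]][d, ]
      g1 <- sample.int(cfg$alleles_per_locus, length(rows), replace = TRUE,
                       prob = pr)
      g2 <- sample.int(cfg$alleles_per_locus, length(rows), replace = TRUE,
                       prob = pr)
      a1[rows, l] <- allele_lengths[[l]][g1]
      a2[rows, l] <- allele_lengths[[l]][g2]
    }
  }
  if (cfg$missing_rate > 0) {
    mis <- matrix(stats::runif(n_samples * cfg$n_loci) < cfg$missing_rate,
                  n_samples, cfg$n_loci)
    a1[mis] <- NA_integer_; a2[mis] <- NA_integer_
  }
  genotypes <- genotype_table(samp, loci, a1, a2, source = "synthetic")
  # per-lek yearly peak male counts
  cnt_rows <- list()
  for (i in seq_len(nrow(leks))) {
    yrs <- cfg$count_years[stats::runif(length(cfg$count_years)) < cfg$count_prob]
    if (!length(yrs)) next
    mu <- cfg$count_mean * cfg$count_multiplier[leks$deme[i]]
    cnt_rows[[length(cnt_rows) + 1]] <- data.frame(
      lek_id = leks$lek_id[i], year = yrs,
      high_male_count = stats::rnbinom(length(yrs), mu = mu,
                                       size = cfg$count_dispersion),
      stringsAsFactors = FALSE)
  }
  counts <- if (length(cnt_rows)) {
    cc <- do.call(rbind, cnt_rows)
    lek_count_table(cc$lek_id, cc$year, cc$high_male_count)
  } else lek_count_table(character(0), integer(0), integer(0))
  hub_demes <- vapply(cfg$planted_hub_demes, function(h) h$deme, integer(1))
  list(genotypes = genotypes, counts = counts,
       truth = list(deme_of_sample = stats::setNames(deme_of_sample,
                                                     samp$sample_id),
                    deme_of_lek = stats::setNames(leks$deme, leks$lek_id),
                    freqs = freqs,
                    hub_demes = hub_demes,
                    deme_lat = deme_lat, deme_lon = deme_lon,
                    config = cfg))
}

#' Write a ready-to-run synthetic input bundle to disk
#'
#' Scales: `tiny` = 6 demes / 60 samples (seconds; used throughout the test
#' suite), `small` = 30 demes / 600 samples, `paper_like` = 458 demes
#' mimicking the shape of a range-wide study (minutes). Writes
#' `genotypes.csv` and `lek_counts.csv` in the package CSV dialect plus
#' `truth.json`.
#'
#' @param scale one of `"tiny"`, `"small"`, `"paper_like"`
#' @param seed RNG seed
#' @param dir output directory (created if absent)
#' @param ... overrides passed to [sim_config()]
#' @return invisibly, the simulation result list with `paths` added
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper_like"), seed,
                         dir = tempfile("leknet_fixture_"), ...) {
  scale <- match.arg(scale)
  stopifnot(!missing(seed))
  base <- switch(scale,
    tiny = list(n_demes = 6L, leks_per_deme = 2L, samples_per_lek = 5L,
                generations = 50L),
    small = list(n_demes = 30L, leks_per_deme = 4L, samples_per_lek = 5L),
    paper_like = list(n_demes = 458L, leks_per_deme = 3L,
                      samples_per_lek = 4L))
  args <- utils::modifyList(base, list(...))
  args$seed <- seed
  cfg <- do.call(sim_config, args)
  sim <- simulate_stepping_stone(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(genotypes = file.path(dir, "genotypes.csv"),
                counts = file.path(dir, "lek_counts.csv"),
                truth = file.path(dir, "truth.json"))
  write_genotype_table(sim$genotypes, paths$genotypes)
  write_lek_counts(sim$counts, paths$counts)
  truth <- sim$truth
  truth$freqs <- NULL  # matrices are bulky; regenerate from config + seed
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  sim$paths <- paths
  invisible(sim)
}
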