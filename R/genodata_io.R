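#' Construct a genotype table
#'
#' The central input container: one row per sampled individual, two allele
#' lengths (base pairs) per microsatellite locus, plus the lek of capture and
#' its WGS84 coordinates. Missing genotypes are locus-level: both alleles of a
#' locus are `NA` or neither is.
#'
#' @param samples data.frame with columns `sample_id`, `lek_id`, `lat`, `lon`.
#' @param loci character vector of locus names (ordered, unique).
#' @param a1,a2 integer matrices (samples x loci) of allele lengths; `NA` for
#'   missing. A call with exactly one `NA` allele is coerced to fully missing
#'   with a warning (half-calls are treated as amplification failure).
#' @param source one of `"feather"`, `"blood"`, `"synthetic"`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, loci, a1, a2, source = "synthetic") {
  source <- match.arg(source, c("feather", "blood", "synthetic"))
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "lek_id", "lat", "lon") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$lek_id <- as.character(samples$lek_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (any(samples$lat < -90 | samples$lat > 90, na.rm = TRUE) ||
      any(samples$lon < -180 | samples$lon > 180, na.rm = TRUE))
    stop("coordinates outside [-90,90] lat / [-180,180] lon")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(samples), ncol(a1) == length(loci),
            identical(dim(a1), dim(a2)))
  dimnames(a1) <- dimnames(a2) <- list(samples$sample_id, loci)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing call(s) coerced to MISSING")
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele lengths must be positive")
  # store unordered pairs canonically: a1 <= a2
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  structure(list(samples = samples[, c("sample_id", "lek_id", "lat", "lon")],
                 loci = as.character(loci), a1 = a1, a2 = a2,
                 source = source),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d loci (%d leks, %d missing calls, source=%s)\n",
              nrow(x$samples), length(x$loci),
              length(unique(x$samples$lek_id)), sum(is.na(x$a1)), x$source))
  invisible(x)
}

#' Number of missing loci per sample
#' @param g genotype_table
#' @return named integer vector
#' @export
missing_loci_count <- function(g) {
  n <- rowSums(is.na(g$a1))
  stats::setNames(as.integer(n), g$samples$sample_id)
}

#' Subset a genotype table by sample ids
#' @param g genotype_table
#' @param sample_ids character vector of ids to keep (order preserved from `g`)
#' @return genotype_table
#' @export
subset_samples <- function(g, sample_ids) {
  keep <- g$samples$sample_id %in% sample_ids
  genotype_table(g$samples[keep, , drop = FALSE], g$loci,
                 g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE],
                 g$source)
}

#' Define a microsatellite locus panel
#'
#' @param locus character locus names (unique).
#' @param motif_length integer repeat-unit size per locus (>= 1).
#' @param known_offset optional integer ladder anchor per locus (>= 0).
#' @return data.frame of class `locus_panel`.
#' @export
locus_panel <- function(locus, motif_length = 1L, known_offset = 0L) {
  locus <- as.character(locus)
  if (anyDuplicated(locus)) stop("locus names must be unique")
  motif_length <- as.integer(rep_len(motif_length, length(locus)))
  known_offset <- as.integer(rep_len(known_offset, length(locus)))
  if (any(motif_length < 1L)) stop("motif_length must be >= 1")
  if (any(known_offset < 0L)) stop("known_offset must be >= 0")
  structure(data.frame(locus = locus, motif_length = motif_length,
                       known_offset = known_offset,
                       stringsAsFactors = FALSE),
            class = c("locus_panel", "data.frame"))
}

#' Read a genotype CSV
#'
#' Expected dialect: header `sample_id,lek_id,lat,lon` followed by two columns
#' per locus named `<locus>_1` and `<locus>_2`. Missing alleles are encoded as
#' `0` or an empty field; a half-missing call is coerced to fully missing with
#' a warning. Row order is preserved.
#'
#' @param path CSV path.
#' @param panel optional [locus_panel()]; when given, the file must contain
#'   exactly the panel's loci (in any order) and loci are returned panel-ordered.
#' @param source sample source label.
#' @return [genotype_table()]
#' @export
read_genotype_table <- function(path, panel = NULL, source = "synthetic") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta_cols <- c("sample_id", "lek_id", "lat", "lon")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  allele_cols <- setdiff(names(df), meta_cols)
  bad <- allele_cols[!grepl("_[12]$", allele_cols)]
  if (length(bad))
    stop("malformed header: unrecognized column(s) ", paste(bad, collapse = ", "))
  loci <- unique(sub("_[12]$", "", allele_cols))
  for (lc in loci) {
    for (suf in c("_1", "_2")) {
      if (!paste0(lc, suf) %in% allele_cols)
        stop("malformed header: missing column ", paste0(lc, suf))
    }
  }
  if (!is.null(panel)) {
    extra <- setdiff(loci, panel$locus)
    absent <- setdiff(panel$locus, loci)
    if (length(extra) || length(absent))
      stop("loci do not match panel; extra: [", paste(extra, collapse = ","),
           "] absent: [", paste(absent, collapse = ","), "]")
    loci <- panel$locus
  }
  parse_allele <- function(v, colname) {
    v <- trimws(v)
    v[v == ""] <- "0"
    suppressWarnings(x <- as.integer(v))
    if (anyNA(x)) {
      bad_row <- which(is.na(x))[1]
      stop("non-integer allele in column '", colname, "' at data row ", bad_row)
    }
    x[x == 0L] <- NA_integer_
    x
  }
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    a1[, j] <- parse_allele(df[[paste0(loci[j], "_1")]], paste0(loci[j], "_1"))
    a2[, j] <- parse_allele(df[[paste0(loci[j], "_2")]], paste0(loci[j], "_2"))
  }
  samples <- data.frame(sample_id = df$sample_id, lek_id = df$lek_id,
                        lat = as.numeric(df$lat), lon = as.numeric(df$lon),
                        stringsAsFactors = FALSE)
  genotype_table(samples, loci, a1, a2, source = source)
}

#' Write a genotype table to CSV (inverse of [read_genotype_table()])
#' @param g genotype_table
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  out <- g$samples
  for (j in seq_along(g$loci)) {
    v1 <- g$a1[, j]; v2 <- g$a2[, j]
    v1[is.na(v1)] <- 0L; v2[is.na(v2)] <- 0L
    out[[paste0(g$loci[j], "_1")]] <- v1
    out[[paste0(g$loci[j], "_2")]] <- v2
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-lek yearly high male counts
#'
#' @param path CSV with columns `lek_id`, `year`, `high_male_count` (the
#'   column name `count` is accepted as an alias).
#' @param years optional integer window; records outside it are rejected.
#' @return data.frame of class `lek_count_table`.
#' @export
read_lek_counts <- function(path, years = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("count" %in% names(df) && !"high_male_count" %in% names(df))
    names(df)[names(df) == "count"] <- "high_male_count"
  need <- c("lek_id", "year", "high_male_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  lek_count_table(df$lek_id, df$year, df$high_male_count, years = years)
}

#' Construct a validated lek count table
#' @param lek_id,year,high_male_count record vectors
#' @param years optional allowed year window (integer vector)
#' @return data.frame of class `lek_count_table`
#' @export
lek_count_table <- function(lek_id, year, high_male_count, years = NULL) {
  df <- data.frame(lek_id = as.character(lek_id), year = as.integer(year),
                   high_male_count = as.integer(high_male_count),
                   stringsAsFactors = FALSE)
  if (any(df$high_male_count < 0, na.rm = TRUE))
    stop("negative high_male_count")
  key <- paste(df$lek_id, df$year)
  if (anyDuplicated(key))
    stop("duplicate (lek, year) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(years) && any(!df$year %in% years))
    stop("year(s) outside configured window: ",
         paste(unique(df$year[!df$year %in% years]), collapse = ", "))
  structure(df, class = c("lek_count_table", "data.frame"))
}

#' Write a lek count table to CSV
#' @param counts lek_count_table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lek_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a population graph as GraphML
#' @param pg popgraph (see [build_popgraph()])
#' @param path output .graphml path
#' @return `path`, invisibly
#' @export
write_popgraph_graphml <- function(pg, path) {
  igraph::write_graph(as_igraph(pg), path, format = "graphml")
  invisible(path)
}

#' Export a population graph edge list as CSV
#' @param pg popgraph
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(pg, path) {
  utils::write.csv(pg$edges[, c("node_a", "node_b", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
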