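#' Per-locus allele frequencies
#'
#' Counts gene copies at each locus (two per non-missing genotype) and returns
#' relative frequencies. Frequencies at a locus sum to 1 whenever any copies
#' were observed.
#'
#' @param g genotype_table
#' @param sample_ids optional subset of samples to tabulate
#' @return list of class `allele_frequencies`: per locus a named numeric
#'   vector of frequencies (names = allele length) with attribute
#'   `n_gene_copies`.
#' @export
allele_frequencies <- function(g, sample_ids = NULL) {
  idx <- if (is.null(sample_ids)) seq_len(nrow(g$samples))
         else match(sample_ids, g$samples$sample_id)
  out <- lapply(seq_along(g$loci), function(j) {
    copies <- c(g$a1[idx, j], g$a2[idx, j])
    copies <- copies[!is.na(copies)]
    if (!length(copies))
      return(structure(numeric(0), n_gene_copies = 0L))
    tab <- table(copies)
    structure(as.numeric(tab) / length(copies),
              names = names(tab), n_gene_copies = length(copies))
  })
  names(out) <- g$loci
  class(out) <- "allele_frequencies"
  out
}

#' Remove individuals whose amplification failed at too many loci
#'
#' A sample is removed when the number of missing loci is greater than or
#' equal to `max_failed_loci` (default 5 of a 15-locus panel, i.e. failure at
#' one third of the loci).
#'
#' @param g genotype_table
#' @param max_failed_loci removal threshold (failed at >= threshold => removed)
#' @return genotype_table of retained samples; removed ids in attribute
#'   `removed`.
#' @export
filter_failed_individuals <- function(g, max_failed_loci = 5L) {
  stopifnot(max_failed_loci >= 0)
  nmiss <- missing_loci_count(g)
  removed <- names(nmiss)[nmiss >= max_failed_loci]
  if (length(removed))
    message("filter_failed_individuals: removed ", length(removed),
            " sample(s) with >= ", max_failed_loci, " failed loci")
  out <- subset_samples(g, setdiff(g$samples$sample_id, removed))
  attr(out, "removed") <- removed
  out
}

#' Detect and collapse duplicate genotypes
#'
#' Two samples match when their genotypes disagree at no more than
#' `max_mismatch_loci` loci, comparing only loci non-missing in both (no
#' shared loci means no match). Clusters are transitive closures of pairwise
#' matches; the retained representative has the fewest missing loci, ties
#' broken by lexicographic sample id.
#'
#' @param g genotype_table
#' @param max_mismatch_loci allowed mismatching loci (default 0 = exact)
#' @return list with `clusters` (list of sample-id character vectors, size
#'   >= 2) and `table` (deduplicated genotype_table).
#' @export
find_duplicate_genotypes <- function(g, max_mismatch_loci = 0L) {
  stopifnot(max_mismatch_loci >= 0)
  n <- nrow(g$samples)
  ids <- g$samples$sample_id
  pairs_a <- integer(0); pairs_b <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (k in seq(i + 1, n)) {
        shared <- !is.na(g$a1[i, ]) & !is.na(g$a1[k, ])
        if (!any(shared)) next
        mm <- sum(g$a1[i, shared] != g$a1[k, shared] |
                  g$a2[i, shared] != g$a2[k, shared])
        if (mm <= max_mismatch_loci) {
          pairs_a <- c(pairs_a, i); pairs_b <- c(pairs_b, k)
        }
      }
    }
  }
  # transitive closure via graph components
  gr <- igraph::make_graph(as.vector(rbind(pairs_a, pairs_b)), n = n,
                           directed = FALSE)
  comp <- igraph::components(gr)$membership
  clusters <- split(ids, comp)
  clusters <- unname(clusters[vapply(clusters, length, 1L) >= 2])
  clusters <- lapply(clusters, sort)
  nmiss <- missing_loci_count(g)
  drop <- unlist(lapply(clusters, function(cl) {
    rep_id <- cl[order(nmiss[cl], cl)][1]
    setdiff(cl, rep_id)
  }))
  keep <- setdiff(ids, drop)
  if (length(drop))
    message("find_duplicate_genotypes: collapsed ", length(clusters),
            " cluster(s), removed ", length(drop), " duplicate sample(s)")
  list(clusters = clusters, table = subset_samples(g, keep))
}

#' Probability of identity
#'
#' Power of the locus panel to distinguish individuals: the probability that
#' two individuals drawn at random share the same genotype. Per locus
#' \eqn{P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}; the multilocus
#' value is the product over loci.
#'
#' @param f allele_frequencies
#' @return list with `per_locus` (named numeric) and `multilocus` (product
#'   over loci with observed gene copies; loci without copies are excluded
#'   with a warning).
#' @export
probability_of_identity <- function(f) {
  per_locus <- vapply(f, function(p) {
    if (!length(p)) return(NA_real_)
    hom <- sum(p^4)
    het <- 0
    if (length(p) > 1) {
      for (i in seq_len(length(p) - 1))
        for (j in seq(i + 1, length(p)))
          het <- het + (2 * p[i] * p[j])^2
    }
    hom + het
  }, numeric(1))
  if (anyNA(per_locus))
    warning("locus/loci with zero gene copies excluded from multilocus P_ID: ",
            paste(names(per_locus)[is.na(per_locus)], collapse = ", "))
  list(per_locus = per_locus,
       multilocus = prod(per_locus, na.rm = TRUE))
}

.locus_stats <- function(a1, a2, unbiased = FALSE) {
  ok <- !is.na(a1)
  if (!any(ok))
    return(c(A = NA, Ae = NA, He = NA, Ho = NA, Fis = NA))
  copies <- c(a1[ok], a2[ok])
  p <- as.numeric(table(copies)) / length(copies)
  sp2 <- sum(p^2)
  He <- 1 - sp2
  if (unbiased) {
    nn <- length(copies)
    He <- He * nn / (nn - 1)
  }
  Ho <- mean(a1[ok] != a2[ok])
  c(A = length(p), Ae = 1 / sp2, He = He, Ho = Ho,
    Fis = if (He > 0) 1 - Ho / He else NA_real_)
}

#' Genetic diversity statistics per group
#'
#' Per locus within each group: number of alleles A, effective number of
#' alleles \eqn{A_e = 1/\sum p_i^2}, expected heterozygosity
#' \eqn{H_e = 1-\sum p_i^2} (uncorrected gene diversity; set
#' `unbiased = TRUE` for the \eqn{2n/(2n-1)} correction), observed
#' heterozygosity \eqn{H_o}, and \eqn{F_{IS} = 1 - H_o/H_e} (`NA` when
#' \eqn{H_e = 0}). The group summary is the across-locus mean and SD,
#' excluding `NA` loci. A multilocus \eqn{F_{IS}} (ratio of across-locus mean
#' \eqn{H_o} to mean \eqn{H_e}) is also reported.
#'
#' @param g genotype_table
#' @param grouping a `node_assignment` (see [cluster_leks_to_nodes()]) or
#'   `"pooled"` for a single all-sample group.
#' @param unbiased use small-sample-corrected He (default FALSE)
#' @return data.frame, one row per group: means, SDs, and `Fis_multi`.
#' @export
diversity_stats <- function(g, grouping = "pooled", unbiased = FALSE) {
  groups <- if (identical(grouping, "pooled")) {
    list(pooled = g$samples$sample_id)
  } else {
    stopifnot(inherits(grouping, "node_assignment"))
    split(names(grouping$sample2node), grouping$sample2node)
  }
  rows <- lapply(names(groups), function(gn) {
    idx <- match(groups[[gn]], g$samples$sample_id)
    per_locus <- t(vapply(seq_along(g$loci), function(j)
      .locus_stats(g$a1[idx, j], g$a2[idx, j], unbiased), numeric(5)))
    colnames(per_locus) <- c("A", "Ae", "He", "Ho", "Fis")
    m <- apply(per_locus, 2, mean, na.rm = TRUE)
    s <- apply(per_locus, 2, stats::sd, na.rm = TRUE)
    mHe <- m["He"]
    data.frame(group = gn, n_samples = length(idx),
               A = m["A"], A_sd = s["A"], Ae = m["Ae"], Ae_sd = s["Ae"],
               He = m["He"], He_sd = s["He"], Ho = m["Ho"], Ho_sd = s["Ho"],
               Fis = m["Fis"], Fis_sd = s["Fis"],
               Fis_multi = if (!is.na(mHe) && mHe > 0) 1 - m["Ho"] / mHe
                           else NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Flag alleles off the repeat-motif ladder
#'
#' At each locus, allele lengths should be congruent modulo the repeat motif
#' length; alleles outside the modal congruence class are flagged (nothing is
#' corrected).
#'
#' @param g genotype_table
#' @param panel locus_panel with `motif_length` per locus
#' @return data.frame with columns sample_id, locus, allele (0 rows when
#'   everything is on-ladder)
#' @export
motif_consistency_check <- function(g, panel) {
  stopifnot(all(g$loci %in% panel$locus))
  out <- list()
  for (j in seq_along(g$loci)) {
    ml <- panel$motif_length[match(g$loci[j], panel$locus)]
    if (ml <= 1L) next
    alleles <- c(g$a1[, j], g$a2[, j])
    present <- !is.na(alleles)
    if (!any(present)) next
    cls <- alleles[present] %% ml
    modal <- as.integer(names(which.max(table(cls))))
    bad <- present & (alleles %% ml != modal)
    if (any(bad)) {
      sid <- rep(g$samples$sample_id, 2L)
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid[bad], locus = g$loci[j], allele = alleles[bad],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), locus = character(0),
                      allele = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$locus, res$allele), , drop = FALSE]
}

#' Write a per-sample QC report
#' @param g genotype_table (pre-filtering)
#' @param filtered result of [filter_failed_individuals()]
#' @param dups result of [find_duplicate_genotypes()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_qc_report <- function(g, filtered, dups, path) {
  nmiss <- missing_loci_count(g)
  removed_fail <- attr(filtered, "removed")
  kept <- dups$table$samples$sample_id
  cluster_id <- rep(NA_integer_, nrow(g$samples))
  for (i in seq_along(dups$clusters))
    cluster_id[g$samples$sample_id %in% dups$clusters[[i]]] <- i
  utils::write.csv(data.frame(
    sample_id = g$samples$sample_id,
    n_missing_loci = as.integer(nmiss),
    removed_failed = g$samples$sample_id %in% removed_fail,
    duplicate_cluster = cluster_id,
    kept = g$samples$sample_id %in% kept,
    stringsAsFactors = FALSE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
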