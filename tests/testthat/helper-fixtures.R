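# Small genotype tables built in code for unit tests.

make_test_genotypes <- function(n = 4, loci = c("locA", "locB"),
                                leks = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(leks)) leks <- rep("lek1", n)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        lek_id = leks,
                        lat = 41 + seq_len(n) * 0.001,
                        lon = -110 + seq_len(n) * 0.001,
                        stringsAsFactors = FALSE)
  a1 <- matrix(sample(c(150L, 152L, 154L), n * length(loci), replace = TRUE),
               n, length(loci))
  a2 <- matrix(sample(c(150L, 152L, 154L), n * length(loci), replace = TRUE),
               n, length(loci))
  genotype_table(samples, loci, a1, a2)
}

# random valid genotype table for round-trip property tests
random_genotype_table <- function(n_samples, n_loci, missing_rate = 0.1) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n_samples)),
                        lek_id = sprintf("lek%d", sample.int(3, n_samples,
                                                             replace = TRUE)),
                        lat = stats::runif(n_samples, 40, 42),
                        lon = stats::runif(n_samples, -112, -108),
                        stringsAsFactors = FALSE)
  a1 <- matrix(sample(seq(100L, 140L, by = 4L), n_samples * n_loci,
                      replace = TRUE), n_samples, n_loci)
  a2 <- matrix(sample(seq(100L, 140L, by = 4L), n_samples * n_loci,
                      replace = TRUE), n_samples, n_loci)
  mis <- matrix(stats::runif(n_samples * n_loci) < missing_rate,
                n_samples, n_loci)
  a1[mis] <- NA_integer_; a2[mis] <- NA_integer_
  genotype_table(samples, loci, a1, a2)
}
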