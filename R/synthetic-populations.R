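#' Simulate a pair of divergent populations at diagnostic SNPs
#'
#' Draws per-SNP allele frequencies for two populations whose absolute
#' frequency differentials follow a requested distribution, emulating the
#' strongly differentiated loci that separate spawning ecotypes, inversion
#' haplotypes or salinity-adapted groups.  For each SNP a differential `d` is
#' drawn, the lower frequency is drawn uniformly on `[0, 1 - d]`, and which
#' population carries the higher frequency is randomised.
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param delta_p Differential distribution: a single value in `[0, 1]` for a
#'   fixed differential, or a length-2 range `c(lo, hi)` for
#'   `Uniform(lo, hi)`.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param labels Names of the two populations.
#' @param chrom Chromosome id for all SNPs.
#' @param chrom_length_bp Chromosome length; SNP positions are drawn uniformly
#'   without replacement and sorted.
#' @return A `two_pop_truth`: list with `snps` (data frame `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `freq1`, `freq2`, where `freq*` is the frequency
#'   of `allele_a` in each population) and `labels`.
#' @examples
#' tr <- simulate_divergent_populations(5, delta_p = 1, seed = 1)
#' tr$snps
#' @export
simulate_divergent_populations <- function(n_snps, delta_p = c(0.5, 1),
                                           seed = 1,
                                           labels = c("pop_a", "pop_b"),
                                           chrom = "1",
                                           chrom_length_bp = max(1e6, n_snps * 1000)) {
  stopifnot(n_snps >= 1, length(labels) == 2, chrom_length_bp >= n_snps)
  if (!is.numeric(delta_p) || !length(delta_p) %in% 1:2 ||
      any(delta_p < 0 | delta_p > 1) ||
      (length(delta_p) == 2 && delta_p[1] > delta_p[2])) {
    stop_input("`delta_p` must be a value in [0,1] or an increasing range within it")
  }
  withr::with_seed(seed, {
    d <- if (length(delta_p) == 1) rep(delta_p, n_snps) else
      stats::runif(n_snps, delta_p[1], delta_p[2])
    p_low <- stats::runif(n_snps, 0, 1 - d)
    hi_in_1 <- stats::runif(n_snps) < 0.5
    freq1 <- ifelse(hi_in_1, p_low + d, p_low)
    freq2 <- ifelse(hi_in_1, p_low, p_low + d)
    pos <- sort(sample.int(chrom_length_bp, n_snps))
    ab <- random_allele_pairs(n_snps)
  })
  structure(list(
    snps = data.frame(chrom = chrom, pos = pos,
                      allele_a = ab[, 1], allele_b = ab[, 2],
                      freq1 = freq1, freq2 = freq2,
                      stringsAsFactors = FALSE),
    labels = labels), class = "two_pop_truth")
}

#' @export
print.two_pop_truth <- function(x, ...) {
  cat(sprintf("<two_pop_truth> %d SNPs; %s vs %s; mean |dp| = %.3f\n",
              nrow(x$snps), x$labels[1], x$labels[2],
              mean(abs(x$snps$freq1 - x$snps$freq2))))
  invisible(x)
}

#' Sample diploid Hardy-Weinberg genotypes from a two-population truth
#'
#' Each individual's dosage at a SNP is drawn `Binomial(2, p)` with `p` the
#' frequency of `allele_a` in its population.
#'
#' @param truth A `two_pop_truth` from [simulate_divergent_populations()].
#' @param n_per_pop Individuals per population (>= 1).
#' @param seed Integer seed.
#' @return A [genotype_set()] with `pop` labels (`truth$labels`).
#' @export
sample_genotypes <- function(truth, n_per_pop, seed = 1) {
  stopifnot(inherits(truth, "two_pop_truth"), n_per_pop >= 1)
  L <- nrow(truth$snps)
  withr::with_seed(seed, {
    g1 <- matrix(stats::rbinom(n_per_pop * L, 2, rep(truth$snps$freq1, each = n_per_pop)),
                 nrow = n_per_pop)
    g2 <- matrix(stats::rbinom(n_per_pop * L, 2, rep(truth$snps$freq2, each = n_per_pop)),
                 nrow = n_per_pop)
  })
  geno <- rbind(g1, g2)
  rownames(geno) <- c(sprintf("%s_%03d", truth$labels[1], seq_len(n_per_pop)),
                      sprintf("%s_%03d", truth$labels[2], seq_len(n_per_pop)))
  genotype_set(geno, truth$snps[, c("chrom", "pos", "allele_a", "allele_b")],
               pop = rep(truth$labels, each = n_per_pop))
}
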