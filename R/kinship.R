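#' Robust pairwise kinship coefficient
#'
#' The within-population robust estimator over jointly called biallelic
#' SNPs:
#' `phi = (N_het,het - 2 N_opp_hom) / (N_het(i) + N_het(j))`,
#' where `N_het,het` counts sites heterozygous in both individuals,
#' `N_opp_hom` sites homozygous for opposite alleles, and `N_het(.)` the
#' per-individual heterozygous sites.  Expected values: 0.5 for self or
#' monozygotic pairs, 0.25 for parent-offspring or full sibs, ~0 for
#' unrelated members of one random-mating population.
#'
#' @param genos A [genotype_set()] or plain dosage matrix (individuals x
#'   SNPs, values 0/1/2, `NA` for missing).
#' @param i,j Row indices or names of the two individuals.
#' @return The kinship estimate, or `NA` when the denominator is zero
#'   (no heterozygous site in either individual).
#' @examples
#' g <- rbind(a = c(1, 1, 0, 2), b = c(1, 0, 0, 2))
#' kinship(g, "a", "b")
#' kinship(g, "a", "a")   # 0.5
#' @export
kinship <- function(genos, i, j) {
  g <- if (inherits(genos, "genotype_set")) genos$geno else as.matrix(genos)
  di <- g[i, ]; dj <- g[j, ]
  called <- !is.na(di) & !is.na(dj)
  if (!any(called)) stop_input("no jointly called SNP for this pair")
  di <- di[called]; dj <- dj[called]
  het_i <- di == 1; het_j <- dj == 1
  n_hh <- sum(het_i & het_j)
  n_opp <- sum((di == 0 & dj == 2) | (di == 2 & dj == 0))
  den <- sum(het_i) + sum(het_j)
  if (den == 0) return(NA_real_)
  (n_hh - 2 * n_opp) / den
}

#' Pairwise kinship matrix
#'
#' @param genos A [genotype_set()] or dosage matrix.
#' @return Symmetric matrix of [kinship()] estimates (diagonal 0.5 by the
#'   estimator's self-kinship identity).
#' @export
kinship_matrix <- function(genos) {
  g <- if (inherits(genos, "genotype_set")) genos$geno else as.matrix(genos)
  n <- nrow(g)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[i, j] <- out[j, i] <- kinship(g, i, j)
    }
  }
  out
}
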