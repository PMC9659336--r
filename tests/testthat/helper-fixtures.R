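# shared fixtures and independent oracles, built in code at test time

# hand-written panel from explicit frequency rows
make_panel <- function(p1, p2, groups = c("g1", "g2"), contrast = "test",
                       chrom = "1") {
  n <- length(p1)
  import_panel(data.frame(chrom = rep(chrom, n),
                          pos = seq(100, by = 100, length.out = n),
                          allele_a = rep("A", n), allele_b = rep("G", n),
                          p_group1 = p1, p_group2 = p2),
               groups = groups, contrast = contrast)
}

# observations hitting given panel rows with given alleles
make_obs <- function(panel, rows, alleles, total = 1e5, specimen = "s") {
  read_observations(specimen,
                    data.frame(chrom = panel$snps$chrom[rows],
                               pos = panel$snps$pos[rows],
                               allele = alleles),
                    total)
}

# independent brute-force posterior: per-observation clamped frequency
# products normalised over the two groups (different arithmetic path from
# score_assignment's summed log ratios)
brute_force_score <- function(obs, panel, clamp = 0.001) {
  p1 <- 1; p2 <- 1
  n_used <- 0
  for (k in seq_len(nrow(obs$records))) {
    r <- obs$records[k, ]
    i <- which(panel$snps$chrom == r$chrom & panel$snps$pos == r$pos)
    if (!length(i)) next
    f1 <- f2 <- NULL
    if (r$allele == panel$snps$allele_a[i]) {
      f1 <- panel$snps$p_group1[i]; f2 <- panel$snps$p_group2[i]
    } else if (r$allele == panel$snps$allele_b[i]) {
      f1 <- 1 - panel$snps$p_group1[i]; f2 <- 1 - panel$snps$p_group2[i]
    } else {
      next
    }
    p1 <- p1 * min(max(f1, clamp), 1 - clamp)
    p2 <- p2 * min(max(f2, clamp), 1 - clamp)
    n_used <- n_used + 1
  }
  if (n_used == 0) return(NA_real_)
  p1 / (p1 + p2)
}

# observations drawn directly from an individual's genotypes at panel sites
# (bypasses genome thinning; used where tests need dense evidence)
obs_from_genotype <- function(gs, ind, n_records, total = 1e5, seed = 1) {
  withr::with_seed(seed, {
    s <- sample.int(n_loci(gs), n_records, replace = TRUE)
    d <- gs$geno[ind, s]
    base <- ifelse(stats::runif(n_records) < d / 2,
                   gs$loci$allele_a[s], gs$loci$allele_b[s])
  })
  read_observations(paste0("ind", ind),
                    data.frame(chrom = gs$loci$chrom[s], pos = gs$loci$pos[s],
                               allele = base),
                    total)
}

# three divergent-contrast truths + selected panels at paper-like sizes
make_three_contrasts <- function(seed, n_ref = 100) {
  spec <- list(season = list(n = 835, dp = c(0.7, 1),
                             labels = c("autumn", "spring"), chrom = "chr4"),
               inversion = list(n = 4503, dp = c(0.7, 1),
                                labels = c("baltic", "atlantic"), chrom = "chr12"),
               salinity = list(n = 2303, dp = c(0.5, 0.9),
                               labels = c("high", "low"), chrom = "chr6"))
  truths <- panels <- list()
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    truths[[names(spec)[k]]] <- simulate_divergent_populations(
      s$n, s$dp, seed = derive_seed(seed, 1, k), labels = s$labels,
      chrom = s$chrom, chrom_length_bp = 50e6)
    ref <- sample_genotypes(truths[[k]], n_ref, seed = derive_seed(seed, 2, k))
    panels[[names(spec)[k]]] <- select_divergent_snps(
      ref, contrast = names(spec)[k], group_names = s$labels)
  }
  list(truths = truths, panels = panels)
}
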