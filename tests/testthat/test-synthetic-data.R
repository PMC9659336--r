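test_that("divergent-population frequencies follow the requested differential", {
  # maximal divergence: the pair is (1,0) or (0,1) at every SNP
  tr <- simulate_divergent_populations(20, delta_p = 1, seed = 1)
  expect_true(all(abs(tr$snps$freq1 - tr$snps$freq2) == 1))
  expect_true(all(tr$snps$freq1 %in% c(0, 1)))

  # no divergence: frequencies agree elementwise
  tr0 <- simulate_divergent_populations(1000, delta_p = 0, seed = 3)
  expect_identical(tr0$snps$freq1, tr0$snps$freq2)

  # Monte-Carlo: mean |dp| of Uniform(0.5, 1) within 3 SE of 0.75
  tru <- simulate_divergent_populations(500, c(0.5, 1), seed = 7)
  dp <- abs(tru$snps$freq1 - tru$snps$freq2)
  se <- sqrt(1 / 48) / sqrt(500)  # sd of U(0.5,1) is sqrt(1/48)
  expect_lt(abs(mean(dp) - 0.75), 3 * se)
  expect_true(all(dp >= 0.5 & dp <= 1))

  # determinism and validation
  expect_identical(tru, simulate_divergent_populations(500, c(0.5, 1), seed = 7))
  expect_error(simulate_divergent_populations(10, c(0.9, 0.2)), "delta_p")
  expect_error(simulate_divergent_populations(10, 1.7), "delta_p")
})

test_that("sampled genotypes follow Hardy-Weinberg proportions", {
  tr <- simulate_divergent_populations(3, delta_p = 0, seed = 2)
  tr$snps$freq1 <- tr$snps$freq2 <- c(1, 0.5, 0.3)
  gs <- sample_genotypes(tr, 5000, seed = 9)

  # fixed allele: everyone homozygous
  expect_true(all(gs$geno[, 1] == 2))

  # heterozygote fraction at p = 0.5 within 3 binomial SEs of 0.5
  het <- mean(gs$geno[, 2] == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))

  # chi-square goodness of fit to p^2, 2pq, q^2 not rejected at alpha = 0.001
  counts <- table(factor(gs$geno[, 3], levels = 0:2))
  p <- 0.3
  gof <- chisq.test(counts, p = c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_gt(gof$p.value, 0.001)

  # determinism
  expect_identical(gs$geno, sample_genotypes(tr, 5000, seed = 9)$geno)
})

test_that("read simulation respects genotypes and the footprint model", {
  tr <- simulate_divergent_populations(1000, delta_p = 1, seed = 4)
  gs <- sample_genotypes(tr, 2, seed = 5)

  # zero reads give an empty record set
  obs0 <- simulate_reads(gs, tr$snps, 0, seed = 1)[[1]]
  expect_identical(nrow(obs0$records), 0L)
  expect_identical(obs0$total_read_count, 0)

  # error-free, damage-free reads from a homozygous individual match the
  # genotype allele at every observed site
  obs <- simulate_reads(gs, tr$snps, 5e5, error_rate = 0, damage_rate = 0,
                        seed = 2)[[1]]
  expect_gt(nrow(obs$records), 0)
  idx <- match(paste(obs$records$chrom, obs$records$pos),
               paste(gs$loci$chrom, gs$loci$pos))
  expected <- ifelse(gs$geno[1, idx] == 2, gs$loci$allele_a[idx],
                     ifelse(gs$geno[1, idx] == 0, gs$loci$allele_b[idx], NA))
  hom <- !is.na(expected)
  expect_identical(obs$records$allele[hom], expected[hom])

  # panel-hit counts are binomial: mean over 200 seeds within 3 SE of
  # total * footprint / genome
  one <- subset_one <- genotype_set(gs$geno[1, , drop = FALSE], gs$loci)
  hits <- vapply(1:200, function(s)
    nrow(simulate_reads(one, tr$snps, 50000, seed = s)[[1]]$records), numeric(1))
  expected_hits <- 50000 * nrow(tr$snps) * 60 / 726e6
  se <- sqrt(expected_hits) / sqrt(200)  # Poisson-scale binomial sd
  expect_lt(abs(mean(hits) - expected_hits), 3 * se)

  # a genome smaller than the panel footprint is a configuration error
  expect_error(simulate_reads(gs, tr$snps, 10, genome_size_bp = 1000), "footprint")
})

test_that("downsampling is binomial thinning of the record set", {
  tr <- simulate_divergent_populations(400, delta_p = 1, seed = 6)
  gs <- sample_genotypes(tr, 1, seed = 6)
  obs <- simulate_reads(gs, tr$snps, 2e6, genome_size_bp = 50e6, seed = 3)[[1]]
  n0 <- nrow(obs$records)
  expect_gt(n0, 100)

  # identity above the original total; empty at zero
  expect_identical(downsample_reads(obs, 3e6, seed = 1), obs)
  expect_identical(nrow(downsample_reads(obs, 0, seed = 1)$records), 0L)

  # halving retains half the records on average (3 SE over 500 seeds)
  kept <- vapply(1:500, function(s)
    nrow(downsample_reads(obs, 1e6, seed = s)$records), numeric(1))
  expect_lt(abs(mean(kept) - n0 / 2), 3 * sqrt(n0 * 0.25) / sqrt(500))
  expect_true(all(vapply(1:20, function(s) {
    ds <- downsample_reads(obs, 1e6, seed = s)
    all(paste(ds$records$chrom, ds$records$pos, ds$records$allele) %in%
          paste(obs$records$chrom, obs$records$pos, obs$records$allele))
  }, logical(1))))

  # two-stage thinning matches single-stage thinning in first moments
  two <- vapply(1:500, function(s) {
    a <- downsample_reads(obs, 1e6, seed = s)
    nrow(downsample_reads(a, 4e5, seed = s + 1000)$records)
  }, numeric(1))
  one <- vapply(1:500, function(s)
    nrow(downsample_reads(obs, 4e5, seed = s + 2000)$records), numeric(1))
  pooled_se <- sqrt(var(two) / 500 + var(one) / 500)
  expect_lt(abs(mean(two) - mean(one)), 3 * pooled_se)
})

test_that("Wright-Fisher LD matches Sved's expectation at constant Ne", {
  # 30 replicates, Ne = 100, 200 generations, 12 loci within ~1 cM; haplotype
  # r2 per segregating pair compared with 1/(1+4Nc) + 1/n
  res <- vapply(1:30, function(r) {
    m <- population_model(data.frame(generation = 0, ne = 100),
                          chromosome_length_bp = 4e5, n_loci = 12, seed = r)
    wf <- simulate_wright_fisher(m, sample_size = 50, generations = 200)
    haps <- wf$haplotypes
    keep <- apply(haps, 2, sd) > 0
    if (sum(keep) < 2) return(NA_real_)
    r2 <- suppressWarnings(cor(haps[, keep]))^2
    cc <- haldane_c(abs(outer(wf$loci$cM[keep], wf$loci$cM[keep], "-")))
    ut <- upper.tri(r2)
    sved <- 1 / (1 + 4 * 100 * cc[ut]) + 1 / nrow(haps)
    mean(r2[ut] - sved, na.rm = TRUE)
  }, numeric(1))
  res <- res[!is.na(res)]
  expect_lt(abs(mean(res)), 3 * sd(res) / sqrt(length(res)))
})

test_that("complete association persists without recombination", {
  # two loci in perfect coupling, (near-)zero recombination: r2 stays 1
  m <- population_model(data.frame(generation = 0, ne = 30),
                        chromosome_length_bp = 1e6,
                        recombination_rate_cM_per_Mb = 1e-9,
                        n_loci = 2, seed = 8)
  init <- matrix(rep(rbinom(60, 1, 0.5), 2), ncol = 2)
  wf <- simulate_wright_fisher(m, sample_size = 30, generations = 50,
                               init_haplotypes = init)
  if (sd(wf$haplotypes[, 1]) > 0) {
    expect_equal(unname(cor(wf$haplotypes)[1, 2]^2), 1, tolerance = 1e-12)
  }
  expect_true(all(wf$haplotypes[, 1] == wf$haplotypes[, 2]))
})

test_that("Wright-Fisher model validates its configuration", {
  tr <- data.frame(generation = c(0, 50), ne = c(100, 1000))
  m <- population_model(tr, chromosome_length_bp = 1e6, n_loci = 10)
  # requested span shorter than the trajectory is a configuration error
  expect_error(simulate_wright_fisher(m, 10, generations = 20), "shorter")
  # sample larger than the smallest Ne is rejected
  expect_error(simulate_wright_fisher(m, 500, generations = 60), "sample_size")
  expect_error(population_model(data.frame(generation = c(5, 2), ne = c(10, 10)),
                                1e6), "increasing")
  expect_error(population_model(data.frame(generation = 0, ne = 1), 1e6), "Ne")
})
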