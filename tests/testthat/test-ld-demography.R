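test_that("pairwise r2 handles the exact-LD corner cases", {
  # duplicated locus (c = 0): r2 = 1
  g <- matrix(rbinom(60, 2, 0.5), 30, 2)
  g[, 2] <- g[, 1]
  gs <- genotype_set(g, data.frame(chrom = "1", pos = c(1000, 1000)))
  pr <- pairwise_r2(gs)
  expect_equal(pr$c, 0)
  expect_equal(pr$r2, 1)

  # perfect repulsion at equal frequencies: r2 = 1
  x <- rbinom(40, 2, 0.5)
  rep_gs <- genotype_set(cbind(x, 2 - x),
                         data.frame(chrom = "1", pos = c(1, 5e5)))
  expect_equal(pairwise_r2(rep_gs)$r2, 1)

  # all loci monomorphic is an input error
  mono <- genotype_set(matrix(2, 10, 2), data.frame(chrom = "1", pos = c(1, 2)))
  expect_error(pairwise_r2(mono), "polymorphic")
})

test_that("independent loci show only sampling-level r2", {
  # cross-chromosome pairs (c = 0.5) between independently drawn loci:
  # squared sample correlation over n individuals has expectation 1/(n-1)
  set.seed(71)
  n <- 500
  gs <- add_genetic_map(genotype_set(
    matrix(rbinom(n * 20, 2, 0.4), n, 20),
    data.frame(chrom = rep(c("c1", "c2"), each = 10),
               pos = rep(seq(1e5, 1e6, length.out = 10), 2))))
  pr <- pairwise_r2(gs, c_max = 0.5)
  cross <- pr$r2[pr$c == 0.5]
  expect_identical(length(cross), 100L)
  se <- sd(cross) / sqrt(length(cross))
  expect_lt(abs(mean(cross) - 1 / (n - 1)), 3 * se)
})

test_that("the binned estimator inverts the Sved relation analytically", {
  # r2 placed exactly at 1/(1+4Nc) + 1/n recovers N to 1e-9 relative error
  n_hap <- 200; N <- 350
  mids <- exp((log(head(default_c_bins(), -1)) +
                 log(tail(default_c_bins(), -1))) / 2)
  pairs <- data.frame(c = rep(mids, each = 40),
                      r2 = rep(1 / (1 + 4 * N * mids) + 1 / n_hap, each = 40))
  traj <- ne_from_ld(pairs, n_hap)
  expect_identical(nrow(traj), length(mids))
  expect_true(all(abs(traj$ne - N) / N < 1e-9))
  expect_equal(traj$t_gen, 1 / (2 * rev(mids)))
  # t strictly increases as c decreases
  expect_true(all(diff(traj$t_gen) > 0) && all(diff(traj$c) < 0))

  # closed-form spot value: r2 = 0.2 at c = 0.01 and huge n gives Ne = 100
  one <- data.frame(c = rep(0.01, 50), r2 = 0.2)
  est <- suppressWarnings(ne_from_ld(one, 1e9, min_pairs_per_bin = 30))
  expect_equal(est$ne, 100, tolerance = 1e-6)
  expect_equal(est$t_gen, 50)
})

test_that("degenerate bins are dropped with warnings", {
  pairs <- data.frame(c = c(rep(0.01, 40), rep(0.1, 5)),
                      r2 = c(rep(0.2, 40), rep(0.3, 5)))
  expect_warning(ne_from_ld(pairs, 100), "fewer than")
  floor_pairs <- data.frame(c = rep(0.01, 40), r2 = 0.004)
  expect_warning(expect_error(ne_from_ld(floor_pairs, 100), "dropped"),
                 "floor")
})

test_that("constant-Ne truth is recovered and declines are detected", {
  # single-replicate constant Ne = 200 recovery (the 20-replicate version
  # backs the acceptance suite); factor-2 check on mid-range bins
  m <- population_model(data.frame(generation = 0, ne = 200),
                        chromosome_length_bp = 4e7, n_loci = 400, seed = 72)
  wf <- simulate_wright_fisher(m, sample_size = 100, generations = 250)
  traj <- suppressWarnings(ne_from_ld(pairwise_r2(wf), n_haplotypes = 200))
  mid <- median(traj$ne[traj$t_gen >= 10 & traj$t_gen <= 100])
  expect_gt(mid, 100)
  expect_lt(mid, 400)

  # bottleneck truth 1000 -> 100 at generation 50: recent Ne below ancient
  mb <- population_model(data.frame(generation = c(0, 50), ne = c(100, 1000)),
                         chromosome_length_bp = 4e7, n_loci = 250, seed = 73)
  wfb <- simulate_wright_fisher(mb, sample_size = 60, generations = 150)
  tb <- suppressWarnings(ne_from_ld(pairwise_r2(wfb), n_haplotypes = 120))
  expect_lt(median(tb$ne[tb$t_gen <= 25]), median(tb$ne[tb$t_gen >= 60]))
})

test_that("bootstrap aggregation is a geometric mean with intervals", {
  m <- population_model(data.frame(generation = 0, ne = 100),
                        chromosome_length_bp = 2e7, n_loci = 150, seed = 74)
  wf <- simulate_wright_fisher(m, sample_size = 50, generations = 150)

  # a single iteration's geometric mean is that iteration's estimate:
  # with one iteration the intervals collapse onto the point estimate
  b1 <- suppressWarnings(bootstrap_ne(wf, n_boot = 1, snps_per_chromosome = 100,
                                      seed = 5))
  expect_true(all(b1$n_iter == 1))
  expect_equal(b1$ne, b1$lo)
  expect_equal(b1$ne, b1$hi)

  # sampling every locus each iteration makes iterations identical:
  # zero-width intervals, gmean equal to the common estimate
  expect_warning(b_all <- bootstrap_ne(wf, n_boot = 3,
                                       snps_per_chromosome = 1000, seed = 6),
                 "capped")
  expect_equal(b_all$lo, b_all$hi)
  expect_equal(b_all$ne, b_all$lo)
  full <- suppressWarnings(ne_from_ld(pairwise_r2(wf), 100))
  common <- merge(as.data.frame(b_all), as.data.frame(full), by = "t_gen")
  expect_equal(common$ne.x, common$ne.y)

  # determinism
  b2 <- suppressWarnings(bootstrap_ne(wf, n_boot = 4, snps_per_chromosome = 100,
                                      seed = 7))
  b3 <- suppressWarnings(bootstrap_ne(wf, n_boot = 4, snps_per_chromosome = 100,
                                      seed = 7))
  expect_identical(as.data.frame(b2), as.data.frame(b3))
})

test_that("calendar calibration is a pure unit transform", {
  traj <- data.frame(c = 1 / (2 * (1:250)), t_gen = 1:250, r2 = 0.1,
                     n_pairs = 100, ne = 500 + (1:250))
  class(traj) <- c("ne_trajectory", "data.frame")

  cal3 <- calibrate_trajectory(traj, 3, sampling_year = 2005)
  expect_identical(attr(cal3, "confidence_boundary_years"), 600)
  expect_identical(min(cal3$t_gen), 5L)                      # 4 most recent trimmed
  expect_identical(nrow(cal3), nrow(traj) - 4L)
  expect_equal(cal3$years_before_sampling, cal3$t_gen * 3)
  expect_identical(cal3$ne, traj$ne[traj$t_gen > 4])         # Ne untouched
  expect_identical(sum(cal3$low_confidence), sum(traj$t_gen > 200))

  cal2 <- calibrate_trajectory(traj, 2, sampling_year = 2010)
  expect_identical(attr(cal2, "confidence_boundary_years"), 400)
  at100 <- cal2[cal2$t_gen == 100, ]
  expect_equal(at100$years_before_sampling, 200)
  expect_equal(at100$calendar_year, 1810)

  # trim_recent = 0 keeps every point
  expect_identical(nrow(calibrate_trajectory(traj, 2, 2010, trim_recent = 0)),
                   nrow(traj))
  # trajectory entirely inside the trimmed window: empty with warning
  short <- traj[1:3, ]
  expect_warning(out <- calibrate_trajectory(short, 2, 2010), "trimmed")
  expect_identical(nrow(out), 0L)
})
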