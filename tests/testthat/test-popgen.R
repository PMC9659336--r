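test_that("windowed diversity equals hand values on tiny fixtures", {
  # two haplotypes differing at 1 of 100,000 sites in one window
  haps <- rbind(c(0, 0, 0), c(1, 0, 0))
  pi1 <- windowed_pi(haps, positions = c(10, 200, 99999), window_bp = 1e5)
  expect_equal(pi1$pi, 1e-5)
  expect_identical(pi1$start, 0)
  expect_identical(pi1$end, 1e5)

  # identical sequences: zero everywhere, zero-variant windows included
  same <- matrix(1, 4, 2)
  pi0 <- windowed_pi(same, positions = c(5, 250001), window_bp = 1e5)
  expect_identical(pi0$pi, c(0, 0, 0))
  expect_identical(pi0$start, c(0, 1e5, 2e5))
})

test_that("windowed diversity equals the all-pairs brute force", {
  set.seed(61)
  for (rep in 1:5) {
    H <- 10; S <- 50
    haps <- matrix(rbinom(H * S, 1, runif(1, 0.1, 0.9)), H, S)
    pos <- sort(sample.int(250000, S))
    got <- windowed_pi(haps, pos, window_bp = 1e5)
    # brute force: mean Hamming distance over all haplotype pairs per window
    win <- (pos - 1) %/% 1e5
    for (w in unique(win)) {
      idx <- which(win == w)
      tot <- 0; np <- 0
      for (i in 1:(H - 1)) for (j in (i + 1):H) {
        tot <- tot + sum(haps[i, idx] != haps[j, idx])
        np <- np + 1
      }
      expect_equal(got$pi[got$start == w * 1e5], tot / np / 1e5,
                   tolerance = 1e-12)
    }
  }
})

test_that("diversity is invariant to sample order and allele relabelling", {
  set.seed(62)
  haps <- matrix(rbinom(80, 1, 0.4), 8, 10)
  pos <- sort(sample.int(9e4, 10))
  base <- windowed_pi(haps, pos)
  expect_equal(windowed_pi(haps[sample(8), ], pos), base)
  expect_equal(windowed_pi(1 - haps, pos), base)
})

test_that("kinship matches its identities and pedigree expectations", {
  set.seed(63)
  p <- runif(10000, 0.1, 0.9)
  parent <- rbinom(10000, 2, p)
  child <- rbinom(10000, 1, parent / 2) + rbinom(10000, 1, p)
  unrel <- rbinom(10000, 2, p)
  g <- rbind(P = parent, C = child, U = unrel)

  expect_equal(kinship(g, "P", "P"), 0.5)                       # self
  expect_equal(kinship(g, "P", "C"), 0.25, tolerance = 0.03)    # parent-offspring
  expect_equal(kinship(g, "P", "U"), 0, tolerance = 0.02)       # unrelated, HWE
  expect_identical(kinship(g, "P", "C"), kinship(g, "C", "P"))  # symmetry

  km <- kinship_matrix(g[, 1:500])
  expect_equal(unname(diag(km)), rep(0.5, 3))
  expect_identical(km, t(km))

  # zero denominator: no heterozygote in either individual
  hom <- rbind(x = c(0, 2, 0), y = c(2, 0, 2))
  expect_true(is.na(kinship(hom, "x", "y")))
})

test_that("ROH detection flags homozygous tracts and only those", {
  pos <- (1:200) * 2500  # 500 kb, 200 SNPs
  loci <- data.frame(chrom = "1", pos = pos)
  # fully heterozygous individual: nothing
  het <- genotype_set(matrix(1, 1, 200), loci)
  expect_identical(nrow(detect_roh(het, min_length_bp = 1e5)), 0L)
  # fully homozygous chromosome: exactly one segment spanning first to last SNP
  hom <- genotype_set(matrix(rep(c(0, 2), 100), 1), loci)
  seg <- detect_roh(hom, min_length_bp = 1e5)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$start, 2500)
  expect_identical(seg$end, 500000)

  # unsorted positions are rejected
  bad <- loci; bad$pos[2] <- 1
  expect_error(detect_roh(genotype_set(matrix(1, 1, 200), bad)), "sorted")
})

test_that("a planted 200-kb homozygous tract is recovered", {
  hits <- 0
  for (r in 1:50) {
    set.seed(r)
    het <- runif(1000) < 0.3
    d <- ifelse(het, 1, sample(c(0, 2), 1000, replace = TRUE))
    d[401:600] <- sample(c(0, 2), 200, replace = TRUE)  # 400-600 kb tract
    gs <- genotype_set(matrix(d, 1),
                       data.frame(chrom = "1", pos = (1:1000) * 1000))
    seg <- detect_roh(gs)  # window 50 SNPs = 50 kb span here
    hit <- seg[seg$start < 600000 & seg$end > 401000, , drop = FALSE]
    if (nrow(hit) == 1 &&
        abs(hit$start - 401000) < 50000 && abs(hit$end - 600000) < 50000) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 45)
})

test_that("ROH segments are disjoint per individual and chromosome", {
  set.seed(64)
  d <- ifelse(runif(2000) < 0.15, 1, sample(c(0, 2), 2000, replace = TRUE))
  gs <- genotype_set(matrix(d, 1),
                     data.frame(chrom = rep(c("1", "2"), each = 1000),
                                pos = rep((1:1000) * 1000, 2)))
  seg <- detect_roh(gs, max_het_per_window = 3, min_length_bp = 10000)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1) {
      s <- s[order(s$start), ]
      expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("ROH dating follows the genetic-length rule and its bins", {
  # L = 1 cM at 2-year generations: g = 50, 100 years
  seg <- data.frame(individual = "i", chrom = "1", start = 1, end = 2,
                    length_bp = 2, n_snps = 2, length_cM = 1)
  dated <- date_and_bin_roh(seg, generation_time_years = 2)
  expect_equal(dated$segments$g_generations, 50)
  expect_equal(dated$segments$years_bp, 100)

  # 100 kb at 2.54 cM/Mb, 3-year generations: ~590.6 years, older bin
  seg2 <- data.frame(individual = "i", chrom = "1", start = 1, end = 1e5,
                     length_bp = 1e5, n_snps = 60)
  dated2 <- date_and_bin_roh(seg2, generation_time_years = 3)
  expect_equal(dated2$segments$length_cM, 0.254)
  expect_equal(dated2$segments$years_bp, 590.551, tolerance = 1e-3)
  expect_identical(dated2$segments$bin, "650-400 YBP")

  # longer segments date strictly younger
  lens <- data.frame(individual = "i", chrom = "1", start = 1, end = 1,
                     length_bp = c(1e5, 2e5, 3e5), n_snps = 1)
  yrs <- date_and_bin_roh(lens, 3)$segments$years_bp
  expect_true(all(diff(yrs) < 0))

  # the formula round-trips exactly
  g <- c(0.5, 7, 196.85, 1000)
  expect_equal(100 / (2 * (100 / (2 * g))), g, tolerance = 1e-12)

  # a segment dated exactly on a shared edge falls in the younger bin
  on_edge <- data.frame(individual = "i", chrom = "1", start = 1, end = 1,
                        length_bp = 1, n_snps = 1,
                        length_cM = 0.25)  # g = 200, exactly 400 years at 2 y
  expect_identical(date_and_bin_roh(on_edge, 2)$segments$bin, "400-200 YBP")

  # outside-all-bins segments are reported separately; zero length skipped
  far <- data.frame(individual = "i", chrom = "1", start = 1, end = 1,
                    length_bp = c(5e6, 0), n_snps = 1)
  expect_warning(out <- date_and_bin_roh(far, 3), "zero-length")
  expect_identical(out$segments$bin, "outside")
  expect_identical(out$summary$n[out$summary$bin == "outside"], 1L)
})
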