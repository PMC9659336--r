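#' Recombination fraction from map distance (inverse Haldane)
#'
#' `c = (1 - exp(-2 d / 100)) / 2` for a map distance `d` in cM; loci on
#' different chromosomes recombine freely at `c = 0.5`.
#'
#' @param d_cM Map distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_c(c(1, 50, 1000))
#' @export
haldane_c <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Pairwise LD (r-squared) against recombination fraction
#'
#' For every locus pair within `c_max`, squared Pearson correlation of
#' genotype dosages (the standard unphased r-squared) and the recombination
#' fraction from the inverse Haldane map of their cM distance.
#' Cross-chromosome pairs sit at `c = 0.5` and are included only when
#' `c_max` reaches 0.5.  Monomorphic loci are removed first; pairs with an
#' undefined correlation are skipped.
#'
#' @param genos A [genotype_set()]; if its loci lack a `cM` column the map
#'   is filled at `recombination_rate_cM_per_Mb`.
#' @param c_max Largest recombination fraction retained (default 0.25).
#' @param recombination_rate_cM_per_Mb Constant rate used when no map is
#'   present (default 2.54 cM/Mb).
#' @return Data frame with columns `c` and `r2`, one row per pair.
#' @export
pairwise_r2 <- function(genos, c_max = 0.25,
                        recombination_rate_cM_per_Mb = 2.54) {
  stopifnot(inherits(genos, "genotype_set"), c_max > 0, c_max <= 0.5)
  if (is.null(genos$loci$cM)) {
    genos <- add_genetic_map(genos, recombination_rate_cM_per_Mb)
  }
  sds <- apply(genos$geno, 2, stats::sd, na.rm = TRUE)
  poly <- which(!is.na(sds) & sds > 0)
  if (length(poly) < 2) stop_input("fewer than two polymorphic loci")
  genos <- subset_loci(genos, poly)
  chroms <- unique(genos$loci$chrom)
  res <- list(data.frame(c = numeric(), r2 = numeric()))
  for (ch in chroms) {
    idx <- which(genos$loci$chrom == ch)
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      stats::cor(genos$geno[, idx, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    cc <- haldane_c(abs(outer(genos$loci$cM[idx], genos$loci$cM[idx], "-")))
    sel <- upper.tri(r2) & cc <= c_max & !is.na(r2)
    res[[length(res) + 1]] <- data.frame(c = cc[sel], r2 = r2[sel])
  }
  if (c_max >= 0.5 && length(chroms) > 1) {
    for (a in seq_along(chroms)[-length(chroms)]) {
      for (b in seq((a + 1), length(chroms))) {
        ia <- which(genos$loci$chrom == chroms[a])
        ib <- which(genos$loci$chrom == chroms[b])
        r2 <- suppressWarnings(
          stats::cor(genos$geno[, ia, drop = FALSE],
                     genos$geno[, ib, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        ok <- !is.na(r2)
        res[[length(res) + 1]] <- data.frame(c = rep(0.5, sum(ok)), r2 = r2[ok])
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default recombination-fraction bin edges
#'
#' Log-spaced bin edges on the recombination fraction; 20 bins over
#' `[5e-4, 0.25]` span roughly 2 to 1,000 generations before sampling at
#' `t = 1 / (2c)`.
#'
#' @param n_bins Number of bins.
#' @param c_range Range of recombination fractions covered.
#' @return Numeric vector of `n_bins + 1` increasing edges.
#' @export
default_c_bins <- function(n_bins = 20, c_range = c(5e-4, 0.25)) {
  exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_bins + 1))
}

#' Effective population size from binned LD decay
#'
#' Classical Sved-relation estimator: within each recombination-fraction
#' bin, with mean fraction `c` and mean r-squared `r2`, expected LD is
#' `E[r2] = 1 / (1 + 4 Ne c) + 1/n` for `n` sampled haplotypes, inverted to
#' `Ne(c) = (1 / (r2 - 1/n) - 1) / (4 c)` and reported at `t = 1 / (2 c)`
#' generations before sampling.  Bins with too few pairs, or whose mean
#' r-squared does not exceed the `1/n` sampling floor, are dropped with a
#' warning.  This is a deliberately transparent binning estimator following
#' the field's aggregation and calibration conventions, not a
#' re-implementation of any specific LD-demography program.
#'
#' @param pairs Data frame from [pairwise_r2()] (`c`, `r2`).
#' @param n_haplotypes Sampled haplotypes (2 x diploids), >= 4.
#' @param c_bins Bin edges on the recombination fraction (default 20
#'   log-spaced bins over `[5e-4, 0.25]`).
#' @param min_pairs_per_bin Minimum pairs per retained bin (default 30).
#' @return An `ne_trajectory` data frame (`c`, `t_gen`, `r2`, `n_pairs`,
#'   `ne`), ordered by increasing `t_gen`.
#' @export
ne_from_ld <- function(pairs, n_haplotypes, c_bins = default_c_bins(),
                       min_pairs_per_bin = 30) {
  stopifnot(n_haplotypes >= 4, length(c_bins) >= 2, all(diff(c_bins) > 0))
  bin <- cut(pairs$c, breaks = c_bins, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  agg <- lapply(split(which(keep), bin[keep]), function(ii) {
    data.frame(c = mean(pairs$c[ii]), r2 = mean(pairs$r2[ii]),
               n_pairs = length(ii))
  })
  out <- do.call(rbind, agg)
  if (is.null(out) || nrow(out) == 0) stop_input("no pairs fall in the bins")
  small <- out$n_pairs < min_pairs_per_bin
  if (any(small)) {
    warning(sum(small), " bin(s) dropped with fewer than ",
            min_pairs_per_bin, " pairs")
    out <- out[!small, , drop = FALSE]
  }
  floor_hit <- out$r2 <= 1 / n_haplotypes
  if (any(floor_hit)) {
    warning(sum(floor_hit), " bin(s) dropped at or below the 1/n sampling floor")
    out <- out[!floor_hit, , drop = FALSE]
  }
  if (nrow(out) == 0) stop_input("all bins dropped; cannot estimate Ne")
  out$ne <- (1 / (out$r2 - 1 / n_haplotypes) - 1) / (4 * out$c)
  out$t_gen <- 1 / (2 * out$c)
  out <- out[order(out$t_gen), c("c", "t_gen", "r2", "n_pairs", "ne")]
  rownames(out) <- NULL
  attr(out, "n_haplotypes") <- n_haplotypes
  attr(out, "c_bins") <- c_bins
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Bootstrap LD-based Ne estimation over SNP subsets
#'
#' Repeats the LD binning estimator on random per-chromosome SNP subsets
#' (without replacement, iteration-derived seeds) and aggregates per bin by
#' geometric mean with 2.5/97.5 percentile intervals — the convention for
#' strictly positive, right-skewed Ne estimates.
#'
#' @param genos A [genotype_set()].
#' @param n_boot Bootstrap iterations (default 40).
#' @param snps_per_chromosome SNPs sampled per chromosome per iteration
#'   (default 2,000 for desk-scale runs; capped, with a warning, at the
#'   available count).
#' @param seed Master seed.
#' @param c_bins,min_pairs_per_bin,c_max,recombination_rate_cM_per_Mb Passed
#'   to [pairwise_r2()] / [ne_from_ld()].
#' @return An `ne_trajectory` data frame (`c`, `t_gen`, `ne` = geometric
#'   mean, `lo`, `hi`, `n_iter`), ordered by increasing `t_gen`.
#' @export
bootstrap_ne <- function(genos, n_boot = 40, snps_per_chromosome = 2000,
                         seed = 1, c_bins = default_c_bins(),
                         min_pairs_per_bin = 30, c_max = 0.25,
                         recombination_rate_cM_per_Mb = 2.54) {
  stopifnot(inherits(genos, "genotype_set"), n_boot >= 1,
            snps_per_chromosome >= 2)
  chroms <- split(seq_len(n_loci(genos)), genos$loci$chrom)
  avail <- vapply(chroms, length, integer(1))
  if (any(avail < snps_per_chromosome)) {
    warning("snps_per_chromosome capped at available count on ",
            sum(avail < snps_per_chromosome), " chromosome(s)")
  }
  n_hap <- 2 * n_individuals(genos)
  bins <- vector("list", length(c_bins) - 1)
  for (it in seq_len(n_boot)) {
    idx <- unlist(lapply(seq_along(chroms), function(ci) {
      ii <- chroms[[ci]]
      withr::with_seed(derive_seed(seed, it, ci),
                       sample(ii, min(snps_per_chromosome, length(ii))))
    }), use.names = FALSE)
    est <- tryCatch(
      suppressWarnings(ne_from_ld(
        pairwise_r2(subset_loci(genos, sort(idx)), c_max,
                    recombination_rate_cM_per_Mb),
        n_hap, c_bins, min_pairs_per_bin)),
      error = function(e) NULL)
    if (is.null(est)) next
    b <- findInterval(est$c, c_bins, rightmost.closed = TRUE)
    for (k in seq_len(nrow(est))) {
      bins[[b[k]]] <- rbind(bins[[b[k]]], est[k, c("c", "ne")])
    }
  }
  filled <- which(vapply(bins, function(x) !is.null(x) && nrow(x) > 0, logical(1)))
  if (!length(filled)) stop_input("no bin retained an estimate in any iteration")
  out <- do.call(rbind, lapply(filled, function(k) {
    v <- bins[[k]]
    data.frame(c = mean(v$c), t_gen = 1 / (2 * mean(v$c)),
               ne = exp(mean(log(v$ne))),
               lo = unname(stats::quantile(v$ne, 0.025)),
               hi = unname(stats::quantile(v$ne, 0.975)),
               n_iter = nrow(v))
  }))
  out <- out[order(out$t_gen), ]
  rownames(out) <- NULL
  attr(out, "n_haplotypes") <- n_hap
  attr(out, "n_boot") <- n_boot
  attr(out, "snps_per_chromosome") <- snps_per_chromosome
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Calibrate an Ne trajectory to calendar years
#'
#' Pure unit transform: Ne values are untouched.  Points in the most recent
#' `trim_recent` generations are removed (LD estimators show artifactual
#' near-zero bottlenecks there at small sample sizes); remaining points get
#' `years_before_sampling = t_gen * generation_time_years` and a calendar
#' year offset from the sampling year.  Points beyond `max_generations`
#' (the estimator's accuracy window) are flagged low-confidence but kept.
#'
#' @param traj An `ne_trajectory` from [ne_from_ld()] or [bootstrap_ne()].
#' @param generation_time_years Generation time (> 0); use the stock's
#'   minimum (e.g. 3 y for autumn-spawning herring, 2 y for spring).
#' @param sampling_year Calendar year of sampling.
#' @param trim_recent Most recent generations removed (default 4).
#' @param max_generations Accuracy window in generations (default 200).
#' @return The trajectory with `years_before_sampling`, `calendar_year` and
#'   `low_confidence` columns, metadata (including the confidence boundary
#'   `max_generations * generation_time_years`) in attributes; empty, with
#'   a warning, if every point is trimmed.
#' @export
calibrate_trajectory <- function(traj, generation_time_years, sampling_year,
                                 trim_recent = 4, max_generations = 200) {
  stopifnot(inherits(traj, "data.frame"), generation_time_years > 0,
            is.numeric(sampling_year), trim_recent >= 0, max_generations > 0)
  out <- traj[order(traj$t_gen), , drop = FALSE]
  out <- out[out$t_gen > trim_recent, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("all points fall within the trimmed recent generations")
  }
  out$years_before_sampling <- out$t_gen * generation_time_years
  out$calendar_year <- sampling_year - out$years_before_sampling
  out$low_confidence <- out$t_gen > max_generations
  rownames(out) <- NULL
  attr(out, "generation_time_years") <- generation_time_years
  attr(out, "sampling_year") <- sampling_year
  attr(out, "trim_recent") <- trim_recent
  attr(out, "max_generations") <- max_generations
  attr(out, "confidence_boundary_years") <- max_generations * generation_time_years
  class(out) <- c("ne_trajectory_calibrated", "data.frame")
  out
}

#' Plot an Ne trajectory
#'
#' @param x An `ne_trajectory` or calibrated trajectory.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ne_trajectory <- function(x, ...) {
  xs <- if (!is.null(x$years_before_sampling)) x$years_before_sampling else x$t_gen
  xl <- if (!is.null(x$years_before_sampling)) "years before sampling" else
    "generations before sampling"
  graphics::plot(xs, x$ne, type = "b", log = "y", xlab = xl,
                 ylab = expression(N[e]), ...)
  if (!is.null(x$lo)) {
    graphics::arrows(xs, x$lo, xs, x$hi, angle = 90, code = 3,
                     length = 0.03, col = "grey50")
  }
  invisible(x)
}

#' @export
plot.ne_trajectory_calibrated <- plot.ne_trajectory
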