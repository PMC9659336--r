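#' Detect runs of homozygosity
#'
#' SNP-count sliding windows (`window_snps` consecutive SNPs) are flagged
#' when they contain at most `max_het_per_window` heterozygous calls;
#' overlapping flagged windows are merged and merged runs shorter than
#' `min_length_bp` (first to last SNP, inclusive) are discarded.  Segments
#' never span chromosomes.  The defaults (50 SNPs, 1 heterozygote, 50 kb)
#' are this package's own, sized so that tracts in the few-hundred-kb range
#' — the coalescent depths of interest at herring-like recombination rates
#' — are detectable; chromosomes with fewer SNPs than one window yield no
#' segments.  Missing genotypes are treated as non-heterozygous.
#'
#' @param genos A [genotype_set()] with positions sorted within chromosomes.
#' @param window_snps Window size in SNPs.
#' @param max_het_per_window Heterozygote tolerance per window.
#' @param min_length_bp Minimum merged segment length in bp.
#' @return Data frame `individual`, `chrom`, `start`, `end` (1-based,
#'   inclusive), `length_bp`, `n_snps`; zero rows when nothing is found.
#' @export
detect_roh <- function(genos, window_snps = 50, max_het_per_window = 1,
                       min_length_bp = 50000) {
  stopifnot(inherits(genos, "genotype_set"), window_snps >= 1,
            max_het_per_window >= 0, min_length_bp >= 1)
  loci <- genos$loci
  for (ch in unique(loci$chrom)) {
    if (is.unsorted(loci$pos[loci$chrom == ch])) {
      stop_input("positions must be sorted within chromosomes")
    }
  }
  empty <- data.frame(individual = character(), chrom = character(),
                      start = integer(), end = integer(),
                      length_bp = integer(), n_snps = integer(),
                      stringsAsFactors = FALSE)
  out <- list(empty)
  ids <- rownames(genos$geno)
  w <- window_snps
  for (i in seq_len(n_individuals(genos))) {
    het <- genos$geno[i, ] == 1
    het[is.na(het)] <- FALSE
    for (ch in unique(loci$chrom)) {
      idx <- which(loci$chrom == ch)
      n <- length(idx)
      if (n < w) next
      hc <- cumsum(c(0, het[idx]))
      win_het <- hc[(w + 1):(n + 1)] - hc[1:(n - w + 1)]
      starts <- which(win_het <= max_het_per_window)
      if (!length(starts)) next
      grp <- cumsum(c(TRUE, diff(starts) > w - 1))
      for (g in split(starts, grp)) {
        first <- g[1]
        last <- g[length(g)] + w - 1
        seg_start <- loci$pos[idx[first]]
        seg_end <- loci$pos[idx[last]]
        len <- seg_end - seg_start + 1
        if (len >= min_length_bp) {
          out[[length(out) + 1]] <- data.frame(
            individual = ids[i], chrom = ch,
            start = seg_start, end = seg_end,
            length_bp = len, n_snps = last - first + 1,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Date runs of homozygosity and bin them by coalescent age
#'
#' A homozygous tract of genetic length `L` cM points to a coalescent event
#' about `g = 100 / (2 L)` generations ago (`L = 100 / (2 g)` cM); calendar
#' age is `g` times the generation time.  Segments are assigned to
#' descending-age bins, half-open on the younger edge: a segment dated
#' exactly on a shared edge falls in the younger bin.  Segments older than
#' the oldest bin or younger than the youngest are reported as `"outside"`.
#'
#' @param segments Data frame from [detect_roh()] (needs `length_bp`; an
#'   optional `length_cM` column overrides the constant-rate conversion).
#' @param generation_time_years Generation time in years (> 0).
#' @param recombination_rate_cM_per_Mb Constant physical-to-genetic rate
#'   (default 2.54 cM/Mb).
#' @param bins Data frame with `older_ybp` and `younger_ybp` per bin
#'   (default the 650-400 and 400-200 years-before-present pair).
#' @return List with `segments` (dated, with `length_cM`, `g_generations`,
#'   `years_bp`, `bin`) and `summary` (per bin plus `"outside"`: `n`,
#'   `sum_length_bp`, `sum_length_cM`).  Zero-length segments are skipped
#'   with a warning.
#' @examples
#' seg <- data.frame(individual = "i", chrom = "1", start = 1,
#'                   end = 100000, length_bp = 100000, n_snps = 60)
#' date_and_bin_roh(seg, generation_time_years = 3)$segments
#' @export
date_and_bin_roh <- function(segments, generation_time_years,
                             recombination_rate_cM_per_Mb = 2.54,
                             bins = data.frame(older_ybp = c(650, 400),
                                               younger_ybp = c(400, 200))) {
  stopifnot(generation_time_years > 0, recombination_rate_cM_per_Mb > 0,
            all(c("older_ybp", "younger_ybp") %in% names(bins)),
            all(bins$older_ybp > bins$younger_ybp))
  segments <- as.data.frame(segments)
  if (is.null(segments$length_cM)) {
    segments$length_cM <- segments$length_bp * recombination_rate_cM_per_Mb / 1e6
  }
  bad <- segments$length_cM <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-length segment(s) skipped")
    segments <- segments[!bad, , drop = FALSE]
  }
  segments$g_generations <- 100 / (2 * segments$length_cM)
  segments$years_bp <- segments$g_generations * generation_time_years
  bin_labels <- sprintf("%g-%g YBP", bins$older_ybp, bins$younger_ybp)
  assign_bin <- function(y) {
    hit <- which(y <= bins$older_ybp & y > bins$younger_ybp)
    if (length(hit)) bin_labels[hit[1]] else "outside"
  }
  segments$bin <- vapply(segments$years_bp, assign_bin, character(1))
  lev <- c(bin_labels, "outside")
  summ <- do.call(rbind, lapply(lev, function(b) {
    s <- segments[segments$bin == b, , drop = FALSE]
    data.frame(bin = b, n = nrow(s),
               sum_length_bp = sum(s$length_bp),
               sum_length_cM = sum(s$length_cM),
               stringsAsFactors = FALSE)
  }))
  rownames(segments) <- rownames(summ) <- NULL
  list(segments = segments, summary = summ,
       generation_time_years = generation_time_years,
       recombination_rate_cM_per_Mb = recombination_rate_cM_per_Mb)
}
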