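#' Windowed nucleotide diversity
#'
#' Average pairwise difference per site (pi) in fixed physical windows.
#' All sampled alleles are treated as exchangeable haplotypes: a site with
#' `k` copies of allele a among `H` called haplotypes contributes
#' `k (H - k) / choose(H, 2)` pairwise differences; monomorphic sites (and
#' the window positions without a variant) contribute zero.  Windows tile
#' the chromosome half-open, `[start, start + window_bp)` in 0-based
#' coordinates, so a 1-based position `p` falls in window
#' `floor((p - 1) / window_bp)`.
#'
#' @param x A [genotype_set()] (diploid dosages), or a matrix of per-sample
#'   allele counts with `ploidy` copies per row (use a 0/1 haplotype matrix
#'   with `ploidy = 1`).
#' @param positions 1-based site positions (taken from the locus table when
#'   `x` is a genotype set).
#' @param window_bp Window size in bp (default 100,000).
#' @param chrom Chromosome per site (default single chromosome `"1"`).
#' @param ploidy Allele copies per row of a plain matrix (default 1).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `pi`,
#'   covering every window from 0 to the last variant.
#' @examples
#' haps <- rbind(rep(0, 3), c(1, 0, 0))
#' windowed_pi(haps, positions = c(10, 500, 900), window_bp = 1000)
#' @export
windowed_pi <- function(x, positions = NULL, window_bp = 1e5,
                        chrom = NULL, ploidy = 1) {
  if (inherits(x, "genotype_set")) {
    positions <- x$loci$pos
    chrom <- x$loci$chrom
    ploidy <- 2
    x <- x$geno
  }
  x <- as.matrix(x)
  stopifnot(window_bp >= 1, nrow(x) * ploidy >= 2,
            length(positions) == ncol(x))
  if (is.null(chrom)) chrom <- rep("1", ncol(x))
  k <- colSums(x, na.rm = TRUE)
  H <- ploidy * colSums(!is.na(x))
  pairs <- H * (H - 1) / 2
  contrib <- ifelse(pairs > 0, k * (H - k) / pairs, 0)
  out <- lapply(split(seq_along(positions), chrom), function(idx) {
    win <- (positions[idx] - 1) %/% window_bp
    sums <- tapply(contrib[idx], win, sum)
    all_win <- 0:max(win)
    pi <- numeric(length(all_win))
    pi[match(as.integer(names(sums)), all_win)] <- sums
    data.frame(chrom = chrom[idx][1],
               start = all_win * window_bp,
               end = (all_win + 1) * window_bp,
               pi = pi / window_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
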