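#' Diploid genotype container
#'
#' Bundles a dosage matrix with its locus table.  Dosages count copies of
#' `allele_a` (0, 1 or 2; `NA` for missing calls), one row per individual and
#' one column per locus.  The locus table must carry `chrom` and `pos`
#' (1-based); optional columns are `allele_a`/`allele_b` (bases) and `cM`
#' (genetic-map position).
#'
#' @param geno Numeric matrix of allele-a dosages, individuals x loci.
#' @param loci Data frame describing the loci (one row per column of `geno`).
#' @param pop Optional population label per individual (character or factor).
#' @param haplotypes Optional 0/1 haplotype matrix (2 x individuals rows,
#'   allele_a coded 1), as produced by [simulate_wright_fisher()].
#' @return An object of class `genotype_set` with elements `geno`, `loci`,
#'   `pop` and `haplotypes`.
#' @examples
#' gs <- genotype_set(matrix(c(0, 1, 2, 2), 2, 2),
#'                    data.frame(chrom = "1", pos = c(100, 200)))
#' n_individuals(gs)
#' @export
genotype_set <- function(geno, loci, pop = NULL, haplotypes = NULL) {
  geno <- as.matrix(geno)
  if (!is.data.frame(loci) || nrow(loci) != ncol(geno)) {
    stop_input("`loci` must be a data frame with one row per genotype column")
  }
  if (!all(c("chrom", "pos") %in% names(loci))) {
    stop_input("`loci` must have columns `chrom` and `pos`")
  }
  if (any(geno < 0 | geno > 2, na.rm = TRUE)) {
    stop_input("dosages must lie in 0..2")
  }
  if (!is.null(pop)) {
    pop <- as.character(pop)
    if (length(pop) != nrow(geno)) {
      stop_input("`pop` must have one label per individual")
    }
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("ind_%03d", seq_len(nrow(geno)))
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci, pop = pop, haplotypes = haplotypes),
            class = "genotype_set")
}

#' @rdname genotype_set
#' @param x A `genotype_set`.
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname genotype_set
#' @export
n_loci <- function(x) ncol(x$geno)

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d individuals x %d loci (%d chromosome%s)%s\n",
              n_individuals(x), n_loci(x),
              length(unique(x$loci$chrom)),
              if (length(unique(x$loci$chrom)) == 1) "" else "s",
              if (is.null(x$pop)) "" else
                paste0("; populations: ",
                       paste(names(table(x$pop)), table(x$pop),
                             sep = "=", collapse = ", "))))
  invisible(x)
}

#' Subset a genotype set by locus index
#'
#' Keeps the dosage matrix, locus table and any haplotypes aligned.
#'
#' @param x A `genotype_set`.
#' @param idx Locus (column) indices to keep.
#' @return A `genotype_set` restricted to the chosen loci.
#' @export
subset_loci <- function(x, idx) {
  genotype_set(x$geno[, idx, drop = FALSE], x$loci[idx, , drop = FALSE],
               pop = x$pop,
               haplotypes = if (is.null(x$haplotypes)) NULL else
                 x$haplotypes[, idx, drop = FALSE])
}

#' Attach genetic-map positions at a constant recombination rate
#'
#' Fills the `cM` column of a genotype set's locus table from physical
#' positions, `cM = pos / 1e6 * rate`.
#'
#' @param x A `genotype_set`.
#' @param recombination_rate_cM_per_Mb Constant rate, default 2.54 cM/Mb
#'   (the herring genome-wide average).
#' @return The genotype set with a `cM` column.
#' @export
add_genetic_map <- function(x, recombination_rate_cM_per_Mb = 2.54) {
  stopifnot(inherits(x, "genotype_set"), recombination_rate_cM_per_Mb > 0)
  x$loci$cM <- x$loci$pos / 1e6 * recombination_rate_cM_per_Mb
  x
}
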