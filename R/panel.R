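#' Diagnostic SNP panel for a binary population contrast
#'
#' A panel records, for each diagnostic SNP, the two alleles and the
#' frequency of `allele_a` in each of the contrast's two groups.  Panels are
#' either *selected* from labelled reference genotypes
#' ([select_divergent_snps()]) or *imported* from published diagnostic loci
#' ([import_panel()]).
#'
#' @name snp_panel
#' @return A `snp_panel`: list with `contrast`, `groups` (length-2 character),
#'   `snps` (data frame `chrom`, `pos`, `allele_a`, `allele_b`, `p_group1`,
#'   `p_group2`) and `provenance` (`"selected"` or `"imported"`).
NULL

new_snp_panel <- function(snps, contrast, groups, provenance) {
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  key <- locus_key(snps$chrom, snps$pos)
  if (anyDuplicated(key)) {
    stop_input("duplicate (chromosome, position) in panel")
  }
  if (any(snps$p_group1 < 0 | snps$p_group1 > 1 |
          snps$p_group2 < 0 | snps$p_group2 > 1, na.rm = TRUE)) {
    stop_input("panel frequencies must lie in [0, 1]")
  }
  structure(list(contrast = contrast, groups = as.character(groups),
                 snps = snps, provenance = provenance, key = key),
            class = "snp_panel")
}

panel_key <- function(panel) panel$key %||% locus_key(panel$snps$chrom, panel$snps$pos)

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> '%s' (%s): %d SNPs; %s vs %s\n",
              x$contrast, x$provenance, nrow(x$snps), x$groups[1], x$groups[2]))
  if (nrow(x$snps)) {
    cat(sprintf("  mean |dp| = %.3f\n",
                mean(abs(x$snps$p_group1 - x$snps$p_group2))))
  }
  invisible(x)
}

#' Select divergent SNPs from labelled reference genotypes
#'
#' Retains exactly the SNPs whose per-group called-allele counts reach
#' `min_group_calls` individuals and whose absolute allele-frequency
#' differential reaches `min_abs_delta_p`.  Frequencies are computed from
#' called alleles only (missing genotypes are excluded from denominators,
#' not imputed).  The defaults (differential 0.5, two calls per group) are
#' this package's own; they yield sites informative enough for assignment
#' from a few tens of thousands of genome-wide reads.
#'
#' @param genos A [genotype_set()]; its `loci` must carry
#'   `allele_a`/`allele_b`.
#' @param groups Group label per individual (defaults to `genos$pop`); must
#'   contain exactly the two `group_names`.
#' @param min_abs_delta_p Selection threshold in `(0, 1]`.
#' @param min_group_calls Minimum called individuals per group per SNP.
#' @param contrast Name for the panel's contrast.
#' @param group_names The two labels, in (group1, group2) order; default the
#'   sorted unique labels.
#' @return A [snp_panel] with provenance `"selected"`, ordered by
#'   (chromosome, position).
#' @examples
#' tr <- simulate_divergent_populations(50, delta_p = c(0.6, 1), seed = 2)
#' gs <- sample_genotypes(tr, 30, seed = 3)
#' select_divergent_snps(gs, contrast = "demo")
#' @export
select_divergent_snps <- function(genos, groups = genos$pop,
                                  min_abs_delta_p = 0.5, min_group_calls = 2,
                                  contrast = "contrast", group_names = NULL) {
  stopifnot(inherits(genos, "genotype_set"),
            min_abs_delta_p > 0, min_abs_delta_p <= 1, min_group_calls >= 1)
  if (is.null(groups)) stop_input("no group labels supplied")
  groups <- as.character(groups)
  if (is.null(group_names)) group_names <- sort(unique(groups))
  if (length(group_names) != 2) stop_input("exactly two groups are required")
  if (!all(group_names %in% groups)) {
    stop_input("group absent from labels: ",
               paste(setdiff(group_names, groups), collapse = ", "))
  }
  if (!all(c("allele_a", "allele_b") %in% names(genos$loci))) {
    stop_input("genotype loci need allele_a/allele_b columns")
  }
  g1 <- genos$geno[groups == group_names[1], , drop = FALSE]
  g2 <- genos$geno[groups == group_names[2], , drop = FALSE]
  calls1 <- colSums(!is.na(g1)); calls2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * calls1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * calls2)
  keep <- calls1 >= min_group_calls & calls2 >= min_group_calls &
    !is.na(p1) & !is.na(p2) &
    abs(p1 - p2) >= min_abs_delta_p - 1e-9
  snps <- data.frame(chrom = genos$loci$chrom[keep], pos = genos$loci$pos[keep],
                     allele_a = genos$loci$allele_a[keep],
                     allele_b = genos$loci$allele_b[keep],
                     p_group1 = unname(p1[keep]), p_group2 = unname(p2[keep]),
                     stringsAsFactors = FALSE)
  new_snp_panel(snps, contrast, group_names, "selected")
}

#' Import a panel of published diagnostic loci
#'
#' @param records Data frame with columns `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `p_group1`, `p_group2` (frequencies of `allele_a`).
#' @param groups Length-2 character vector naming the two groups.
#' @param contrast Name for the contrast.
#' @return A [snp_panel] with provenance `"imported"`.
#' @export
import_panel <- function(records, groups, contrast = "imported") {
  stopifnot(length(groups) == 2)
  records <- as.data.frame(records)
  need <- c("chrom", "pos", "allele_a", "allele_b", "p_group1", "p_group2")
  if (!all(need %in% names(records))) {
    stop_input("panel records need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records)) {
    alleles <- c(records$allele_a, records$allele_b)
    if (any(nchar(alleles) != 1) || !all(alleles %in% IUPAC_BASES)) {
      stop_input("alleles must be single IUPAC bases")
    }
  }
  new_snp_panel(records[, need], contrast, groups, "imported")
}

#' Panel holding a simulated truth's population frequencies
#'
#' Convenience wrapper turning a [simulate_divergent_populations()] truth
#' into an imported panel whose frequencies are the true population values
#' (rather than estimates from a finite reference sample).
#'
#' @param truth A `two_pop_truth`.
#' @param contrast Name for the contrast.
#' @return A [snp_panel] with provenance `"imported"`.
#' @export
panel_from_truth <- function(truth, contrast = "truth") {
  stopifnot(inherits(truth, "two_pop_truth"))
  rec <- truth$snps
  names(rec)[names(rec) == "freq1"] <- "p_group1"
  names(rec)[names(rec) == "freq2"] <- "p_group2"
  import_panel(rec, truth$labels, contrast)
}
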