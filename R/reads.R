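#' Per-specimen allele observations at panel positions
#'
#' The native low-coverage evidence unit: one record per sequencing read
#' overlapping a diagnostic SNP, plus the genome-wide total read count the
#' record set was drawn from (the unit in which depth gates and the
#' downsampling grid are expressed).
#'
#' @param specimen Specimen id.
#' @param records Data frame with columns `chrom`, `pos` (1-based) and
#'   `allele` (observed base); may have zero rows.
#' @param total_read_count Genome-wide aligned reads behind the record set;
#'   must be at least `nrow(records)`.
#' @return An object of class `read_obs`.
#' @examples
#' read_observations("s1", data.frame(chrom = "1", pos = 100, allele = "A"), 5000)
#' @export
read_observations <- function(specimen, records, total_read_count) {
  if (is.null(records) || nrow(records) == 0) {
    records <- data.frame(chrom = character(), pos = integer(),
                          allele = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("chrom", "pos", "allele") %in% names(records))) {
    stop_input("`records` needs columns chrom, pos, allele")
  }
  if (total_read_count < nrow(records)) {
    stop_input("`total_read_count` cannot be smaller than the number of records")
  }
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(specimen = as.character(specimen),
                 records = records,
                 total_read_count = as.double(total_read_count)),
            class = "read_obs")
}

#' @export
print.read_obs <- function(x, ...) {
  cat(sprintf("<read_obs> specimen %s: %d panel-site observations from %s total reads\n",
              x$specimen, nrow(x$records),
              format(x$total_read_count, big.mark = ",")))
  invisible(x)
}

# simulate one individual's panel observations; loci/d are the matched panel
# loci and the individual's dosages there
sim_reads_one <- function(id, loci, d, total_reads, p_hit,
                          error_rate, damage_rate) {
  n_hits <- stats::rbinom(1, total_reads, p_hit)
  if (n_hits == 0 || nrow(loci) == 0) {
    return(read_observations(id, NULL, total_reads))
  }
  s <- sample.int(nrow(loci), n_hits, replace = TRUE)
  ds <- d[s]
  keep <- !is.na(ds)
  s <- s[keep]; ds <- ds[keep]
  base <- ifelse(stats::runif(length(s)) < ds / 2, loci$allele_a[s], loci$allele_b[s])
  err <- stats::runif(length(s)) < error_rate
  if (any(err)) {
    shift <- sample.int(3, sum(err), replace = TRUE)
    base[err] <- DNA_BASES[(match(base[err], DNA_BASES) - 1 + shift) %% 4 + 1]
  }
  dmg <- stats::runif(length(s)) < damage_rate
  base[dmg & base == "C"] <- "T"
  base[dmg & base == "G"] <- "A"
  read_observations(id, data.frame(chrom = loci$chrom[s], pos = loci$pos[s],
                                   allele = base, stringsAsFactors = FALSE),
                    total_reads)
}

#' Simulate low-coverage reads over a diagnostic panel
#'
#' Emulates the evidence an ultra-low-coverage (0.002-2.5x) ancient specimen
#' yields at panel SNPs.  The number of reads hitting the panel is binomial
#' with hit probability `n_sites * read_length_bp / genome_size_bp`; each hit
#' samples one of the individual's two alleles, is flipped to a uniformly
#' chosen other base with probability `error_rate`, and then subjected to
#' post-mortem C-to-T (and complementary G-to-A) substitution with
#' probability `damage_rate`.  Damage-created off-panel alleles are retained:
#' scoring ignores them but counts them as observations, as with real data.
#'
#' @param genos A [genotype_set()] whose `loci` carry `allele_a`/`allele_b`.
#' @param panel A [snp_panel] or data frame with `chrom`/`pos`; only loci of
#'   `genos` present in the panel are observable.
#' @param total_reads Genome-wide aligned reads per specimen (>= 0).
#' @param genome_size_bp Genome size (default 726 Mb, herring-scale).
#' @param error_rate,damage_rate Per-observation probabilities in `[0, 1)`.
#' @param read_length_bp Read length used only for the footprint calculation.
#' @param seed Integer seed.
#' @return A named list of `read_obs`, one per individual.
#' @export
simulate_reads <- function(genos, panel, total_reads,
                           genome_size_bp = 726e6,
                           error_rate = 0.002, damage_rate = 0.05,
                           read_length_bp = 60, seed = 1) {
  stopifnot(inherits(genos, "genotype_set"), total_reads >= 0,
            error_rate >= 0, error_rate < 1, damage_rate >= 0, damage_rate < 1)
  if (!all(c("allele_a", "allele_b") %in% names(genos$loci))) {
    stop_input("genotype loci need allele_a/allele_b for read simulation")
  }
  psnps <- if (inherits(panel, "snp_panel")) panel$snps else as.data.frame(panel)
  idx <- match(locus_key(psnps$chrom, psnps$pos),
               locus_key(genos$loci$chrom, genos$loci$pos))
  idx <- idx[!is.na(idx)]
  footprint <- length(idx) * read_length_bp
  if (footprint > genome_size_bp) {
    stop_input("genome_size_bp is smaller than the panel footprint")
  }
  p_hit <- footprint / genome_size_bp
  loci <- genos$loci[idx, , drop = FALSE]
  out <- vector("list", n_individuals(genos))
  names(out) <- rownames(genos$geno)
  for (i in seq_along(out)) {
    out[[i]] <- withr::with_seed(
      derive_seed(seed, i),
      sim_reads_one(names(out)[i], loci, genos$geno[i, idx],
                    total_reads, p_hit, error_rate, damage_rate))
  }
  out
}

#' Downsample a specimen's reads to a target genome-wide total
#'
#' Simulates drawing `target` reads from the original genome-wide total:
#' each panel-hitting record is retained independently with probability
#' `target / total_read_count` (binomial thinning).  With `target` at or
#' above the original total the observations are returned unchanged.
#'
#' @param obs A [read_observations()] object.
#' @param target Target total read count (>= 0).
#' @param seed Integer seed.
#' @return A `read_obs` whose records are a subset of the input's and whose
#'   `total_read_count` is `min(target, original)`.
#' @export
downsample_reads <- function(obs, target, seed = 1) {
  stopifnot(inherits(obs, "read_obs"), target >= 0)
  if (target >= obs$total_read_count) return(obs)
  keep <- withr::with_seed(
    seed, stats::runif(nrow(obs$records)) < target / obs$total_read_count)
  read_observations(obs$specimen, obs$records[keep, , drop = FALSE], target)
}
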