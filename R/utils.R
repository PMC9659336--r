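`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with any number of integer-valued identifiers
#' (grid value, individual index, replicate index, stage number, ...) into a
#' new seed below 2^31, so that nested stochastic stages are independent yet
#' fully reproducible from a single master seed.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param ... Further integer-valued identifiers.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, 500, 3, 12)
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  h <- 17
  for (p in parts) {
    h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# clamp allele frequencies away from 0/1 so log-ratios stay finite
clamp_freq <- function(p, clamp) {
  pmin(pmax(p, clamp), 1 - clamp)
}

# "chrom:pos" keys used to join observations, panels and loci tables
locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

DNA_BASES <- c("A", "C", "G", "T")
# single-letter IUPAC nucleotide codes accepted in imported panels
IUPAC_BASES <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# draw pairs of distinct bases for synthetic loci
random_allele_pairs <- function(n) {
  a <- sample(DNA_BASES, n, replace = TRUE)
  shift <- sample.int(3, n, replace = TRUE)
  b <- DNA_BASES[(match(a, DNA_BASES) - 1 + shift) %% 4 + 1]
  cbind(a, b)
}

stop_input <- function(...) stop(..., call. = FALSE)
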