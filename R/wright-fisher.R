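#' Demographic model for the forward Wright-Fisher simulator
#'
#' Piecewise-constant effective size through time plus the physical/genetic
#' layout of one simulated chromosome.  `ne_trajectory` gives `(generation,
#' ne)` pairs with `generation` counted backwards from sampling (0 = the
#' sampled generation); `ne[k]` applies to generations in
#' `[generation[k], generation[k+1])` and the last value extends indefinitely
#' into the past.
#'
#' @param ne_trajectory Data frame with columns `generation` (>= 0, strictly
#'   increasing, first row 0) and `ne` (> 1).
#' @param chromosome_length_bp Chromosome length in bp.
#' @param recombination_rate_cM_per_Mb Constant recombination rate
#'   (default 2.54 cM/Mb, the herring genome-wide average).
#' @param n_loci Number of segregating loci (>= 2) placed uniformly at random.
#' @param init_freq_range Initial allele-a frequencies are drawn uniformly
#'   from this range (standing variation; no new mutation is simulated).
#' @param seed Integer seed, used by [simulate_wright_fisher()] unless
#'   overridden.
#' @return A `population_model`.
#' @examples
#' m <- population_model(data.frame(generation = 0, ne = 100),
#'                       chromosome_length_bp = 1e7, n_loci = 50)
#' @export
population_model <- function(ne_trajectory, chromosome_length_bp,
                             recombination_rate_cM_per_Mb = 2.54,
                             n_loci = 100,
                             init_freq_range = c(0.05, 0.95),
                             seed = 1) {
  tr <- as.data.frame(ne_trajectory)
  if (!all(c("generation", "ne") %in% names(tr))) {
    stop_input("`ne_trajectory` needs columns `generation` and `ne`")
  }
  if (nrow(tr) < 1 || tr$generation[1] != 0 ||
      any(diff(tr$generation) <= 0)) {
    stop_input("trajectory generations must start at 0 and be strictly increasing")
  }
  if (any(tr$ne <= 1)) stop_input("all Ne values must exceed 1")
  stopifnot(chromosome_length_bp >= 1, recombination_rate_cM_per_Mb > 0,
            n_loci >= 2, length(init_freq_range) == 2,
            init_freq_range[1] > 0, init_freq_range[2] < 1,
            init_freq_range[1] <= init_freq_range[2])
  structure(list(ne_trajectory = tr,
                 chromosome_length_bp = chromosome_length_bp,
                 recombination_rate_cM_per_Mb = recombination_rate_cM_per_Mb,
                 n_loci = n_loci,
                 init_freq_range = init_freq_range,
                 seed = seed),
            class = "population_model")
}

# Ne in force at generation g before sampling (step function)
ne_at_generation <- function(model, g) {
  tr <- model$ne_trajectory
  tr$ne[findInterval(g, tr$generation)]
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates a closed diploid population forward in time under the
#' piecewise-constant `Ne(t)` of a [population_model()], with crossovers
#' between adjacent loci at the recombination fraction implied by their
#' genetic-map distance (Haldane).  The population starts at linkage
#' equilibrium with standing variation; no mutation occurs, so LD at the
#' sampled generation reflects drift and recombination alone — the input the
#' LD-decay Ne estimator assumes.
#'
#' @param model A [population_model()].
#' @param sample_size Diploid individuals sampled at generation 0; must not
#'   exceed the smallest Ne of the trajectory.
#' @param generations Number of generations simulated; must cover the
#'   trajectory (>= its oldest change point).  Defaults to the oldest change
#'   point, or errors if the trajectory is constant and no span is given.
#' @param seed Integer seed (defaults to the model's).
#' @param init_haplotypes Optional 0/1 matrix (`2 * Ne(oldest)` rows,
#'   `n_loci` columns) fixing the founding haplotypes instead of drawing
#'   them at linkage equilibrium; lets tests plant known LD structure.
#' @return A [genotype_set()] with `cM` map positions and the sampled
#'   haplotypes in `$haplotypes` (rows `2i-1`, `2i` belong to individual `i`).
#' @examples
#' m <- population_model(data.frame(generation = 0, ne = 50),
#'                       chromosome_length_bp = 1e6, n_loci = 20)
#' gs <- simulate_wright_fisher(m, sample_size = 10, generations = 30)
#' @export
simulate_wright_fisher <- function(model, sample_size,
                                   generations = NULL, seed = model$seed,
                                   init_haplotypes = NULL) {
  stopifnot(inherits(model, "population_model"), sample_size >= 1)
  oldest <- max(model$ne_trajectory$generation)
  if (is.null(generations)) {
    if (oldest == 0) stop_input("constant trajectory: give `generations` explicitly")
    generations <- oldest
  }
  if (generations < oldest) {
    stop_input("`generations` is shorter than the span described by the trajectory")
  }
  stopifnot(generations >= 1)
  if (sample_size > min(model$ne_trajectory$ne)) {
    stop_input("`sample_size` must not exceed the smallest Ne")
  }
  L <- model$n_loci
  withr::with_seed(seed, {
    pos <- sort(sample.int(model$chromosome_length_bp, L))
    cM <- pos / 1e6 * model$recombination_rate_cM_per_Mb
    c_adj <- 0.5 * (1 - exp(-2 * diff(cM) / 100))  # Haldane, adjacent intervals
    N <- ne_at_generation(model, generations)
    if (is.null(init_haplotypes)) {
      p0 <- stats::runif(L, model$init_freq_range[1], model$init_freq_range[2])
      H <- matrix(stats::rbinom(2 * N * L, 1, rep(p0, each = 2 * N)), nrow = 2 * N)
    } else {
      H <- as.matrix(init_haplotypes)
      if (nrow(H) != 2 * N || ncol(H) != L) {
        stop_input("init_haplotypes must be 2*Ne(oldest) x n_loci")
      }
    }
    col_of <- function(G) matrix(c_adj, G, L - 1, byrow = TRUE)
    for (g in seq(generations - 1, 0)) {
      N2 <- ne_at_generation(model, g)
      G <- 2 * N2
      parent <- sample.int(N, G, replace = TRUE)
      # which parental haplotype each gamete copies, per locus (0/1)
      w <- matrix(0L, G, L)
      w[, 1] <- sample.int(2, G, replace = TRUE) - 1L
      x <- matrix(stats::runif(G * (L - 1)), G) < col_of(G)
      for (l in 2:L) w[, l] <- (w[, l - 1] + x[, l - 1]) %% 2L
      row_idx <- 2L * (parent - 1L) + 1L + w       # recycles parent down columns
      lin <- row_idx + matrix((seq_len(L) - 1L) * nrow(H), G, L, byrow = TRUE)
      # as.vector: a two-column index matrix would otherwise be read as
      # (row, col) pairs when L == 2
      H <- matrix(H[as.vector(lin)], G, L)
      N <- N2
    }
    ind <- sample.int(N, sample_size)
    hap_rows <- as.vector(rbind(2 * ind - 1, 2 * ind))
    haps <- H[hap_rows, , drop = FALSE]
    ab <- random_allele_pairs(L)
  })
  geno <- haps[seq(1, nrow(haps), 2), , drop = FALSE] +
    haps[seq(2, nrow(haps), 2), , drop = FALSE]
  rownames(geno) <- sprintf("wf_%03d", seq_len(sample_size))
  loci <- data.frame(chrom = "1", pos = pos, allele_a = ab[, 1],
                     allele_b = ab[, 2], cM = cM, stringsAsFactors = FALSE)
  genotype_set(geno, loci, haplotypes = haps)
}
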