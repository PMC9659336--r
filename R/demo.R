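#' Simulate one specimen's reads across several diagnostic panels
#'
#' Draws a fresh diploid genotype for the specimen at each contrast's panel
#' SNPs — from the truth-side frequencies named in `sides` — and simulates
#' low-coverage reads over each panel from one genome-wide read pool.
#' Panel hits are drawn per panel with probability
#' `footprint / genome_size_bp`; since the combined footprint is a tiny
#' fraction of the genome the per-panel draws are effectively independent.
#'
#' @param id Specimen id.
#' @param truths Named list of `two_pop_truth` objects (one per contrast).
#' @param sides Named character vector: for each contrast, which truth
#'   label the specimen belongs to.
#' @param total_reads Genome-wide aligned reads.
#' @param genome_size_bp,error_rate,damage_rate,read_length_bp As in
#'   [simulate_reads()].
#' @param seed Integer seed.
#' @return A single [read_observations()] object pooling all panels'
#'   records.
#' @export
simulate_specimen_reads <- function(id, truths, sides, total_reads,
                                    genome_size_bp = 726e6,
                                    error_rate = 0.002, damage_rate = 0.05,
                                    read_length_bp = 60, seed = 1) {
  stopifnot(is.list(truths), length(truths) >= 1,
            all(names(truths) %in% names(sides)))
  recs <- list()
  for (k in seq_along(truths)) {
    tr <- truths[[k]]
    side <- sides[[names(truths)[k]]]
    if (!side %in% tr$labels) {
      stop_input("side '", side, "' is not a label of contrast '",
                 names(truths)[k], "'")
    }
    p <- if (side == tr$labels[1]) tr$snps$freq1 else tr$snps$freq2
    g <- withr::with_seed(derive_seed(seed, k, 1),
                          stats::rbinom(length(p), 2, p))
    gs <- genotype_set(matrix(g, nrow = 1, dimnames = list(id, NULL)),
                       tr$snps[, c("chrom", "pos", "allele_a", "allele_b")])
    obs <- simulate_reads(gs, tr$snps[, c("chrom", "pos")], total_reads,
                          genome_size_bp, error_rate, damage_rate,
                          read_length_bp, seed = derive_seed(seed, k, 2))[[1]]
    recs[[k]] <- obs$records
  }
  read_observations(id, do.call(rbind, recs), total_reads)
}

demo_default_config <- function() {
  list(
    # reference panel construction
    n_ref_per_pop = 100,
    panel_snps = c(season = 835, inversion = 4503, salinity = 2303),
    delta_p = list(season = c(0.7, 1), inversion = c(0.7, 1),
                   salinity = c(0.5, 0.9)),
    min_abs_delta_p = 0.5,
    # specimens: 3 sites x 8, planted composition per site
    sites = list(
      site_A = c(high = 5, low = 3, spring = 0),
      site_B = c(high = 4, low = 4, spring = 0),
      site_C = c(high = 0, low = 6, spring = 2)),
    specimen_reads = 100000,
    genome_size_bp = 726e6,
    error_rate = 0.002, damage_rate = 0.05, read_length_bp = 60,
    min_reads = c(season = 50000, inversion = 50000, salinity = 60000),
    tau_salinity = c(0.3, 0.7),
    # scaled-down sensitivity stage
    sensitivity_grid = c(10000L, 50000L, 100000L),
    sensitivity_n_boot = 5, sensitivity_individuals = 4,
    sensitivity_base_reads = 150000,
    # demography stage (scaled down)
    wf = list(ne = 150, generations = 150, n_loci = 300,
              chromosome_length_bp = 2e7, sample_size = 50),
    ne_boot = 10, snps_per_chromosome = 300,
    generation_time_years = 3, sampling_year = 2010,
    # reference statistics stage
    pi_window_bp = 1e5,
    roh = c(window_snps = 50, max_het = 1, min_length_bp = 50000))
}

#' Run the full pipeline on synthetic data with known truth
#'
#' End-to-end demonstration workflow: simulate divergent-population truths
#' for the three contrasts (spawning season, chromosomal inversion,
#' salinity), build panels from labelled reference genotypes, run the
#' downsampling sensitivity protocol, assign a cohort of low-coverage
#' specimens hierarchically, aggregate per site, compute reference
#' diversity/kinship/ROH statistics, and estimate a recent Ne trajectory
#' from a Wright-Fisher cohort.  Every stage writes a TSV under `out_dir`
#' and the run closes with a manifest of per-file MD5 checksums, so two
#' runs with the same seed produce identical manifests.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param config Optional overrides of the demo defaults (see
#'   `stocktrace:::demo_default_config()`).
#' @return Invisibly, a list with the per-stage objects, the planted truth
#'   labels, file paths and the manifest data frame.
#' @export
run_demo <- function(out_dir, seed = 1, config = list()) {
  cfg <- utils::modifyList(demo_default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  save_tsv <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  # stage 1: truths and reference panels (distinct chromosomes per contrast)
  contrasts <- list(
    season = list(labels = c("autumn", "spring"), chrom = "chr4"),
    inversion = list(labels = c("baltic", "atlantic"), chrom = "chr12"),
    salinity = list(labels = c("high", "low"), chrom = "chr6"))
  truths <- list(); panels <- list()
  for (k in seq_along(contrasts)) {
    nm <- names(contrasts)[k]
    truths[[nm]] <- simulate_divergent_populations(
      cfg$panel_snps[[nm]], cfg$delta_p[[nm]], seed = derive_seed(seed, 10, k),
      labels = contrasts[[nm]]$labels, chrom = contrasts[[nm]]$chrom,
      chrom_length_bp = 50e6)
    ref <- sample_genotypes(truths[[nm]], cfg$n_ref_per_pop,
                            seed = derive_seed(seed, 11, k))
    panels[[nm]] <- select_divergent_snps(ref, min_abs_delta_p = cfg$min_abs_delta_p,
                                          contrast = nm,
                                          group_names = contrasts[[nm]]$labels)
    save_tsv(paste0("panel_", nm, ".tsv"),
             function(p) write_panel_tsv(panels[[nm]], p))
  }

  # stage 2: sensitivity for the season test (scaled grid)
  sens_truth <- rep(contrasts$season$labels,
                    length.out = cfg$sensitivity_individuals)
  sens_ind <- lapply(seq_len(cfg$sensitivity_individuals), function(i) {
    obs <- simulate_specimen_reads(
      sprintf("sens_%02d", i), truths["season"],
      c(season = sens_truth[i]), cfg$sensitivity_base_reads,
      cfg$genome_size_bp, cfg$error_rate, cfg$damage_rate,
      cfg$read_length_bp, seed = derive_seed(seed, 20, i))
    list(obs = obs, truth = sens_truth[i])
  })
  curve <- run_sensitivity(sens_ind, panels$season, cfg$sensitivity_grid,
                           cfg$sensitivity_n_boot, seed = derive_seed(seed, 21))
  save_tsv("sensitivity_season.tsv", function(p) {
    utils::write.table(as.data.frame(curve), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  min_depth <- minimum_read_depth(curve)

  # stage 3: specimen cohort with planted composition
  planted <- list(); specimens <- list()
  i <- 0
  for (site in names(cfg$sites)) {
    comp <- cfg$sites[[site]]
    for (kind in names(comp)) {
      for (r in seq_len(comp[[kind]])) {
        i <- i + 1
        id <- sprintf("%s_%02d", site, i)
        sides <- switch(kind,
                        high = c(season = "autumn", inversion = "baltic",
                                 salinity = "high"),
                        low = c(season = "autumn", inversion = "baltic",
                                salinity = "low"),
                        spring = c(season = "spring", inversion = "baltic",
                                   salinity = "low"))
        truth_label <- if (kind == "spring") {
          paste("spring", "NA", sides[["salinity"]], sep = "/")
        } else {
          paste(sides[["season"]], sides[["inversion"]], sides[["salinity"]],
                sep = "/")
        }
        planted[[id]] <- list(site = site, sides = sides, label = truth_label)
        specimens[[id]] <- simulate_specimen_reads(
          id, truths, sides, cfg$specimen_reads, cfg$genome_size_bp,
          cfg$error_rate, cfg$damage_rate, cfg$read_length_bp,
          seed = derive_seed(seed, 30, i))
      }
    }
  }
  save_tsv("specimen_observations.tsv",
           function(p) write_observations_tsv(specimens, p))

  # stage 4: hierarchical assignment + per-site aggregation
  assignments <- lapply(specimens, function(obs) {
    hierarchical_assign(obs, panels$season, panels$inversion, panels$salinity,
                        min_reads = cfg$min_reads,
                        tau_salinity = cfg$tau_salinity)
  })
  assign_df <- do.call(rbind, lapply(names(assignments), function(id) {
    a <- assignments[[id]]
    data.frame(specimen = id, site = planted[[id]]$site,
               truth = planted[[id]]$label,
               season = a$season, inversion = a$inversion,
               salinity = a$salinity, composite = a$composite,
               label = ifelse(is.na(a$label), "NA", a$label),
               total_reads = a$total_read_count, stringsAsFactors = FALSE)
  }))
  save_tsv("assignments.tsv", function(p) {
    utils::write.table(assign_df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  target <- "autumn/baltic/high"
  site_df <- do.call(rbind, lapply(names(cfg$sites), function(site) {
    idx <- assign_df$site == site
    agg <- aggregate_site(ifelse(assign_df$label[idx] == "NA", NA,
                                 assign_df$label[idx]), target)
    data.frame(site = site, target = target, count = agg$count, n = agg$n,
               percentage = agg$percentage, stringsAsFactors = FALSE)
  }))
  save_tsv("site_aggregation.tsv", function(p) {
    utils::write.table(site_df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # stage 5: reference diversity, kinship, ROH on a reference cohort
  ref_stats <- sample_genotypes(truths$salinity, 10,
                                seed = derive_seed(seed, 40))
  pi_tab <- windowed_pi(ref_stats, window_bp = cfg$pi_window_bp)
  save_tsv("windowed_pi.tsv", function(p) write_windowed_pi_tsv(pi_tab, p))
  kin <- kinship_matrix(subset_loci(ref_stats, seq_len(min(1000, n_loci(ref_stats)))))
  save_tsv("kinship.tsv", function(p) {
    utils::write.table(round(kin, 6), p, sep = "\t", quote = FALSE,
                       col.names = NA)
  })
  wf <- simulate_wright_fisher(
    population_model(data.frame(generation = 0, ne = cfg$wf$ne),
                     chromosome_length_bp = cfg$wf$chromosome_length_bp,
                     n_loci = cfg$wf$n_loci, seed = derive_seed(seed, 41)),
    sample_size = cfg$wf$sample_size, generations = cfg$wf$generations)
  roh <- detect_roh(wf, cfg$roh[["window_snps"]], cfg$roh[["max_het"]],
                    cfg$roh[["min_length_bp"]])
  roh_dated <- date_and_bin_roh(roh, cfg$generation_time_years)
  save_tsv("roh_bins.tsv", function(p) {
    utils::write.table(roh_dated$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # stage 6: LD-decay Ne trajectory, calibrated
  traj <- bootstrap_ne(wf, n_boot = cfg$ne_boot,
                       snps_per_chromosome = cfg$snps_per_chromosome,
                       seed = derive_seed(seed, 42))
  calib <- calibrate_trajectory(traj, cfg$generation_time_years,
                                cfg$sampling_year)
  save_tsv("ne_trajectory.tsv", function(p) write_trajectory_tsv(calib, p))

  # manifest: parameters echo + per-file checksums
  manifest <- data.frame(file = names(paths),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  p <- file.path(out_dir, "manifest.tsv")
  writeLines(c(paste0("# seed=", seed),
               paste0("# package_version=", "0.1.0"),
               paste(c("file", "md5"), collapse = "\t"),
               paste(manifest$file, manifest$md5, sep = "\t")), p)

  invisible(list(truths = truths, panels = panels, sensitivity = curve,
                 minimum_read_depth = min_depth, planted = planted,
                 assignments = assignments, assignment_table = assign_df,
                 site_table = site_df, pi = pi_tab, kinship = kin,
                 roh = roh_dated, trajectory = calib,
                 paths = paths, manifest = manifest))
}
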