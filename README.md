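# stocktrace

Population assignment of ultra-low-coverage specimens and recent
demographic reconstruction for high-gene-flow stocks.

Marine species such as herring form huge, weakly structured stocks that
differ mainly at a small set of highly diagnostic loci — spawning-season
genes, chromosomal inversions, salinity-adaptation SNPs.  Archaeological
(ancient DNA) specimens of such species typically yield only 0.002–2.5×
coverage, far too little for genotype calling, yet enough to place a fish
in its stock of origin if the evidence is used read by read.  stocktrace
implements that inference chain for analysts working at the interface of
population genomics and historical ecology:

* **Diagnostic panels** — select SNPs with allele-frequency differential
  |Δp| ≥ τ between two labelled reference groups, or import published
  panels (`select_divergent_snps()`, `import_panel()`).
* **Low-coverage assignment** — per-read log-likelihood-ratio scoring
  with frequency clamping: Λ = Σ ln(p₁ᶜ/p₂ᶜ), score = 1/(1+e^(−Λ)),
  the posterior weight of group 1 under equal priors
  (`score_assignment()`, `classify()`); three tests (spawning season →
  chromosome-12-style inversion → salinity, with a "mid" salinity band)
  combine hierarchically into a final stock label
  (`hierarchical_assign()`, `aggregate_site()`).
* **Sensitivity** — the downsampling/bootstrap protocol that determines
  each test's minimum read depth for perfect classification over a
  500–100,000-read grid (`run_sensitivity()`, `minimum_read_depth()`).
* **Reference statistics** — windowed nucleotide diversity π, KING-robust
  kinship φ, runs of homozygosity with coalescent dating L = 100/(2g) cM
  (`windowed_pi()`, `kinship()`, `detect_roh()`, `date_and_bin_roh()`).
* **Recent Ne from LD decay** — Sved-relation binning estimator
  E[r²] ≈ 1/(1+4Nₑc) + 1/n on unphased dosage r², geometric-mean
  bootstrap, calendar calibration with generation times and sampling-year
  offsets (`pairwise_r2()`, `ne_from_ld()`, `bootstrap_ne()`,
  `calibrate_trajectory()`).
* **Synthetic truth** — generators for divergent population pairs,
  Hardy–Weinberg genotypes, forward Wright–Fisher simulation with
  recombination, and damaged low-coverage reads, so every stage is
  testable against known ground truth (`simulate_*()`, `run_demo()`).

The methods vignette (`vignettes/stock-reconstruction.Rmd`) documents the
models, defaults and design decisions in detail.

## Worked example

Build an inversion-type panel from labelled reference genotypes, assign a
low-coverage specimen, and measure the read depth the test needs:

```r
library(stocktrace)

truth <- simulate_divergent_populations(4503, delta_p = c(0.7, 1), seed = 101,
                                        labels = c("baltic", "atlantic"),
                                        chrom = "chr12", chrom_length_bp = 25e6)
ref   <- sample_genotypes(truth, 100, seed = 102)
panel <- select_divergent_snps(ref, min_abs_delta_p = 0.5,
                               contrast = "inversion",
                               group_names = truth$labels)
panel
#> <snp_panel> 'inversion' (selected): 4503 SNPs; baltic vs atlantic
#>   mean |dp| = 0.849

obs <- simulate_specimen_reads("ancient_01", list(inversion = truth),
                               c(inversion = "baltic"),
                               total_reads = 55000, seed = 7)
obs
#> <read_obs> specimen ancient_01: 18 panel-site observations from 55,000 total reads

classify(score_assignment(obs, panel))
#> <assignment_result> inversion: score 1.0000 from 18 informative / 18 observations; call group1
```

Of 55,000 genome-wide reads, 18 landed on panel SNPs; their summed
log-likelihood ratios give a posterior weight ≈ 1 for the Baltic-type
inversion (group 1), so the specimen is called `baltic`.  The sensitivity
protocol (8 known individuals × 29 grid depths × 20 bootstrap replicates)
reports the smallest depth at which every replicate of every individual is
classified correctly, stably across all larger depths:

```r
inds <- lapply(1:8, function(i) {
  lab <- truth$labels[(i %% 2) + 1]
  list(obs = simulate_specimen_reads(sprintf("modern_%d", i),
                                     list(inversion = truth),
                                     c(inversion = lab), 150000,
                                     seed = derive_seed(101, 60, i)),
       truth = lab)
})
curve <- run_sensitivity(inds, panel, n_boot = 20, seed = 103)
minimum_read_depth(curve)
#> [1] 30000
```

Recent effective population size from LD decay, on simulated truth with
constant Nₑ = 200 (100 sampled diploids, 500 loci over ~100 cM):

```r
m  <- population_model(data.frame(generation = 0, ne = 200),
                       chromosome_length_bp = 4e7, n_loci = 500, seed = 42)
wf <- simulate_wright_fisher(m, sample_size = 100, generations = 250)
traj <- bootstrap_ne(wf, n_boot = 10, snps_per_chromosome = 400, seed = 1)
cal  <- calibrate_trajectory(traj, generation_time_years = 3, sampling_year = 2010)
round(head(as.data.frame(cal)[, c("t_gen", "ne", "lo", "hi",
                                  "years_before_sampling")], 8), 1)
#>   t_gen    ne    lo    hi years_before_sampling
#> 1   4.3 200.5 195.3 209.6                  12.9
#> 2   5.9 175.1 166.3 183.5                  17.6
#> 3   8.0 217.3 196.4 237.8                  24.1
#> 4  11.0 249.9 230.5 279.3                  32.9
#> 5  14.9 253.6 242.6 277.7                  44.8
#> 6  20.2 194.4 183.6 208.9                  60.7
#> 7  27.7 246.6 216.5 277.2                  83.1
#> 8  37.8 275.1 243.4 302.6                 113.4
```

Each row is one recombination-fraction bin: `t_gen` is the generation
depth ≈ 1/(2c) that bin informs, `ne` the geometric-mean estimate over
bootstrap iterations with its 2.5/97.5 percentile interval, and the years
column the calendar calibration at a 3-year generation time.  The truth
(200) is recovered throughout within the estimator's expected factor-1.5
band.  `run_demo(out_dir, seed)` chains all stages — simulation, panel
selection, sensitivity, hierarchical assignment of a 24-specimen cohort,
per-site aggregation, diversity/kinship/ROH statistics and the calibrated
trajectory — writing TSVs plus a checksum manifest that is identical
across runs with the same seed.

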