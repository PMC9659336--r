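---
title: "Reconstructing stock dynamics from low-coverage genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stock dynamics from low-coverage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stocktrace)
```

stocktrace implements an inference chain used in marine historical ecology:
given labelled reference genomes for a set of stocks, and ancient specimens
that yield only a few thousand to a few hundred thousand aligned reads
(0.002–2.5× coverage, chemically damaged), identify which stock each
specimen came from, quantify how many reads that identification needs, and
reconstruct each stock's recent effective-population-size history.  This
vignette documents the models, the tunable parameters and their defaults,
the synthetic-data generator that backs the test suite, and the design
decisions taken where the methodology is genuinely open.

## 1. Diagnostic panels

A panel ties a binary population contrast (spring vs. autumn spawning,
Atlantic-type vs. Baltic-type chromosomal inversion, high vs. low salinity
adaptation) to a set of SNPs with per-group frequencies of a reference
allele.  `select_divergent_snps()` retains the SNPs with at least
`min_group_calls` called individuals per group (default 2) and an absolute
frequency differential of at least `min_abs_delta_p` (default 0.5).
Frequencies come from called alleles only; missing genotypes are excluded
from denominators rather than imputed, because imputation would leak the
group label into the frequency estimate.  Published panels enter through
`import_panel()` unchanged.  Selection is label-symmetric and monotone in
the threshold, two properties the test suite checks against brute-force
recomputation.

## 2. Assignment scoring

For low-coverage data a genotype call per site is impossible; the unit of
evidence is one read overlapping one panel SNP.  `score_assignment()` sums
per-observation log-likelihood ratios: an observed allele with clamped
group frequencies $p_1^c, p_2^c$ contributes $\ln(p_1^c / p_2^c)$, and
under equal priors the summed ratio $\Lambda$ maps to the posterior weight
of group 1, $s = 1 / (1 + e^{-\Lambda})$.  Choices worth stating:

* **Clamping** (`freq_clamp`, default 0.001) bounds frequencies into
  $[0.001, 0.999]$ so fixed differences contribute $\pm\ln(999) \approx
  \pm 6.9$ rather than $\pm\infty$; a single damaged read can then never
  be unrecoverable.
* **Duplicate reads** at one SNP count as independent observations.  At
  well under 1× coverage, two reads on the same panel SNP are rare, and
  the sensitivity protocol quantifies any residual inflation empirically.
* **Off-panel alleles** (sequencing error or deamination products that
  match neither panel allele) are ignored by the likelihood but counted in
  `n_observations`, mirroring how real pileups behave.

`classify()` turns scores into calls: binary contrasts split at 0.5;
the salinity-style contrast keeps an intermediate "mid" band, by default
scores in (0.3, 0.7).  No published numeric band exists for the mid zone,
so these are package defaults, symmetric about ½ and configurable.  Ties
at a threshold go to group 1, deterministically; the chance-level test in
the suite therefore uses panels whose frequencies are noisy estimates
(which is how an uninformative contrast manifests in practice) rather than
exactly equal numbers.

`hierarchical_assign()` chains the three tests: spawning season first;
the inversion test only for autumn-side calls (only autumn-spawning fish
are differentiated at the inversion); salinity last with the mid band.
Each test runs only if the specimen's genome-wide read total reaches its
gate — defaults 50,000 reads for season and inversion and 60,000 for
salinity, the depths at which the sensitivity protocol saturates for
panels of this size.  The composite string always shows `NA` for a test
that was skipped or absent (e.g. `"autumn/baltic/NA"`), while the
population *label* is only emitted when every applicable test produced a
call; `aggregate_site()` then tabulates labels per assemblage with
percentages rounded to one decimal.

## 3. Read-depth sensitivity

`run_sensitivity()` implements the downsampling/bootstrap protocol on the
grid `downsampling_grid()`: 500–10,000 reads in steps of 500, then
20,000–100,000 in steps of 10,000 (29 depths; the coarse arm starts at
20,000 so that 10,000 appears once).  For every depth, individual and
bootstrap replicate (default 20) the observations are binomially thinned
to the depth and classified; `minimum_read_depth()` reports the smallest
depth at which *all* replicates of *all* individuals are correct — with a
stability requirement that every larger grid depth also satisfies this,
because the minimum is used as a gate for real specimens and a depth that
fails again further up the grid would be an unsafe gate.  Replicate seeds
derive deterministically from the master seed and the (depth, individual,
replicate) triple via an integer mixing function (`derive_seed()`), giving
replicate independence with bit-level reproducibility.

## 4. Reference-cohort statistics

* `windowed_pi()` computes nucleotide diversity in 100-kb physical windows
  (half-open, 0-based output per the BED convention), treating all sampled
  alleles as exchangeable haplotypes; each site contributes
  $k(H-k)/\binom{H}{2}$ pairwise differences.
* `kinship()` is the robust within-population estimator
  $\varphi = (N_{het,het} - 2N_{opp,hom}) / (N_{het}(i) + N_{het}(j))$,
  with its exact self-kinship identity of 0.5 and pedigree expectations
  (0.25 parent–offspring) used as test oracles.
* `detect_roh()` flags sliding windows of `window_snps` SNPs (default 50)
  containing at most `max_het_per_window` heterozygotes (default 1),
  merges overlapping flagged windows, and discards merged runs shorter
  than `min_length_bp` (default 50 kb).  No standard caller parameterisation
  exists for this estimator family; these defaults are this package's own,
  sized so that tracts of a few hundred kb — the depths reachable at a
  herring-like 2.54 cM/Mb recombination rate — are recoverable, which the
  suite verifies with planted tracts.
* `date_and_bin_roh()` dates a tract of genetic length $L$ cM to
  $g = 100/(2L)$ generations (the expected IBD-segment-length relation),
  converts with the generation time, and bins ages half-open on the
  younger edge (default bins 650–400 and 400–200 years before present), so
  a tract dated exactly on a shared edge falls in the younger bin.

## 5. LD-decay effective population size

Pairs of loci at recombination fraction $c$ carry information about
effective size roughly $t = 1/(2c)$ generations ago.  `pairwise_r2()`
computes unphased dosage correlations (Rogers–Huff style — no phasing is
assumed or required), with $c$ from the inverse Haldane map
$c = (1 - e^{-2d/100})/2$ of the cM distance.  `ne_from_ld()` bins pairs
on $c$ (default 20 log-spaced bins over $[5\times10^{-4}, 0.25]$) and
inverts the Sved relation per bin:

$$E[r^2] \approx \frac{1}{1 + 4 N_e c} + \frac{1}{n}
\quad\Rightarrow\quad
\hat N_e(\bar c) = \frac{1/(\bar r^2 - 1/n) - 1}{4\bar c},$$

with $n$ the number of sampled haplotypes (2 × diploids).  This is a
deliberately transparent classical binning estimator following the
field's aggregation and calibration conventions; it is *not* a
re-implementation of any specific LD-demography program, and no
equivalence is claimed.  Its validation is by parameter recovery: exact
Sved-form input inverts to machine precision, and forward Wright–Fisher
truth at constant $N_e = 200$ is recovered within a factor of 1.5 (median
over 20 replicates) in the 10–100-generation bins.  Two numerical notes:
bins whose mean $r^2$ does not exceed the $1/n$ sampling floor are
unidentifiable and dropped with a warning; and for *independent* loci the
expected squared dosage correlation over $n_{ind}$ individuals is
$1/(n_{ind}-1) \approx 2/n$, which is why distant bins approach the floor
from above.

`bootstrap_ne()` repeats the estimate on random per-chromosome SNP subsets
(default 40 iterations — the convention for this analysis — at a
desk-scale 2,000 SNPs per chromosome; the field-scale 50,000 remains a
configuration value) and aggregates per bin by geometric mean with
2.5/97.5 percentile intervals, the appropriate mean for strictly positive,
right-skewed estimates.

`calibrate_trajectory()` is a pure unit transform: $N_e$ values are never
modified.  It removes points in the most recent `trim_recent` generations
(default 4; LD estimators at small sample sizes produce artifactual
near-zero bottlenecks there), multiplies generations by the generation
time — use the stock's *minimum* (3 y for autumn-spawning herring, 2 y for
spring-spawning), since overlapping generations make the average
unidentifiable and the minimum is the earliest age at which fish
contribute to the next generation — and offsets by the sampling year.
Points beyond `max_generations` (default 200, the estimator family's
accuracy window; 600/400 calendar years at 3-/2-year generations) are
flagged low-confidence but retained.  A documented caveat: LD-based
estimators are sensitive to population structure, so stocks should be
analysed as separately as the data allow.

## 6. The synthetic-data generator

Every pipeline input can be generated with known truth:

* `simulate_divergent_populations()` draws per-SNP frequency pairs whose
  absolute differential follows a requested distribution.  The defaults
  used in the package's own harnesses are $|\Delta p| \sim U(0.7, 1)$ for
  season- and inversion-like contrasts (these loci are near-diagnostic in
  the wild) and $U(0.5, 0.9)$ for the weaker salinity contrast, at
  paper-scale panel sizes (835, 4,503 and 2,303 SNPs).
* `sample_genotypes()` draws diploid Hardy–Weinberg genotypes
  (chi-square goodness of fit checked at $n = 10{,}000$).
* `simulate_reads()` models a specimen as a genome-wide pool of
  `total_reads` aligned reads (the unit the depth grid and gates use, since
  downsampling operates on alignment files).  A read hits the panel with
  probability `n_sites × read_length / genome_size` (defaults 60 bp and
  726 Mb, herring-scale); each hit samples one of the two alleles, suffers
  sequencing error with probability 0.002 (flip to a uniformly chosen
  other base) and post-mortem C→T / G→A substitution with probability
  0.05 applied to the observed base.  Damage is uniform per observation —
  assignment only sees per-site allele observations, so a within-read
  position profile would add parameters without changing the math; that
  profile, and read-level FASTQ/BAM simulation, are out of scope.  The
  effective panel-overlap rate of real alignments is not published for
  any dataset we emulate; the footprint model is this package's own
  construction and is validated only against its binomial expectation.
* `simulate_wright_fisher()` runs a forward diploid Wright–Fisher model
  with piecewise-constant $N_e(t)$ and Haldane crossovers, started from
  standing variation at linkage equilibrium ($U(0.05, 0.95)$ initial
  frequencies, no new mutation — LD-decay estimation uses segregating
  sites only).  Sved's expectation at constant $N_e$ is verified on the
  simulated haplotypes; bottleneck truths produce declining recovered
  trajectories.
* `downsample_reads()` is binomial thinning, composable in distribution.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: reference bias and mapping error, damage
concentrated at read termini, contamination, linked selection on panel
SNPs, overlapping generations, and population structure within a labelled
group.  Conclusions about real specimens still require the wet-lab
authentication steps (deamination profiles, decontamination) that sit
outside this package.

## 7. Problem sizes and determinism

The shipped test suite runs the full sensitivity protocol at its design
scale (8 individuals × 29 depths × 20 replicates = 4,640 assignments per
test), 24-specimen hierarchical cohorts at 100,000 reads, 20 replicate
Wright–Fisher recoveries at $N_e = 200$ with 100 sampled diploids and 500
loci over ~100 cM, and desk-scale bootstraps; these sizes were chosen so a
complete run finishes in a few minutes on one CPU while keeping every
Monte-Carlo check at 3-standard-error resolution.  All stochastic stages
take explicit seeds, and nested stages derive child seeds with
`derive_seed()`, so every result in the demo (`run_demo()`) reproduces
checksum-identically from one master seed.
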