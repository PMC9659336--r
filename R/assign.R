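#' Score a low-coverage specimen against a diagnostic panel
#'
#' For every observation whose position and allele match a panel SNP, the
#' observed allele's group frequencies (clamped to
#' `[freq_clamp, 1 - freq_clamp]`) contribute a log-likelihood-ratio term
#' `log(p1 / p2)`.  Under equal priors the summed log ratio maps to the
#' posterior weight of group1, `score = 1 / (1 + exp(-lambda))`.
#' Observations at non-panel positions, or with alleles matching neither
#' panel allele (e.g. damage products), are ignored but counted in
#' `n_observations`.  Multiple reads at one SNP are treated as independent
#' observations: at the coverages this estimator targets (well below 1x)
#' duplicate hits at a site are rare.
#'
#' @param obs A [read_observations()] object.
#' @param panel A non-empty [snp_panel].
#' @param freq_clamp Clamp in `(0, 0.5)`; keeps log ratios finite at fixed
#'   differences (default 0.001).
#' @return An `assignment_result`: list with `contrast`, `score`, `lambda`,
#'   `n_informative_sites` (usable observations), `n_observations` and
#'   `call` (`"no_call"` until [classify()] is applied, and always
#'   `"no_call"` when no observation was usable).
#' @examples
#' pan <- import_panel(data.frame(chrom = "1", pos = 100, allele_a = "A",
#'                                allele_b = "G", p_group1 = 1, p_group2 = 0),
#'                     groups = c("g1", "g2"))
#' obs <- read_observations("s", data.frame(chrom = "1", pos = 100, allele = "A"), 10)
#' score_assignment(obs, pan)$score
#' @export
score_assignment <- function(obs, panel, freq_clamp = 0.001) {
  stopifnot(inherits(obs, "read_obs"), inherits(panel, "snp_panel"),
            freq_clamp > 0, freq_clamp < 0.5)
  if (nrow(panel$snps) == 0) stop_input("empty panel")
  rec <- obs$records
  lambda <- 0
  n_inf <- 0L
  if (nrow(rec)) {
    m <- match(locus_key(rec$chrom, rec$pos), panel_key(panel))
    hit <- !is.na(m)
    if (any(hit)) {
      mi <- m[hit]
      is_a <- rec$allele[hit] == panel$snps$allele_a[mi]
      is_b <- rec$allele[hit] == panel$snps$allele_b[mi]
      use <- is_a | is_b
      if (any(use)) {
        p1 <- ifelse(is_a, panel$snps$p_group1[mi], 1 - panel$snps$p_group1[mi])[use]
        p2 <- ifelse(is_a, panel$snps$p_group2[mi], 1 - panel$snps$p_group2[mi])[use]
        lambda <- sum(log(clamp_freq(p1, freq_clamp) / clamp_freq(p2, freq_clamp)))
        n_inf <- sum(use)
      }
    }
  }
  structure(list(contrast = panel$contrast,
                 score = if (n_inf) stats::plogis(lambda) else NA_real_,
                 lambda = if (n_inf) lambda else NA_real_,
                 n_informative_sites = n_inf,
                 n_observations = nrow(rec),
                 call = "no_call"),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %s: score %s from %d informative / %d observations; call %s\n",
              x$contrast,
              if (is.na(x$score)) "NA" else sprintf("%.4f", x$score),
              x$n_informative_sites, x$n_observations, x$call))
  invisible(x)
}

#' Turn an assignment score into a call
#'
#' `score >= tau_high` calls group1, `score <= tau_low` calls group2.
#' Scores in between call `"mid"` when `allow_mid` (the salinity-style
#' three-way contrast) and otherwise the nearer side, with exact ties going
#' to group1.  A result with no informative observation stays `"no_call"`.
#'
#' @param result An `assignment_result` from [score_assignment()].
#' @param tau_low,tau_high Thresholds with `0 < tau_low <= tau_high < 1`;
#'   the default 0.5/0.5 split is the binary test.
#' @param allow_mid Whether intermediate scores call `"mid"`.
#' @return The result with `call` set to the group1 label-slot `"group1"`,
#'   `"group2"`, `"mid"` or `"no_call"` (callers map these onto group names).
#' @export
classify <- function(result, tau_low = 0.5, tau_high = 0.5, allow_mid = FALSE) {
  stopifnot(inherits(result, "assignment_result"),
            tau_low > 0, tau_high < 1, tau_low <= tau_high)
  if (result$n_informative_sites < 1) {
    result$call <- "no_call"
    return(result)
  }
  s <- result$score
  result$call <- if (s >= tau_high) "group1"
  else if (s <= tau_low) "group2"
  else if (allow_mid) "mid"
  else if (s >= (tau_low + tau_high) / 2) "group1" else "group2"
  result$tau <- c(low = tau_low, high = tau_high)
  result
}

# map a classify() slot onto the panel's group names ("mid"/"no_call" pass through)
call_label <- function(result, panel) {
  switch(result$call,
         group1 = panel$groups[1],
         group2 = panel$groups[2],
         result$call)
}

#' Hierarchical three-test population assignment
#'
#' Runs the spawning-season test, then — for autumn-side calls only — the
#' chromosomal-inversion test, then the salinity test (three-way, with a
#' `"mid"` band).  Each test runs only if the specimen's genome-wide read
#' total reaches its gate (defaults 50,000 / 50,000 / 60,000 reads); tests
#' skipped for insufficient reads are reported as `no_call` with reason.
#' The composite string always shows `NA` for absent tests; the population
#' `label` is only set when every applicable test produced a call.
#'
#' @param obs A [read_observations()] object.
#' @param season_panel,inversion_panel,salinity_panel [snp_panel] objects.
#' @param min_reads Named gates (total aligned reads) per test.
#' @param tau_salinity `c(low, high)` band for the salinity test's `"mid"`
#'   zone (default 0.3/0.7).
#' @param freq_clamp Passed to [score_assignment()].
#' @param autumn_group Season-panel group that triggers the inversion test
#'   (default the season panel's group1).
#' @return A `final_assignment`: list with per-test calls and results,
#'   `composite` (e.g. `"autumn/baltic/NA"`), `label` (composite or `NA`),
#'   `complete`, `total_read_count` and skip reasons.
#' @export
hierarchical_assign <- function(obs, season_panel, inversion_panel, salinity_panel,
                                min_reads = c(season = 50000, inversion = 50000,
                                              salinity = 60000),
                                tau_salinity = c(0.3, 0.7),
                                freq_clamp = 0.001,
                                autumn_group = season_panel$groups[1]) {
  for (p in list(season_panel, inversion_panel, salinity_panel)) {
    if (!inherits(p, "snp_panel")) stop_input("all three panels are required")
  }
  stopifnot(inherits(obs, "read_obs"),
            all(c("season", "inversion", "salinity") %in% names(min_reads)))
  total <- obs$total_read_count
  reason <- character()

  run_test <- function(panel, gate, tau_low = 0.5, tau_high = 0.5, allow_mid = FALSE) {
    if (total < gate) return(NULL)
    classify(score_assignment(obs, panel, freq_clamp), tau_low, tau_high, allow_mid)
  }

  season_res <- run_test(season_panel, min_reads[["season"]])
  if (is.null(season_res)) reason["season"] <- "insufficient_reads"
  season <- if (is.null(season_res)) "no_call" else call_label(season_res, season_panel)

  inversion_res <- NULL
  inversion <- NA_character_
  if (identical(season, autumn_group)) {
    inversion_res <- run_test(inversion_panel, min_reads[["inversion"]])
    if (is.null(inversion_res)) reason["inversion"] <- "insufficient_reads"
    inversion <- if (is.null(inversion_res)) "no_call" else
      call_label(inversion_res, inversion_panel)
  }

  salinity_res <- run_test(salinity_panel, min_reads[["salinity"]],
                           tau_salinity[1], tau_salinity[2], allow_mid = TRUE)
  if (is.null(salinity_res)) reason["salinity"] <- "insufficient_reads"
  salinity <- if (is.null(salinity_res)) "no_call" else
    call_label(salinity_res, salinity_panel)

  comp_part <- function(call) {
    if (is.na(call) || call == "no_call") "NA" else call
  }
  composite <- paste(comp_part(season), comp_part(inversion), comp_part(salinity),
                     sep = "/")
  called <- function(call) !is.na(call) && !call %in% "no_call"
  complete <- called(season) && called(salinity) &&
    (!identical(season, autumn_group) || called(inversion))
  structure(list(specimen = obs$specimen,
                 season = season, season_result = season_res,
                 inversion = inversion, inversion_result = inversion_res,
                 salinity = salinity, salinity_result = salinity_res,
                 composite = composite,
                 label = if (complete) composite else NA_character_,
                 complete = complete,
                 total_read_count = total,
                 skipped = reason),
            class = "final_assignment")
}

#' @export
print.final_assignment <- function(x, ...) {
  cat(sprintf("<final_assignment> %s (%s reads): %s%s\n",
              x$specimen, format(x$total_read_count, big.mark = ","),
              x$composite,
              if (x$complete) "" else "  [incomplete]"))
  invisible(x)
}

#' Aggregate assignments for one site
#'
#' Counts specimens carrying a target population label and reports the
#' percentage rounded to one decimal, the per-assemblage summary used for
#' site tables.
#'
#' @param assignments A list of `final_assignment` objects, or a character
#'   vector of labels (`NA` for unassigned).
#' @param target_label Label to count.
#' @return List with `count`, `n` and `percentage` (one decimal).
#' @examples
#' aggregate_site(c(rep("WBAS", 5), rep("CBAS", 6)), "WBAS")
#' @export
aggregate_site <- function(assignments, target_label) {
  if (length(assignments) == 0) stop_input("no assignments supplied")
  labels <- if (is.character(assignments)) assignments else
    vapply(assignments, function(a) {
      if (!inherits(a, "final_assignment")) stop_input("not a final_assignment")
      a$label
    }, character(1))
  count <- sum(labels == target_label, na.rm = TRUE)
  n <- length(labels)
  list(count = count, n = n, percentage = round(100 * count / n, 1))
}
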