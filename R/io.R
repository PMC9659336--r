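# File formats.  Conventions, declared in every writer's header comments:
# VCF, panel TSV and observation TSV positions are 1-based; windowed-pi
# output is 0-based half-open (BED convention).  All TSVs are plain text
# with '#'-prefixed metadata lines, and every writer round-trips through its
# reader.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         vapply(x, function(v) format(v, digits = 12, scientific = FALSE),
                character(1)))
}

read_tsv_checked <- function(path, expected_cols) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body_idx)) stop_input(path, ": no header line found")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!all(expected_cols %in% header)) {
    stop_input(path, ": header must contain: ",
               paste(expected_cols, collapse = ", "))
  }
  rows <- body_idx[-1]
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- rows[which(nf != length(header))[1]]
    stop_input(path, ": line ", bad, ": expected ", length(header),
               " fields, found ", nf[which(nf != length(header))[1]])
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- as.data.frame(matrix(character(), 0, length(header)),
                         stringsAsFactors = FALSE)
  }
  names(out) <- header
  attr(out, "meta") <- grep("^# ", lines, value = TRUE)
  out
}

meta_value <- function(meta, key) {
  hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0("^# ", key, "="), "", hit[1])
}

#' Write / read a diagnostic panel as TSV
#'
#' Tab-separated panel dialect: metadata lines `# contrast=`, `# groups=`
#' (comma-separated pair), `# provenance=`, then columns `chrom`, `pos`
#' (1-based), `allele_a`, `allele_b`, `p_group1`, `p_group2`.
#'
#' @param panel A [snp_panel].
#' @param path File path.
#' @return `write_panel_tsv` returns `path` invisibly; `read_panel_tsv`
#'   returns the [snp_panel].
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  s <- panel$snps
  lines <- c("# coordinates=1-based",
             paste0("# contrast=", panel$contrast),
             paste0("# groups=", paste(panel$groups, collapse = ",")),
             paste0("# provenance=", panel$provenance),
             paste(c("chrom", "pos", "allele_a", "allele_b",
                     "p_group1", "p_group2"), collapse = "\t"))
  if (nrow(s)) {
    lines <- c(lines, paste(s$chrom, s$pos, s$allele_a, s$allele_b,
                            fmt_num(s$p_group1), fmt_num(s$p_group2),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "allele_a", "allele_b",
                                 "p_group1", "p_group2"))
  meta <- attr(df, "meta")
  groups <- strsplit(meta_value(meta, "groups") %||%
                       stop_input(path, ": missing '# groups=' line"),
                     ",", fixed = TRUE)[[1]]
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$p_group1 <- suppressWarnings(as.numeric(df$p_group1))
  df$p_group2 <- suppressWarnings(as.numeric(df$p_group2))
  if (anyNA(df$pos) || anyNA(df$p_group1) || anyNA(df$p_group2)) {
    stop_input(path, ": non-numeric pos or frequency field")
  }
  panel <- import_panel(df, groups, meta_value(meta, "contrast") %||% "imported")
  panel$provenance <- meta_value(meta, "provenance") %||% "imported"
  panel
}

#' Write / read specimen read observations as TSV
#'
#' The pileup dialect: one row per allele observation with columns
#' `specimen`, `chrom`, `pos` (1-based), `allele`, `total_reads` (the
#' specimen's genome-wide total, repeated on each row).  Specimens whose
#' record set is empty occupy one row with `allele` `"."` and `pos` 0.
#'
#' @param obs_list A `read_obs` or list of them.
#' @param path File path.
#' @return `write_observations_tsv` returns `path` invisibly;
#'   `read_observations_tsv` returns a named list of `read_obs`.
#' @export
write_observations_tsv <- function(obs_list, path) {
  if (inherits(obs_list, "read_obs")) obs_list <- list(obs_list)
  lines <- c("# coordinates=1-based",
             paste(c("specimen", "chrom", "pos", "allele", "total_reads"),
                   collapse = "\t"))
  for (obs in obs_list) {
    stopifnot(inherits(obs, "read_obs"))
    r <- obs$records
    if (nrow(r) == 0) {
      lines <- c(lines, paste(obs$specimen, ".", 0, ".", obs$total_read_count,
                              sep = "\t"))
    } else {
      lines <- c(lines, paste(obs$specimen, r$chrom, r$pos, r$allele,
                              obs$total_read_count, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_observations_tsv
#' @export
read_observations_tsv <- function(path) {
  df <- read_tsv_checked(path, c("specimen", "chrom", "pos", "allele",
                                 "total_reads"))
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$total_reads <- suppressWarnings(as.numeric(df$total_reads))
  if (anyNA(df$pos) || anyNA(df$total_reads)) {
    stop_input(path, ": non-numeric pos or total_reads field")
  }
  out <- lapply(split(df, factor(df$specimen, levels = unique(df$specimen))),
                function(d) {
                  rec <- d[d$allele != ".", c("chrom", "pos", "allele")]
                  read_observations(d$specimen[1], rec, d$total_reads[1])
                })
  out[unique(df$specimen)]
}

#' Write / read genotypes as a minimal GT-only VCF
#'
#' Writes a plain-text VCFv4.2 dialect with `allele_a` as REF, `allele_b`
#' as ALT and unphased diploid GT fields (`0/0`, `0/1`, `1/1`, `./.`);
#' positions are 1-based.  Reading goes through `vcfR` and accepts any
#' biallelic GT-bearing VCF; dosages count REF (= `allele_a`) copies.
#'
#' @param genos A [genotype_set()] with `allele_a`/`allele_b` loci columns.
#' @param path File path.
#' @return `write_genotypes_vcf` returns `path` invisibly;
#'   `read_genotypes_vcf` returns a [genotype_set()].
#' @export
write_genotypes_vcf <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_set"),
            all(c("allele_a", "allele_b") %in% names(genos$loci)))
  ids <- rownames(genos$geno)
  gt_code <- c(`2` = "0/0", `1` = "0/1", `0` = "1/1")
  gt <- matrix("./.", n_loci(genos), n_individuals(genos))
  for (d in c(0, 1, 2)) {
    gt[t(genos$geno) == d] <- gt_code[[as.character(d)]]
  }
  lines <- c("##fileformat=VCFv4.2",
             "##source=stocktrace (GT-only dialect, 1-based positions)",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"),
             paste(genos$loci$chrom, genos$loci$pos, ".",
                   genos$loci$allele_a, genos$loci$allele_b, ".", ".", ".",
                   "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "0") + (a2 == "0")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_set(t(dos), loci)
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Columns `chrom`, `pos`, `allele_a`, `allele_b`, then one dosage column
#' per individual (count of `allele_a`, `NA` for missing); an optional
#' `# pop=` metadata line carries population labels.
#'
#' @param genos A [genotype_set()].
#' @param path File path.
#' @return `write_genotypes_tsv` returns `path` invisibly;
#'   `read_genotypes_tsv` returns a [genotype_set()].
#' @export
write_genotypes_tsv <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_set"))
  ids <- rownames(genos$geno)
  lines <- "# coordinates=1-based"
  if (!is.null(genos$pop)) {
    lines <- c(lines, paste0("# pop=", paste(genos$pop, collapse = ",")))
  }
  has_ab <- all(c("allele_a", "allele_b") %in% names(genos$loci))
  aa <- if (has_ab) genos$loci$allele_a else "A"
  bb <- if (has_ab) genos$loci$allele_b else "C"
  lines <- c(lines,
             paste(c("chrom", "pos", "allele_a", "allele_b", ids),
                   collapse = "\t"),
             paste(genos$loci$chrom, genos$loci$pos, aa, bb,
                   apply(t(genos$geno), 1, function(r)
                     paste(ifelse(is.na(r), "NA", r), collapse = "\t")),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "allele_a", "allele_b"))
  meta <- attr(df, "meta")
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(df$pos)) stop_input(path, ": non-numeric pos field")
  ids <- setdiff(names(df), c("chrom", "pos", "allele_a", "allele_b"))
  geno <- t(vapply(ids, function(id) {
    d <- suppressWarnings(as.numeric(df[[id]]))
    d
  }, numeric(nrow(df))))
  if (nrow(df) == 1) geno <- matrix(geno, ncol = 1, dimnames = list(ids, NULL))
  rownames(geno) <- ids
  pop <- meta_value(meta, "pop")
  if (!is.null(pop)) pop <- strsplit(pop, ",", fixed = TRUE)[[1]]
  genotype_set(geno, df[, c("chrom", "pos", "allele_a", "allele_b")], pop = pop)
}

#' Write a windowed-diversity table (BED-like)
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `pi`.
#'
#' @param pi_table Output of [windowed_pi()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_windowed_pi_tsv <- function(pi_table, path) {
  lines <- c("# coordinates=0-based half-open (BED convention)",
             paste(c("chrom", "start", "end", "pi"), collapse = "\t"),
             paste(pi_table$chrom, pi_table$start, pi_table$end,
                   fmt_num(pi_table$pi), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an Ne trajectory as TSV
#'
#' All numeric trajectory columns are preserved; calibration metadata
#' (generation time, sampling year, trims) travels in `# key=value` lines.
#'
#' @param traj An `ne_trajectory` or calibrated trajectory.
#' @param path File path.
#' @return `write_trajectory_tsv` returns `path` invisibly;
#'   `read_trajectory_tsv` returns the trajectory data frame.
#' @export
write_trajectory_tsv <- function(traj, path) {
  cols <- names(traj)
  lines <- "# units=generations (t_gen) and years before sampling where present"
  for (key in c("generation_time_years", "sampling_year", "trim_recent",
                "max_generations", "n_haplotypes", "n_boot")) {
    if (!is.null(attr(traj, key))) {
      lines <- c(lines, paste0("# ", key, "=", attr(traj, key)))
    }
  }
  body <- do.call(paste, c(lapply(cols, function(cn) {
    v <- traj[[cn]]
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }), sep = "\t"))
  writeLines(c(lines, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- read_tsv_checked(path, c("c", "t_gen", "ne"))
  meta <- attr(df, "meta")
  for (cn in names(df)) {
    v <- df[[cn]]
    if (all(v %in% c("TRUE", "FALSE"))) {
      df[[cn]] <- as.logical(v)
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (!any(is.na(num) & v != "NA")) df[[cn]] <- num
    }
  }
  for (key in c("generation_time_years", "sampling_year", "trim_recent",
                "max_generations", "n_haplotypes", "n_boot")) {
    v <- meta_value(meta, key)
    if (!is.null(v)) attr(df, key) <- as.numeric(v)
  }
  class(df) <- c("ne_trajectory", "data.frame")
  df
}
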