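#' The read-depth downsampling grid
#'
#' 500 to 10,000 reads in steps of 500, then 20,000 to 100,000 in steps of
#' 10,000 — 29 strictly increasing genome-wide read totals.
#'
#' @return Integer vector of length 29.
#' @export
downsampling_grid <- function() {
  c(seq(500L, 10000L, by = 500L), seq(20000L, 100000L, by = 10000L))
}

#' Downsampling/bootstrap sensitivity protocol for one assignment test
#'
#' For every grid depth, individual and bootstrap replicate, downsamples the
#' individual's observations to the depth (with a seed derived from the
#' master seed and the triple), scores against the panel, applies the binary
#' classifier, and records whether the call matches the individual's known
#' label.  A `no_call` (no informative observation survived) counts as
#' incorrect.  Fully reproducible given `(inputs, seed)`.
#'
#' @param individuals List of `list(obs = read_obs, truth = label)` entries;
#'   every truth must be one of the panel's groups and every observation set
#'   must have at least `min(grid)` total reads.
#' @param panel A [snp_panel].
#' @param grid Read-depth grid (default [downsampling_grid()]), strictly
#'   increasing.
#' @param n_boot Bootstrap replicates per depth and individual (default 20).
#' @param seed Master seed.
#' @return A `sensitivity_curve`: long data frame (`depth`, `individual`,
#'   `replicate`, `correct`) with the grid, `n_boot` and truth labels as
#'   attributes.
#' @export
run_sensitivity <- function(individuals, panel, grid = downsampling_grid(),
                            n_boot = 20, seed = 1) {
  stopifnot(inherits(panel, "snp_panel"), n_boot >= 1,
            length(grid) >= 1, all(diff(grid) > 0))
  truths <- vapply(individuals, function(x) x$truth, character(1))
  if (!all(truths %in% panel$groups)) {
    stop_input("truth labels must be among the panel's groups")
  }
  totals <- vapply(individuals, function(x) x$obs$total_read_count, numeric(1))
  if (any(totals < min(grid))) {
    stop_input("every individual needs at least min(grid) total reads")
  }
  rows <- vector("list", length(grid) * length(individuals))
  k <- 0
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    for (i in seq_along(individuals)) {
      correct <- logical(n_boot)
      for (b in seq_len(n_boot)) {
        ds <- downsample_reads(individuals[[i]]$obs, g, derive_seed(seed, g, i, b))
        res <- classify(score_assignment(ds, panel))
        correct[b] <- identical(call_label(res, panel), truths[i])
      }
      k <- k + 1
      rows[[k]] <- data.frame(depth = g, individual = i,
                              replicate = seq_len(n_boot), correct = correct)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "n_boot") <- n_boot
  attr(out, "truth") <- truths
  attr(out, "contrast") <- panel$contrast
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Minimum read depth for perfect classification
#'
#' The smallest grid depth at which every individual's bootstrap replicates
#' are all correct *and* every larger grid depth also satisfies this
#' (stability requirement — the minimum is used as a gate for real
#' specimens, so a depth that fails again further up the grid would be an
#' unsafe gate).
#'
#' @param curve A `sensitivity_curve` from [run_sensitivity()].
#' @return The grid depth (integer), or `NA` if never satisfied.
#' @export
minimum_read_depth <- function(curve) {
  stopifnot(inherits(curve, "sensitivity_curve"), nrow(curve) > 0)
  grid <- attr(curve, "grid")
  all_correct <- vapply(grid, function(g) all(curve$correct[curve$depth == g]),
                        logical(1))
  stable <- rev(cumprod(rev(all_correct))) > 0
  if (!any(stable)) return(NA_integer_)
  as.integer(grid[which(stable)[1]])
}

#' Per-depth correctness summary of a sensitivity curve
#'
#' @param object A `sensitivity_curve`.
#' @param ... Unused.
#' @return Data frame with `depth`, `n`, `n_correct`, `rate` and
#'   `all_correct`.
#' @export
summary.sensitivity_curve <- function(object, ...) {
  grid <- attr(object, "grid")
  out <- do.call(rbind, lapply(grid, function(g) {
    ok <- object$correct[object$depth == g]
    data.frame(depth = g, n = length(ok), n_correct = sum(ok),
               rate = mean(ok), all_correct = all(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Plot assignment correctness against read depth
#'
#' @param x A `sensitivity_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sensitivity_curve <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$depth, s$rate, type = "b", log = "x",
                 xlab = "total reads (genome-wide)",
                 ylab = "fraction of replicates correct",
                 ylim = c(0, 1),
                 main = attr(x, "contrast"), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
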