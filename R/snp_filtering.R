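#' Filter configuration for SNP calling and retention
#'
#' Bundles the thresholds used by [call_snps()], [coverage_bounds()],
#' [apply_coverage_filter()] and [apply_control_filter()].  All bound
#' comparisons are strict: a cell is dropped when depth is *less than*
#' `min_cov` or *greater than* the upper bound, and a control-pool
#' frequency is dropped when *less than* `control_low` or *greater than*
#' `control_high`, so boundary values always survive.
#'
#' @param min_call_depth minimum summed depth (across pools) for a SNP to
#'   be called (default 10).
#' @param min_call_maf minimum minor-allele frequency over pooled counts
#'   for a SNP to be called (default 0.25).
#' @param min_cov per-pool minimum depth for an allele-frequency estimate
#'   (default 20).
#' @param max_cov_k upper per-pool depth bound is mean + `max_cov_k` * SD
#'   of depth over all (SNP, pool) cells (default 1).
#' @param control_low,control_high retained range of the control-pool
#'   reference-allele frequency (defaults 0.25 and 0.75).
#' @param control_pool name of the control pool (default `"control"`).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_call_depth = 10L, min_call_maf = 0.25,
                          min_cov = 20L, max_cov_k = 1,
                          control_low = 0.25, control_high = 0.75,
                          control_pool = "control") {
  stopifnot(min_call_depth >= 0, min_call_maf >= 0, min_call_maf <= 0.5,
            min_cov >= 0, max_cov_k >= 0,
            control_low >= 0, control_low < control_high, control_high <= 1)
  structure(list(min_call_depth = as.integer(min_call_depth),
                 min_call_maf = min_call_maf,
                 min_cov = as.integer(min_cov), max_cov_k = max_cov_k,
                 control_low = control_low, control_high = control_high,
                 control_pool = control_pool),
            class = "filter_config")
}

#' Call SNPs from pooled counts
#'
#' A site is called a SNP when its depth summed across all pools is at
#' least `min_call_depth` and the minor-allele frequency of the pooled
#' counts is at least `min_call_maf`.  This mirrors variant discovery on
#' a merged pileup of all pools.
#'
#' @param table a [pool_counts] table.
#' @param config a [filter_config].
#' @return data.frame with columns `chrom`, `pos` of the called SNPs.
#' @export
call_snps <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "pool_counts"))
  pl <- pools(table)
  ref <- Reduce(`+`, lapply(paste0(pl, "_ref"), function(cn) table[[cn]]))
  tot <- Reduce(`+`, lapply(paste0(pl, "_tot"), function(cn) table[[cn]]))
  if (is.null(ref)) ref <- integer(0)
  f <- ifelse(tot > 0, ref / tot, NA_real_)
  maf <- pmin(f, 1 - f)
  keep <- tot >= config$min_call_depth & !is.na(maf) &
    maf >= config$min_call_maf
  out <- table[which(keep), c("chrom", "pos"), drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Per-pool allele-frequency estimates
#'
#' Plug-in frequencies `ref_count / total_count` per (SNP, pool) cell,
#' with depth carried through.  Cells with zero depth are missing.
#'
#' @param table a [pool_counts] table.
#' @return a `pool_freqs` data.frame with columns `chrom`, `pos` and, per
#'   pool, `<pool>_freq` and `<pool>_depth`; `NA` marks missing cells.
#' @export
estimate_freqs <- function(table) {
  stopifnot(inherits(table, "pool_counts"))
  out <- table[, c("chrom", "pos"), drop = FALSE]
  for (p in pools(table)) {
    tot <- table[[paste0(p, "_tot")]]
    out[[paste0(p, "_freq")]] <-
      ifelse(tot > 0L, table[[paste0(p, "_ref")]] / tot, NA_real_)
    out[[paste0(p, "_depth")]] <- tot
  }
  structure(as.data.frame(out), pools = pools(table),
            class = c("pool_freqs", "data.frame"))
}

#' Coverage bounds for the per-pool depth filter
#'
#' The lower bound is `config$min_cov`; the upper bound is the mean plus
#' `config$max_cov_k` standard deviations (sample SD, n - 1 denominator)
#' of depth, computed jointly over every (SNP, pool) cell.
#'
#' @param table a [pool_counts] table.
#' @param config a [filter_config].
#' @return list with elements `min_cov` and `max_cov`.
#' @export
coverage_bounds <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "pool_counts"))
  if (nrow(table) == 0L) stop("cannot compute coverage bounds: empty table")
  depths <- unlist(lapply(paste0(pools(table), "_tot"),
                          function(cn) table[[cn]]), use.names = FALSE)
  if (all(is.na(depths))) stop("cannot compute coverage bounds: no depths")
  s <- if (length(depths) > 1L) sd(depths) else 0
  list(min_cov = config$min_cov,
       max_cov = mean(depths) + config$max_cov_k * s)
}

#' Mask allele-frequency cells outside the coverage bounds
#'
#' Cells with depth strictly below `min_cov` or strictly above `max_cov`
#' become missing (both frequency and depth set to `NA`).  Masking is per
#' (SNP, pool) cell; other pools at the same SNP are untouched.
#'
#' @param freqs a `pool_freqs` table from [estimate_freqs()].
#' @param min_cov,max_cov the bounds, e.g. from [coverage_bounds()].
#' @return the filtered `pool_freqs` table.
#' @export
apply_coverage_filter <- function(freqs, min_cov, max_cov) {
  stopifnot(inherits(freqs, "pool_freqs"),
            is.finite(min_cov), is.finite(max_cov), min_cov <= max_cov)
  for (p in pools(freqs)) {
    dcol <- paste0(p, "_depth"); fcol <- paste0(p, "_freq")
    d <- freqs[[dcol]]
    drop <- !is.na(d) & (d < min_cov | d > max_cov)
    freqs[[fcol]][drop] <- NA_real_
    freqs[[dcol]][drop] <- NA_integer_
  }
  freqs
}

#' Discard SNPs by control-pool frequency
#'
#' Rows whose control-pool reference-allele frequency is missing, strictly
#' below `control_low`, or strictly above `control_high` are removed
#' entirely (all pools).  A control pool near 0.5 indicates a well-behaved
#' marker segregating freely in the unselected population; extreme control
#' frequencies flag mapping or paralogy artifacts.
#'
#' @param freqs a `pool_freqs` table.
#' @param config a [filter_config] naming the control pool.
#' @return the filtered `pool_freqs` table.
#' @export
apply_control_filter <- function(freqs, config = filter_config()) {
  stopifnot(inherits(freqs, "pool_freqs"))
  cp <- config$control_pool
  fcol <- paste0(cp, "_freq")
  if (!fcol %in% names(freqs))
    stop("control pool '", cp, "' not present in frequency table")
  f <- freqs[[fcol]]
  keep <- !is.na(f) & f >= config$control_low & f <= config$control_high
  out <- freqs[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, pools = pools(freqs),
            class = c("pool_freqs", "data.frame"))
}

#' Full filtering stage with a removal report
#'
#' Convenience wrapper: estimates frequencies, applies the coverage filter
#' with bounds from [coverage_bounds()], then the control filter, and
#' reports how many cells/rows each rule removed.
#'
#' @param table a [pool_counts] table.
#' @param config a [filter_config].
#' @return list with `freqs` (the filtered `pool_freqs` table), `bounds`,
#'   and `report` (a data.frame of per-rule removal counts).
#' @export
filter_counts <- function(table, config = filter_config()) {
  freqs <- estimate_freqs(table)
  b <- coverage_bounds(table, config)
  n_cells <- function(fr) sum(!is.na(as.matrix(
    fr[, paste0(pools(fr), "_freq"), drop = FALSE])))
  c0 <- n_cells(freqs)
  freqs_cov <- apply_coverage_filter(freqs, b$min_cov, b$max_cov)
  c1 <- n_cells(freqs_cov)
  out <- apply_control_filter(freqs_cov, config)
  report <- data.frame(
    rule = c("input_snps", "cells_masked_coverage",
             "rows_removed_control", "retained_snps"),
    value = c(nrow(table), c0 - c1, nrow(freqs_cov) - nrow(out), nrow(out)))
  list(freqs = out, bounds = b, report = report)
}
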