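#' Assemble an end-to-end run configuration
#'
#' @param counts path to a counts file (canonical TSV) or a [pool_counts]
#'   table.
#' @param out_dir output directory (created if absent).
#' @param filter a [filter_config()].
#' @param scan a [scan_config()].
#' @param quantile outlier fraction for [outlier_threshold()] (default
#'   0.005).
#' @param flank_snps,merge_bp region-calling parameters (defaults 7 and
#'   5e6); see [call_regions()].
#' @param seed seed echoed into provenance headers (the scan itself is
#'   deterministic given its inputs).
#' @return a `run_config` list.
#' @export
run_config <- function(counts, out_dir, filter = filter_config(),
                       scan = scan_config(), quantile = 0.005,
                       flank_snps = 7L, merge_bp = 5e6, seed = 1L) {
  stopifnot(inherits(filter, "filter_config"),
            inherits(scan, "scan_config"),
            quantile >= 0, quantile < 1)
  structure(list(counts = counts, out_dir = out_dir, filter = filter,
                 scan = scan, quantile = quantile,
                 flank_snps = as.integer(flank_snps),
                 merge_bp = merge_bp, seed = as.integer(seed)),
            class = "run_config")
}

# internal: deterministic provenance header lines for output files
provenance <- function(config) {
  fc <- config$filter; sc <- config$scan
  c(paste0("bsascan ", as.character(utils::packageVersion("bsascan"))),
    paste0("filter: min_call_depth=", fc$min_call_depth,
           " min_call_maf=", fc$min_call_maf,
           " min_cov=", fc$min_cov, " max_cov_k=", fc$max_cov_k,
           " control=[", fc$control_low, ",", fc$control_high,
           "] control_pool=", fc$control_pool),
    paste0("scan: d=", sc$d, " top=", sc$top_pool,
           " bottom=", sc$bottom_pool,
           " scale_window=", sc$scale_window),
    paste0("regions: quantile=", config$quantile,
           " flank_snps=", config$flank_snps,
           " merge_bp=", format(config$merge_bp, scientific = FALSE)),
    paste0("seed: ", config$seed))
}

#' Run the full scan pipeline on a counts table
#'
#' Executes filtering (coverage bounds, coverage mask, control-pool
#' filter), the sliding-window Z scan, empirical outlier thresholding and
#' region calling, and writes `scan.tsv`, `regions.tsv`, `regions.bed`
#' and `filter_report.tsv` into `config$out_dir`, each with a provenance
#' header.  Identical configuration and inputs produce byte-identical
#' outputs.  Configuration errors (missing pools) are raised before any
#' computation; on a stage failure, partial outputs are removed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `scan`, `regions`, `threshold`,
#'   `report`, `bounds`, and the output `paths`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- if (inherits(config$counts, "pool_counts")) config$counts
            else read_counts(config$counts, format = "tsv")
  # fail fast before any stage computes
  need <- unique(c(config$scan$top_pool, config$scan$bottom_pool,
                   config$filter$control_pool))
  absent <- setdiff(need, pools(counts))
  if (length(absent))
    stop("configuration error: pool(s) not in counts table: ",
         paste(absent, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(scan = "scan.tsv", regions = "regions.tsv",
                       bed = "regions.bed", report = "filter_report.tsv"))
  names(paths) <- c("scan", "regions", "bed", "report")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))

  hdr <- provenance(config)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  filt <- stage("filter", filter_counts(counts, config$filter))
  scan <- stage("scan", window_scan(filt$freqs, counts, config$scan))
  thr <- stage("threshold",
               outlier_threshold(scan$neglogp, q = config$quantile))
  regions <- stage("call-regions",
                   call_regions(scan, thr, flank_snps = config$flank_snps,
                                merge_bp = config$merge_bp))

  write_scan(scan, paths["scan"], header = hdr)
  write_regions(regions, tsv = paths["regions"], bed = paths["bed"],
                header = c(hdr, paste0("threshold: ", thr)))
  con <- file(paths["report"], "w")
  writeLines(paste0("# ", hdr), con)
  write.table(filt$report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ok <- TRUE
  message("scan: ", nrow(counts), " input SNPs, ", nrow(filt$freqs),
          " retained, ", nrow(scan), " scanned, threshold ",
          signif(thr, 4), ", ", nrow(regions), " region(s)")
  invisible(list(scan = scan, regions = regions, threshold = thr,
                 report = filt$report, bounds = filt$bounds, paths = paths))
}

# internal: read an interval file (regions TSV with header, or BED)
read_intervals <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    df <- read.table(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    data.frame(chrom = as.character(df[[1L]]),
               left = as.integer(df[[2L]]) + 1L,  # 0-based half-open -> 1-based
               right = as.integer(df[[3L]]),
               stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
    if (!all(c("chrom", "left", "right") %in% names(df)))
      stop("interval file '", path,
           "' must have chrom/left/right columns (or be a .bed file)")
    df[, c("chrom", "left", "right")]
  }
}

#' Compare two interval files and write an overlap report
#'
#' Reads a called-region TSV (or BED) and a second interval file (e.g.
#' 1.5-LOD linkage-mapping support intervals), runs
#' [compare_region_sets()], and writes the report as TSV.  BED input is
#' converted from 0-based half-open to the internal 1-based inclusive
#' coordinates.
#'
#' @param regions_a path to the scan's region file.
#' @param intervals_b path to the comparison interval file.
#' @param out output TSV path.
#' @return invisibly, the overlap report data.frame.
#' @export
run_compare <- function(regions_a, intervals_b, out) {
  a <- read_intervals(regions_a)
  b <- read_intervals(intervals_b)
  report <- compare_region_sets(a, b)
  write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Simulate an experiment and write its artifacts
#'
#' Runs [simulate_bsa()] and writes the canonical counts TSV, a truth TSV
#' (planted QTL and per-pool true frequencies) and a phenotype TSV.
#'
#' @param out_dir output directory.
#' @param map a [sim_genome_map()] map.
#' @param qtls planted QTL data.frame or `NULL`.
#' @param config a [sim_config()].
#' @return invisibly, the [simulate_bsa()] result with a `paths` element.
#' @export
run_simulate <- function(out_dir, map = sim_genome_map(), qtls = NULL,
                         config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_bsa(map, qtls, config)
  paths <- file.path(out_dir, c(counts = "counts.tsv", truth = "truth.tsv",
                                qtls = "qtls.tsv",
                                phenotypes = "phenotypes.tsv"))
  names(paths) <- c("counts", "truth", "qtls", "phenotypes")
  write_counts(sim$counts, paths["counts"])
  write.table(sim$truth$true_freqs, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(qtls))
    write.table(qtls, paths["qtls"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  write.table(data.frame(individual = seq_along(sim$phenotypes),
                         phenotype = as.numeric(sim$phenotypes)),
              paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sim$paths <- paths
  invisible(sim)
}
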