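#' Empirical outlier threshold
#'
#' The (1 - q) empirical quantile of the -log10(p) values by the
#' nearest-rank rule: the value at rank `ceiling((1 - q) * N)` of the
#' sorted vector.  SNPs strictly above the returned value are declared
#' significant.  An empirical outlier quantile is used in place of formal
#' multiple-testing correction because the linkage disequilibrium among
#' windowed SNPs is unknown, making permutation thresholds infeasible and
#' Bonferroni/FDR mis-calibrated.
#'
#' @param neglogp numeric vector of -log10(p) values (finite; `NA`s are
#'   dropped).
#' @param q outlier fraction (default 0.005, i.e. the 99.5th percentile).
#' @return the threshold value.
#' @examples
#' outlier_threshold(0:999)      # 994
#' @export
outlier_threshold <- function(neglogp, q = 0.005) {
  neglogp <- neglogp[!is.na(neglogp)]
  if (length(neglogp) == 0L) stop("no finite -log10(p) values")
  if (!all(is.finite(neglogp))) stop("-log10(p) values must be finite")
  stopifnot(q >= 0, q < 1)
  s <- sort(neglogp)
  rank <- max(1L, ceiling((1 - q) * length(s)))
  s[rank]
}

#' Call QTL regions from a windowed scan
#'
#' Per chromosome: (1) maximal runs of SNPs with `neglogp` strictly above
#' the threshold are found; (2) each run is extended by `flank_snps` scan
#' SNPs up- and downstream (clipped at the chromosome's first/last scan
#' SNP) — the flanking SNPs supported the estimate of the last significant
#' SNP through the window; (3) scanning left to right, a region is merged
#' into its predecessor when the gap between its left boundary SNP and the
#' predecessor's right boundary SNP is below `merge_bp`, iterating until
#' stable; (4) the peak is the SNP with maximum `neglogp` (leftmost on
#' ties) and the direction is the sign of the windowed frequency
#' difference at the peak (`+` means the reference-parent allele is
#' elevated in the top pool).
#'
#' @param scan a `bsa_scan` data.frame from [window_scan()].
#' @param threshold significance threshold on `neglogp`, e.g. from
#'   [outlier_threshold()].
#' @param flank_snps number of scan SNPs added to each side of a
#'   significant run (default 7).
#' @param merge_bp minimum non-significant gap, in bp between boundary SNP
#'   positions, required to keep two regions separate (default 5e6).
#' @return a `region_set` data.frame with columns `chrom`, `left`,
#'   `right`, `peak_pos`, `peak_p`, `neglogp`, `length_kb`, `direction`,
#'   `n_snps`; attribute `threshold` records the threshold used.
#' @export
call_regions <- function(scan, threshold, flank_snps = 7L,
                         merge_bp = 5e6) {
  stopifnot(is.data.frame(scan),
            all(c("chrom", "pos", "neglogp", "wdiff") %in% names(scan)),
            is.finite(threshold), flank_snps >= 0L, merge_bp >= 0)
  regions <- list()
  for (chr in unique(scan$chrom)) {
    s <- scan[scan$chrom == chr, , drop = FALSE]
    sig <- !is.na(s$neglogp) & s$neglogp > threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # extend by flank_snps scan SNPs, clipped at the chromosome ends
    runs$start <- pmax(1L, runs$start - flank_snps)
    runs$end <- pmin(nrow(s), runs$end + flank_snps)
    # merge left to right until stable
    repeat {
      merged <- runs[1L, , drop = FALSE]
      for (k in seq_len(nrow(runs))[-1L]) {
        last <- nrow(merged)
        gap <- s$pos[runs$start[k]] - s$pos[merged$end[last]]
        if (gap < merge_bp) {
          merged$end[last] <- max(merged$end[last], runs$end[k])
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
      if (nrow(merged) == nrow(runs)) { runs <- merged; break }
      runs <- merged
    }
    for (k in seq_len(nrow(runs))) {
      i <- runs$start[k]:runs$end[k]
      nlp <- s$neglogp[i]
      peak <- i[which.max(ifelse(is.na(nlp), -Inf, nlp))]
      wd <- s$wdiff[peak]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chr,
        left = s$pos[runs$start[k]],
        right = s$pos[runs$end[k]],
        peak_pos = s$pos[peak],
        peak_p = s$p[peak],
        neglogp = s$neglogp[peak],
        length_kb = as.integer(round_half_up((s$pos[runs$end[k]] -
                                                s$pos[runs$start[k]]) / 1000)),
        direction = if (is.na(wd)) NA_character_
                    else if (wd >= 0) "+" else "-",
        n_snps = length(i),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), left = integer(), right = integer(),
               peak_pos = integer(), peak_p = numeric(), neglogp = numeric(),
               length_kb = integer(), direction = character(),
               n_snps = integer(), stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chrom), out$left), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("region_set", "data.frame"))
}

#' Summarize called regions in publication-table style
#'
#' One row per region: chromosome, left and right boundary positions,
#' most significant position, interval length in kb (rounded half away
#' from zero to the nearest integer), peak p-value, and the direction of
#' the allele-frequency shift.
#'
#' @param regions a `region_set` or a data.frame with at least `chrom`,
#'   `left`, `right`; `peak_pos`, `peak_p`, `direction` are carried when
#'   present.
#' @return a data.frame with columns `chrom`, `left`, `right`,
#'   `peak_pos`, `length_kb`, `peak_p`, `direction`.
#' @export
summarize_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "left", "right") %in% names(regions)))
  n <- nrow(regions)
  data.frame(
    chrom = regions$chrom,
    left = regions$left,
    right = regions$right,
    peak_pos = if ("peak_pos" %in% names(regions)) regions$peak_pos
               else rep(NA_integer_, n),
    length_kb = as.integer(round_half_up((regions$right - regions$left) / 1000)),
    peak_p = if ("peak_p" %in% names(regions)) regions$peak_p
             else rep(NA_real_, n),
    direction = if ("direction" %in% names(regions)) regions$direction
                else rep(NA_character_, n),
    stringsAsFactors = FALSE)
}

#' Overlap report between two interval sets
#'
#' Compares every region in `a` against every interval in `b` on the same
#' chromosome and classifies the relationship.  The typical use is
#' checking whether 1.5-LOD support intervals from linkage mapping fall
#' within regions called by the pooled-sequencing scan; both inputs must
#' use the same (1-based, inclusive) coordinate system.
#'
#' @param a data.frame with columns `chrom`, `left`, `right` (the scan's
#'   regions).
#' @param b data.frame with columns `chrom`, `left`, `right` (e.g.
#'   linkage-mapping intervals).
#' @return data.frame with one row per same-chromosome pair: the two
#'   intervals, `relationship` (`disjoint`, `partial-overlap`,
#'   `a-contains-b`, `b-contains-a`), `overlap_bp`, and logical `shared`.
#' @export
compare_region_sets <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("chrom", "left", "right") %in% names(a)),
            all(c("chrom", "left", "right") %in% names(b)))
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    al <- a$left[i]; ar <- a$right[i]; bl <- b$left[j]; br <- b$right[j]
    ov <- max(0, min(ar, br) - max(al, bl))
    rel <- if (ov <= 0 && !(bl >= al && br <= ar) && !(al >= bl && ar <= br))
      "disjoint"
    else if (bl >= al && br <= ar) "a-contains-b"
    else if (al >= bl && ar <= br) "b-contains-a"
    else "partial-overlap"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = a$chrom[i], a_left = al, a_right = ar,
      b_left = bl, b_right = br, relationship = rel,
      overlap_bp = ov, shared = ov > 0, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), a_left = integer(), a_right = integer(),
               b_left = integer(), b_right = integer(),
               relationship = character(), overlap_bp = numeric(),
               shared = logical(), stringsAsFactors = FALSE)
}

#' Recovery metrics against simulated truth
#'
#' Evaluates a called region set against the QTL planted by the
#' simulator.  A QTL is recovered when some region, widened by `slack_bp`
#' on each side, contains its position; a region is false when it
#' contains no planted QTL within the same slack.
#'
#' @param called a `region_set` (or data.frame with `chrom`, `left`,
#'   `right`, `peak_pos`).
#' @param truth a data.frame of planted QTL with columns `chrom`, `pos`
#'   (e.g. the `qtls` element of a [simulate_bsa()] truth).
#' @param slack_bp slack added to both region boundaries (default 0).
#' @return list with `sensitivity` (recovered / planted), `false_regions`
#'   (count), and `peak_offset_bp` (absolute peak-to-QTL distance for each
#'   recovered QTL).
#' @export
recovery_metrics <- function(called, truth, slack_bp = 0) {
  stopifnot(is.data.frame(called), is.data.frame(truth),
            all(c("chrom", "pos") %in% names(truth)))
  n_qtl <- nrow(truth)
  if (n_qtl == 0L)
    return(list(sensitivity = NA_real_, false_regions = nrow(called),
                peak_offset_bp = numeric(0)))
  recovered <- logical(n_qtl)
  offsets <- rep(NA_real_, n_qtl)
  region_hit <- logical(nrow(called))
  for (q in seq_len(n_qtl)) {
    hit <- which(called$chrom == truth$chrom[q] &
                   called$left - slack_bp <= truth$pos[q] &
                   called$right + slack_bp >= truth$pos[q])
    if (length(hit)) {
      recovered[q] <- TRUE
      region_hit[hit] <- TRUE
      pk <- if ("peak_pos" %in% names(called)) called$peak_pos[hit]
            else (called$left[hit] + called$right[hit]) / 2
      offsets[q] <- min(abs(pk - truth$pos[q]))
    }
  }
  list(sensitivity = mean(recovered),
       false_regions = sum(!region_hit),
       peak_offset_bp = offsets[recovered])
}

#' Write a region set as BED and/or TSV
#'
#' The TSV mirrors the publication-table summary (1-based inclusive
#' coordinates); the BED file converts to 0-based half-open intervals.
#'
#' @param regions a `region_set`.
#' @param tsv,bed output paths (either may be `NULL` to skip).
#' @param header optional provenance lines for the TSV (prefixed `# `).
#' @return invisibly, the paths written.
#' @export
write_regions <- function(regions, tsv = NULL, bed = NULL, header = NULL) {
  stopifnot(is.data.frame(regions))
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(summarize_regions(regions), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  if (!is.null(bed) && nrow(regions) > 0) {
    bed_df <- data.frame(chrom = regions$chrom,
                         start = regions$left - 1L,
                         end = regions$right,
                         name = sprintf("region_%d", seq_len(nrow(regions))))
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (!is.null(bed)) {
    file.create(bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}
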