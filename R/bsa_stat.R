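#' Scan configuration for the windowed Z statistic
#'
#' @param d window size in SNPs; odd integer (default 15, i.e. the focal
#'   SNP plus 7 neighbors on each side).
#' @param top_pool,bottom_pool names of the two contrasted tail pools
#'   (e.g. early/late or tall/short).  The statistic is signed top minus
#'   bottom.
#' @param scale_window if `TRUE`, the window mean is rescaled by
#'   `sqrt(d)` before the normal comparison so it is standard normal under
#'   independence.  Off by default: the unscaled mean compared to N(0,1)
#'   is deliberately conservative, trading power for robustness to the
#'   unknown linkage disequilibrium among neighboring SNPs.
#' @return a `scan_config` list.
#' @export
scan_config <- function(d = 15L, top_pool = "high", bottom_pool = "low",
                        scale_window = FALSE) {
  d <- as.integer(d)
  stopifnot(d >= 1L, d %% 2L == 1L, top_pool != bottom_pool)
  structure(list(d = d, top_pool = top_pool, bottom_pool = bottom_pool,
                 scale_window = isTRUE(scale_window)),
            class = "scan_config")
}

#' Per-SNP two-pool Z statistic
#'
#' Standardized difference in pooled reference-allele frequency between
#' two pools at one SNP:
#' \deqn{z = \frac{p_{top} - p_{bottom}}
#'   {\sqrt{\hat p (1-\hat p)\left(\frac{1}{n_{top}} +
#'    \frac{1}{n_{bottom}}\right)}}}
#' with the pooled estimate
#' \eqn{\hat p = (x_{top}+x_{bottom})/(n_{top}+n_{bottom})}.
#'
#' Vectorized over SNPs.  Returns 0 when the two frequencies are equal,
#' and `NA` when either pool has zero depth or the pooled frequency is 0
#' or 1 (monomorphic across both pools: the standard error is undefined).
#'
#' @param x_top,n_top reference-allele and total read counts in the top pool.
#' @param x_bottom,n_bottom the same for the bottom pool.
#' @return numeric vector of z values.
#' @examples
#' per_snp_z(30, 40, 10, 40)  # ~ 4.47
#' @export
per_snp_z <- function(x_top, n_top, x_bottom, n_bottom) {
  stopifnot(all(x_top <= n_top, na.rm = TRUE),
            all(x_bottom <= n_bottom, na.rm = TRUE),
            all(x_top >= 0, na.rm = TRUE), all(x_bottom >= 0, na.rm = TRUE))
  ok <- !is.na(n_top) & !is.na(n_bottom) & n_top > 0 & n_bottom > 0
  p_top <- ifelse(ok, x_top / n_top, NA_real_)
  p_bot <- ifelse(ok, x_bottom / n_bottom, NA_real_)
  phat <- ifelse(ok, (x_top + x_bottom) / (n_top + n_bottom), NA_real_)
  se <- sqrt(phat * (1 - phat) * (1 / n_top + 1 / n_bottom))
  num <- p_top - p_bot
  ifelse(!ok | phat <= 0 | phat >= 1, NA_real_,
         ifelse(num == 0, 0, num / se))
}

#' Sliding-window Z scan over a genome
#'
#' Computes the per-SNP Z statistic between the top and bottom pools and
#' averages it over a centered window of `d` consecutive scan SNPs within
#' each chromosome.  Only SNPs non-missing in *both* pools (and not
#' monomorphic across them) participate; missing SNPs are removed from
#' the sequence before windowing, so windows always contain `d`
#' participating SNPs.  The window mean is compared (unscaled, unless
#' `scale_window`) to the standard normal for a two-sided p-value, and
#' the window mean of the raw frequency difference is reported alongside
#' as the direction profile.
#'
#' @param freqs a `pool_freqs` table (post-filtering) from
#'   [estimate_freqs()] and the filter functions.
#' @param counts the [pool_counts] table the frequencies came from
#'   (supplies the read counts for the pooled standard error).
#' @param config a [scan_config].
#' @return a `bsa_scan` data.frame with columns `chrom`, `pos`, `z`,
#'   `zprime` (`NA` within `floor(d/2)` SNPs of a chromosome edge), `p`,
#'   `neglogp`, `wdiff`; one row per participating SNP.
#' @export
window_scan <- function(freqs, counts, config = scan_config()) {
  stopifnot(inherits(freqs, "pool_freqs"), inherits(counts, "pool_counts"))
  tp <- config$top_pool; bp <- config$bottom_pool
  for (p in c(tp, bp)) {
    if (!paste0(p, "_freq") %in% names(freqs))
      stop("pool '", p, "' not present in frequency table")
    if (!paste0(p, "_ref") %in% names(counts))
      stop("pool '", p, "' not present in count table")
  }
  key_f <- paste(freqs$chrom, freqs$pos)
  key_c <- paste(counts$chrom, counts$pos)
  idx <- match(key_f, key_c)
  if (anyNA(idx))
    stop("frequency table contains SNPs absent from the count table")

  x_top <- counts[[paste0(tp, "_ref")]][idx]
  n_top <- counts[[paste0(tp, "_tot")]][idx]
  x_bot <- counts[[paste0(bp, "_ref")]][idx]
  n_bot <- counts[[paste0(bp, "_tot")]][idx]
  # honor post-filter missingness: a masked cell does not participate
  miss <- is.na(freqs[[paste0(tp, "_freq")]]) |
    is.na(freqs[[paste0(bp, "_freq")]])
  n_top[miss] <- NA_integer_; n_bot[miss] <- NA_integer_

  z <- per_snp_z(x_top, n_top, x_bot, n_bot)
  part <- !is.na(z)
  df <- data.frame(chrom = freqs$chrom[part], pos = freqs$pos[part],
                   z = z[part],
                   fdiff = (x_top / n_top - x_bot / n_bot)[part],
                   stringsAsFactors = FALSE)

  d <- config$d
  halo <- d %/% 2L
  zprime <- rep(NA_real_, nrow(df))
  wdiff <- rep(NA_real_, nrow(df))
  for (chr in unique(df$chrom)) {
    i <- which(df$chrom == chr)
    if (length(i) < d) {
      warning("chromosome '", chr, "' has ", length(i),
              " participating SNPs (< window size ", d,
              "): no windowed statistic assigned")
      next
    }
    zprime[i] <- zoo::rollmean(df$z[i], k = d, fill = NA_real_,
                               align = "center")
    wdiff[i] <- zoo::rollmean(df$fdiff[i], k = d, fill = NA_real_,
                              align = "center")
  }
  if (config$scale_window) zprime <- zprime * sqrt(d)
  p <- 2 * pnorm(-abs(zprime))
  p <- pmax(p, 1e-300)
  df$zprime <- zprime
  df$p <- p
  df$neglogp <- -log10(p)
  df$wdiff <- wdiff
  df$fdiff <- NULL
  # keep missing zprime at edges explicit rather than dropping the rows:
  # edge SNPs still carry a per-SNP z
  structure(df[, c("chrom", "pos", "z", "zprime", "p", "neglogp", "wdiff")],
            pools = c(top = tp, bottom = bp), d = d,
            class = c("bsa_scan", "data.frame"))
}

#' Write a scan result as TSV
#' @param scan a `bsa_scan` data.frame.
#' @param path output path.
#' @param header optional character vector of `# `-prefixed provenance
#'   lines to prepend.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, header = NULL) {
  stopifnot(inherits(scan, "bsa_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
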