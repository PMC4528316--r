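#' Genome-wide scan profile plot
#'
#' Plots -log10(p) of the windowed statistic along the genome, with
#' chromosomes laid out side by side in alternating shades and a dashed
#' line at the outlier threshold — the conventional view of a
#' pooled-sequencing scan.  Requires \pkg{ggplot2}.
#'
#' @param scan a `bsa_scan` data.frame from [window_scan()].
#' @param threshold optional threshold line, e.g. from
#'   [outlier_threshold()].
#' @param what column to plot: `"neglogp"` (default) or `"wdiff"` (the
#'   windowed allele-frequency difference profile).
#' @return a ggplot object.
#' @export
plot_scan <- function(scan, threshold = NULL, what = c("neglogp", "wdiff")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan requires the 'ggplot2' package")
  df <- scan[!is.na(scan[[what]]), , drop = FALSE]
  chroms <- unique(df$chrom)
  offset <- c(0, cumsum(vapply(chroms, function(ch)
    max(df$pos[df$chrom == ch]), numeric(1))))
  names(offset) <- c(chroms, "end")
  df$x <- df$pos + offset[df$chrom]
  df$y <- df[[what]]
  df$shade <- factor(match(df$chrom, chroms) %% 2L)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = shade)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("steelblue", "grey60")) +
    ggplot2::labs(x = "genome position",
                  y = if (what == "neglogp") expression(-log[10](p))
                      else "windowed allele-frequency difference") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && what == "neglogp")
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "darkgreen")
  p
}
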