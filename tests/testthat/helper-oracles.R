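# Independent brute-force oracles and small fixture builders.

# brute-force centered window mean: NA outside full windows
brute_window_mean <- function(x, d) {
  h <- d %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n))
    if (i - h >= 1L && i + h <= n) out[i] <- mean(x[(i - h):(i + h)])
  out
}

# one-line independent evaluation of the two-pool z statistic
oracle_z <- function(x1, n1, x2, n2) {
  phat <- (x1 + x2) / (n1 + n2)
  (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
}

# a small well-formed counts data.frame
toy_counts_df <- function() {
  data.frame(chrom = c("1", "1", "2"), pos = c(100L, 200L, 50L),
             high_ref = c(10L, 0L, 7L), high_tot = c(20L, 15L, 30L),
             low_ref = c(5L, 12L, 22L), low_tot = c(18L, 25L, 30L),
             control_ref = c(11L, 13L, 15L),
             control_tot = c(22L, 26L, 30L),
             stringsAsFactors = FALSE)
}

# random counts table for property tests
random_counts <- function(n_snps, pools = c("high", "low", "control"),
                          depth = 40) {
  df <- data.frame(chrom = as.character(rep(1:2, length.out = n_snps)),
                   pos = rep(seq_len(ceiling(n_snps / 2)) * 1000L,
                             each = 2)[seq_len(n_snps)],
                   stringsAsFactors = FALSE)
  for (p in pools) {
    tot <- rpois(n_snps, depth)
    df[[paste0(p, "_ref")]] <- rbinom(n_snps, tot, runif(n_snps, 0.2, 0.8))
    df[[paste0(p, "_tot")]] <- tot
  }
  pool_counts(df, pools = pools)
}

# a synthetic scan table (for region-caller property tests); positions
# sorted, neglogp and wdiff arbitrary
random_scan <- function(n_snps, n_chrom = 2, spacing = 1e6) {
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), n_snps))
  pos <- unlist(lapply(table(chrom), function(k)
    cumsum(sample.int(spacing, k, replace = TRUE))))
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   z = rnorm(n_snps), stringsAsFactors = FALSE)
  df$zprime <- df$z
  df$p <- 2 * pnorm(-abs(df$zprime))
  df$neglogp <- -log10(df$p)
  df$wdiff <- df$z / 10
  df
}

# path to the bundled region-summary fixture
region_fixture_path <- function() {
  system.file("extdata", "maize_ft_ph_regions.tsv", package = "bsascan",
              mustWork = TRUE)
}
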