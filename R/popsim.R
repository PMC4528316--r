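#' Build a genome map for simulation
#'
#' Defines chromosomes, SNP positions, and genetic positions.  Genetic
#' positions default to a constant cM/Mb rate applied to the physical
#' coordinate; SNPs are evenly spaced unless `spacing = "uniform"`, in
#' which case positions are sorted uniform draws.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_snps total SNP count, apportioned to chromosomes by length.
#' @param cm_per_mb constant recombination rate (default 0.5 cM/Mb, a
#'   typical genome-wide average for a large-genome cereal).
#' @param spacing `"even"` (default, deterministic) or `"uniform"`.
#' @param seed RNG seed used only when `spacing = "uniform"`.
#' @return a `genome_map` data.frame with columns `chrom`, `pos`, `cm`,
#'   and attribute `chrom_lengths`.
#' @export
sim_genome_map <- function(chrom_lengths = c(`1` = 150e6, `2` = 150e6),
                           n_snps = 5000L, cm_per_mb = 0.5,
                           spacing = c("even", "uniform"), seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(length(chrom_lengths) >= 1L, all(chrom_lengths > 0),
            n_snps >= 1L, cm_per_mb > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  per_chrom <- setNames(pmax(1L, round_half_up(n_snps * chrom_lengths /
                                                 sum(chrom_lengths))),
                        names(chrom_lengths))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(chrom_lengths), function(chr) {
    n <- per_chrom[[chr]]
    len <- chrom_lengths[[chr]]
    pos <- switch(spacing,
                  even = round(seq(len / (n + 1), len * n / (n + 1),
                                   length.out = n)),
                  uniform = sort(ceiling(runif(n, 0, len))))
    pos <- as.integer(pmin(pmax(pos, 1), len))
    data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$cm <- map$pos / 1e6 * cm_per_mb
  structure(map, chrom_lengths = chrom_lengths,
            class = c("genome_map", "data.frame"))
}

#' Simulation configuration
#'
#' Defaults emulate the study design this generator exists to validate
#' against: ten thousand individuals from a biparental cross intermated
#' for 14 generations, 46 individuals selected per phenotypic tail plus a
#' 92-plant random control pool, a moderately heritable polygenic trait,
#' and pooled whole-genome sequencing at ~40x mean per-SNP depth.
#'
#' @param pop_size population size N (default 10000).
#' @param generations intermating generations after the F2 (default 14).
#' @param n_selected individuals selected per tail (default 46).
#' @param n_control size of the random control pool (default 92).
#' @param h2 narrow-sense heritability of the simulated trait (default 0.7).
#' @param depth mean sequencing depth per SNP per pool, Poisson (default 40).
#' @param error_rate symmetric allele-flip sequencing error rate
#'   (default 0.001).
#' @param seed master seed; every stochastic stage derives its own child
#'   seed from it, so a full run is exactly reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pop_size = 10000L, generations = 14L,
                       n_selected = 46L, n_control = 92L, h2 = 0.7,
                       depth = 40, error_rate = 0.001, seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 0L,
            2L * n_selected <= pop_size, n_control >= 1L,
            h2 > 0, h2 <= 1, depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 n_selected = as.integer(n_selected),
                 n_control = as.integer(n_control),
                 h2 = h2, depth = depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: one generation of gametes for one chromosome.
# haps: S x (2 * n_parents) matrix of 0/1 reference-allele indicators,
# gametes in columns (parent i owns columns 2i-1, 2i) so each meiosis
# touches contiguous memory.  parent_of: length-n_gametes vector of
# parent indices.  cm: SNP genetic positions.  Haldane model: crossover
# count ~ Poisson(length in Morgans), breakpoints uniform on the cM axis,
# no interference.
meiose_chrom <- function(haps, parent_of, cm) {
  n_g <- length(parent_of)
  s <- length(cm)
  len_m <- (max(cm) - min(cm)) / 100
  n_xo <- rpois(n_g, len_m)
  start <- sample.int(2L, n_g, replace = TRUE) - 1L  # 0 = first haplotype
  out <- matrix(0L, nrow = s, ncol = n_g)
  plain <- n_xo == 0L
  if (any(plain))
    out[, plain] <- haps[, 2L * parent_of[plain] - 1L + start[plain],
                         drop = FALSE]
  lo <- min(cm); hi <- max(cm)
  for (g in which(!plain)) {
    xo <- runif(n_xo[g], lo, hi)
    if (n_xo[g] > 1L) xo <- sort.int(xo, method = "quick")
    use <- (start[g] + findInterval(cm, xo)) %% 2L
    col <- haps[, 2L * parent_of[g] - 1L]
    swap <- use == 1L
    col[swap] <- haps[, 2L * parent_of[g]][swap]
    out[, g] <- col
  }
  out
}

#' Forward simulation of an intermated biparental population
#'
#' Two fully homozygous founders (the reference parent carrying allele 1
#' at every SNP, the alternate parent allele 0) are crossed; the F1 is
#' randomly mated to produce the F2, then `generations` further rounds of
#' random mating follow, with two distinct parents per offspring.
#' Meiosis uses Poisson crossover counts with uniform breakpoint placement
#' on the genetic map (Haldane, no interference).
#'
#' @param map a [sim_genome_map()] map.
#' @param config a [sim_config()].
#' @return a `sim_population`: list with `haps` (an `S x (2N)` integer
#'   matrix of reference-allele indicators; individual i owns columns
#'   `2i-1`, `2i`) and `map`.
#' @export
simulate_population <- function(map, config = sim_config()) {
  stopifnot(inherits(map, "genome_map"))
  if (nrow(map) == 0L) stop("genome map has no SNPs")
  n <- config$pop_size
  set.seed(child_seed(config$seed, 1L))
  chroms <- unique(map$chrom)
  cm_by_chrom <- lapply(chroms, function(ch) map$cm[map$chrom == ch])
  names(cm_by_chrom) <- chroms
  s_total <- nrow(map)
  row_of <- split(seq_len(s_total), factor(map$chrom, levels = chroms))

  # F1: every individual heterozygous with intact parental haplotypes
  haps <- matrix(0L, nrow = s_total, ncol = 2L * n)
  haps[, seq(1L, 2L * n, by = 2L)] <- 1L

  n_rounds <- 1L + config$generations   # F1 -> F2, then intermating
  for (gen in seq_len(n_rounds)) {
    p1 <- sample.int(n, n, replace = TRUE)
    shift <- sample.int(n - 1L, n, replace = TRUE)
    p2 <- 1L + (p1 - 1L + shift) %% n    # distinct from p1
    parent_of <- as.vector(rbind(p1, p2))  # gametes 2i-1, 2i
    nxt <- matrix(0L, nrow = s_total, ncol = 2L * n)
    for (ch in chroms)
      nxt[row_of[[ch]], ] <- meiose_chrom(haps[row_of[[ch]], , drop = FALSE],
                                          parent_of, cm_by_chrom[[ch]])
    haps <- nxt
  }
  structure(list(haps = haps, map = map, n = n),
            class = "sim_population")
}

#' Genotype dosage matrix of a simulated population
#' @param pop a `sim_population`.
#' @return N x S integer matrix of reference-allele copies (0/1/2).
#' @export
genotypes <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  odd <- seq(1L, 2L * pop$n, by = 2L)
  t(pop$haps[, odd, drop = FALSE] + pop$haps[, odd + 1L, drop = FALSE])
}

#' Assign polygenic phenotypes with planted QTL
#'
#' Each QTL contributes `a * (c - 1) + a * k * (c == 1)` to the genetic
#' value, where `c` is the individual's reference-allele dosage at the
#' QTL (snapped to the nearest map SNP), `a` the additive effect and `k`
#' the dominance degree (0 additive, 1 full dominance).  Environmental
#' noise is scaled so the realized heritability matches `h2`.
#'
#' @param pop a `sim_population`.
#' @param qtls data.frame with columns `chrom`, `pos`, `a`, and optional
#'   `k` (default 0).
#' @param h2 target heritability.
#' @param seed RNG seed for the environmental noise.
#' @return numeric phenotype vector with attributes `genetic_value` and
#'   `qtl_snp` (the map row index each QTL snapped to).
#' @export
assign_phenotypes <- function(pop, qtls, h2 = 0.7, seed = 1L) {
  stopifnot(inherits(pop, "sim_population"), h2 > 0, h2 <= 1)
  geno <- genotypes(pop)
  g <- numeric(pop$n)
  qtl_snp <- integer(0)
  if (!is.null(qtls) && nrow(qtls) > 0) {
    if (!"k" %in% names(qtls)) qtls$k <- 0
    qtl_snp <- vapply(seq_len(nrow(qtls)), function(i) {
      on_chr <- which(pop$map$chrom == qtls$chrom[i])
      if (!length(on_chr)) stop("QTL chromosome '", qtls$chrom[i],
                                "' not on the map")
      on_chr[which.min(abs(pop$map$pos[on_chr] - qtls$pos[i]))]
    }, integer(1))
    for (i in seq_along(qtl_snp)) {
      c_i <- geno[, qtl_snp[i]]
      g <- g + qtls$a[i] * (c_i - 1) + qtls$a[i] * qtls$k[i] * (c_i == 1)
    }
  }
  var_g <- var(g)
  if (var_g == 0 && h2 < 1) {
    warning("zero genetic variance; environmental variance set to 1")
    var_e <- 1
  } else {
    var_e <- var_g * (1 - h2) / h2
  }
  set.seed(child_seed(seed, 2L))
  y <- g + rnorm(pop$n, 0, sqrt(var_e))
  structure(y, genetic_value = g, qtl_snp = qtl_snp)
}

#' Truncation selection of phenotypic extremes and a random control
#'
#' @param phenotypes numeric vector.
#' @param config a [sim_config()] (uses `n_selected`, `n_control`, `seed`).
#' @return named list of index vectors `high`, `low`, `control`, with an
#'   attribute `differentials`: the achieved selection differential of
#'   each tail in phenotypic SD units.  Ties at the cutoff are broken by
#'   index; the control pool is drawn uniformly without replacement from
#'   the whole population (it may overlap the tails, as when control
#'   tissue is sampled before phenotyping).
#' @export
select_pools <- function(phenotypes, config = sim_config()) {
  stopifnot(all(is.finite(phenotypes)))
  n <- length(phenotypes)
  if (2L * config$n_selected > n)
    stop("n_selected exceeds half the population")
  ord <- order(phenotypes, seq_len(n))
  low <- sort(ord[seq_len(config$n_selected)])
  high <- sort(ord[seq(n, n - config$n_selected + 1L)])
  set.seed(child_seed(config$seed, 3L))
  control <- sort(sample.int(n, config$n_control))
  s <- sd(phenotypes); m <- mean(phenotypes)
  structure(list(high = high, low = low, control = control),
            differentials = c(high = (mean(phenotypes[high]) - m) / s,
                              low = (mean(phenotypes[low]) - m) / s))
}

#' Pool DNA and simulate pooled sequencing
#'
#' For every SNP and pool, the true pool frequency is the fraction of
#' reference-allele copies among the pool's `2 * n` haplotypes; observed
#' depth is Poisson(`depth`) and the reference read count is binomial at
#' the error-perturbed frequency `f * (1 - e) + (1 - f) * e`.
#'
#' @param pop a `sim_population`.
#' @param pool_idx named list of individual index vectors (e.g. from
#'   [select_pools()]).
#' @param config a [sim_config()].
#' @param qtls optional data.frame of planted QTL, recorded in the truth.
#' @return list with `counts` (a [pool_counts] table) and `truth` (list:
#'   `qtls`, `true_freqs` data.frame of per-pool true frequencies).
#' @export
pool_and_sequence <- function(pop, pool_idx, config = sim_config(),
                              qtls = NULL) {
  stopifnot(inherits(pop, "sim_population"), length(pool_idx) >= 1L)
  if (is.null(names(pool_idx)) || any(!nzchar(names(pool_idx))))
    stop("pools must be named")
  if (any(lengths(pool_idx) == 0L)) stop("empty pool")
  set.seed(child_seed(config$seed, 4L))
  s <- nrow(pop$map)
  df <- pop$map[, c("chrom", "pos")]
  truth <- pop$map[, c("chrom", "pos")]
  e <- config$error_rate
  for (pname in names(pool_idx)) {
    idx <- pool_idx[[pname]]
    cols <- c(rbind(2L * idx - 1L, 2L * idx))
    f <- rowSums(pop$haps[, cols, drop = FALSE]) / (2 * length(idx))
    depth <- rpois(s, config$depth)
    fobs <- f * (1 - e) + (1 - f) * e
    df[[paste0(pname, "_ref")]] <- rbinom(s, depth, fobs)
    df[[paste0(pname, "_tot")]] <- depth
    truth[[paste0(pname, "_freq")]] <- f
  }
  list(counts = pool_counts(df, pools = names(pool_idx)),
       truth = list(qtls = qtls, true_freqs = as.data.frame(truth)))
}

#' One-call simulation of a pooled-sequencing experiment
#'
#' Runs [simulate_population()], [assign_phenotypes()], [select_pools()]
#' and [pool_and_sequence()] with child seeds derived from
#' `config$seed`.
#'
#' @param map a [sim_genome_map()] map.
#' @param qtls data.frame of planted QTL (`chrom`, `pos`, `a`, optional
#'   `k`), or `NULL` for a null simulation.
#' @param config a [sim_config()].
#' @return list with `counts`, `truth` (including achieved selection
#'   differentials), `phenotypes`, and `pools`.
#' @export
simulate_bsa <- function(map = sim_genome_map(), qtls = NULL,
                         config = sim_config()) {
  pop <- simulate_population(map, config)
  phen <- assign_phenotypes(pop, qtls, h2 = config$h2, seed = config$seed)
  pool_idx <- select_pools(as.numeric(phen), config)
  seq_out <- pool_and_sequence(pop, pool_idx, config, qtls = qtls)
  seq_out$truth$differentials <- attr(pool_idx, "differentials")
  list(counts = seq_out$counts, truth = seq_out$truth,
       phenotypes = phen, pools = pool_idx)
}

#' Simulate a null pair of pools sequenced from identical frequencies
#'
#' Both pools' reads are drawn binomially from the *same* per-SNP true
#' frequency, emulating two sequencing runs of one DNA pool.  Useful for
#' calibration checks of the per-SNP Z statistic.
#'
#' @param n_snps number of SNPs (placed on one chromosome at 1 kb spacing).
#' @param depth mean Poisson depth per pool.
#' @param freq_range range of the uniform true-frequency draw
#'   (default `c(0.25, 0.75)`, the control-retained band).
#' @param pool_names names of the two pools.
#' @param seed RNG seed.
#' @return list with `counts` (a [pool_counts] table) and `true_freq`.
#' @export
simulate_null_pools <- function(n_snps = 10000L, depth = 40,
                                freq_range = c(0.25, 0.75),
                                pool_names = c("high", "low"), seed = 1L) {
  stopifnot(n_snps >= 1L, depth > 0, length(pool_names) == 2L)
  set.seed(child_seed(seed, 5L))
  f <- runif(n_snps, freq_range[1L], freq_range[2L])
  df <- data.frame(chrom = "1", pos = seq_len(n_snps) * 1000L,
                   stringsAsFactors = FALSE)
  for (pname in pool_names) {
    dp <- rpois(n_snps, depth)
    df[[paste0(pname, "_ref")]] <- rbinom(n_snps, dp, f)
    df[[paste0(pname, "_tot")]] <- dp
  }
  list(counts = pool_counts(df, pools = pool_names), true_freq = f)
}
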