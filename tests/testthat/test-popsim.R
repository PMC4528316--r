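# small map for fast population tests
small_map <- function(n_snps = 200)
  sim_genome_map(c(`1` = 100e6), n_snps = n_snps, cm_per_mb = 0.5)

test_that("genome maps are monotone and apportioned by length", {
  map <- sim_genome_map(c(a = 100e6, b = 50e6), n_snps = 300)
  expect_equal(sum(map$chrom == "a"), 200)
  expect_equal(sum(map$chrom == "b"), 100)
  for (ch in unique(map$chrom)) {
    expect_true(all(diff(map$pos[map$chrom == ch]) > 0))
    expect_true(all(diff(map$cm[map$chrom == ch]) >= 0))
  }
  expect_error(sim_genome_map(c(a = -1), 10))
})

test_that("the F2 segregates 1:2:1 and has balanced allele frequency", {
  cfg <- sim_config(pop_size = 4000, generations = 0, seed = 5)
  pop <- simulate_population(small_map(50), cfg)
  geno <- genotypes(pop)
  # chi-square goodness of fit against 1/4, 1/2, 1/4 at a few SNPs
  for (j in c(1, 25, 50)) {
    tab <- tabulate(geno[, j] + 1L, nbins = 3)
    pval <- suppressWarnings(
      chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value)
    expect_gt(pval, 0.01)
  }
  f <- colMeans(geno) / 2
  expect_true(all(f > 0.45 & f < 0.55))
})

test_that("allele frequencies stay drift-bounded after intermating", {
  cfg <- sim_config(pop_size = 3000, generations = 14, seed = 6)
  pop <- simulate_population(small_map(50), cfg)
  f <- colMeans(genotypes(pop)) / 2
  expect_true(all(f > 0.4 & f < 0.6))
})

test_that("crossover counts per meiosis match the map length", {
  # one chromosome of 100 Mb at 0.5 cM/Mb: 0.5 Morgans
  map <- small_map(100)
  cfg <- sim_config(pop_size = 5000, generations = 0, seed = 9)
  pop <- simulate_population(map, cfg)
  # in the F2, each gamete came from an F1 with intact parental
  # haplotypes, so observed allele switches along a gamete equal
  # realized crossovers
  switches <- mean(abs(diff(pop$haps)) > 0) * (nrow(pop$haps) - 1)
  expect_gt(switches, 0.5 * 0.9 * 0.9)  # Haldane mean, 10% slack, finite SNPs
  expect_lt(switches, 0.5 * 1.1)
})

test_that("phenotypes realize the requested architecture", {
  map <- small_map(100)
  cfg <- sim_config(pop_size = 4000, generations = 5, seed = 10)
  pop <- simulate_population(map, cfg)

  # pure-noise trait: no SNP association
  expect_warning(y0 <- assign_phenotypes(pop, NULL, h2 = 0.5, seed = 1),
                 "zero genetic variance")
  g <- genotypes(pop)
  expect_lt(abs(cor(y0, g[, 50])), 0.06)

  # one additive QTL: dosage contrast approximately 2a
  qtl <- data.frame(chrom = "1", pos = 50e6, a = 1)
  y <- assign_phenotypes(pop, qtl, h2 = 0.7, seed = 2)
  j <- attr(y, "qtl_snp")
  c2 <- mean(y[g[, j] == 2]); c0 <- mean(y[g[, j] == 0])
  expect_equal(c2 - c0, 2, tolerance = 0.15)

  # realized heritability near target
  gv <- attr(y, "genetic_value")
  h2_real <- var(gv) / var(y)
  expect_equal(h2_real, 0.7, tolerance = 0.05)
})

test_that("dominance shifts the heterozygote toward the high homozygote", {
  map <- small_map(60)
  cfg <- sim_config(pop_size = 3000, generations = 2, seed = 13)
  pop <- simulate_population(map, cfg)
  qtl <- data.frame(chrom = "1", pos = 50e6, a = 1, k = 1)
  y <- assign_phenotypes(pop, qtl, h2 = 0.99, seed = 3)
  g <- genotypes(pop)[, attr(y, "qtl_snp")]
  expect_equal(mean(y[g == 1]), mean(y[g == 2]), tolerance = 0.1)
})

test_that("pool selection takes order statistics and a distinct control", {
  cfg <- sim_config(pop_size = 10, n_selected = 2, n_control = 4, seed = 1)
  sel <- select_pools(as.numeric(1:10), cfg)
  expect_setequal(sel$high, c(9, 10))
  expect_setequal(sel$low, c(1, 2))
  expect_equal(anyDuplicated(sel$control), 0L)
  expect_error(select_pools(as.numeric(1:9),
                            sim_config(pop_size = 10, n_selected = 5,
                                       n_control = 2)),
               "exceeds")
})

test_that("selection differential matches the truncation expectation", {
  set.seed(77)
  y <- rnorm(10000)
  cfg <- sim_config(pop_size = 10000, n_selected = 46, n_control = 92,
                    seed = 2)
  sel <- select_pools(y, cfg)
  d <- attr(sel, "differentials")
  # ~0.46% truncation of a normal: expected differential ~ 2.9
  expect_gt(d[["high"]], 2.6); expect_lt(d[["high"]], 3.2)
  expect_lt(d[["low"]], -2.6); expect_gt(d[["low"]], -3.2)
})

test_that("pooled sequencing reproduces pool frequencies in expectation", {
  map <- small_map(500)
  cfg <- sim_config(pop_size = 400, generations = 2, depth = 40,
                    error_rate = 0, seed = 3)
  pop <- simulate_population(map, cfg)
  pools_idx <- list(high = 1:50, low = 51:100)
  out <- pool_and_sequence(pop, pools_idx, cfg)
  obs <- out$counts$high_ref / out$counts$high_tot
  expect_lt(abs(mean(obs, na.rm = TRUE) -
                  mean(out$truth$true_freqs$high_freq)), 0.01)
  expect_true(all(out$truth$true_freqs$high_freq >= 0 &
                    out$truth$true_freqs$high_freq <= 1))
  expect_error(pool_and_sequence(pop, list(high = integer(0))), "empty pool")
})

test_that("a fixed pool with no error yields ref_count equal to depth", {
  map <- small_map(20)
  # generations = 0 from homozygous founders keeps... F2 segregates, so
  # instead force fixation by pooling one individual's two identical
  # haplotypes: use the F1 (pre-meiosis founders are not exposed), so
  # construct directly
  pop <- structure(list(haps = matrix(1L, nrow = 20, ncol = 4),
                        map = map[1:20, ], n = 2),
                   class = "sim_population")
  cfg <- sim_config(pop_size = 2, n_selected = 1, n_control = 1,
                    depth = 30, error_rate = 0, seed = 4)
  out <- pool_and_sequence(pop, list(high = 1:2), cfg)
  expect_equal(out$counts$high_ref, out$counts$high_tot)
})

test_that("selection moves pool frequencies apart at the QTL", {
  map <- sim_genome_map(c(`1` = 100e6), n_snps = 300)
  qtl <- data.frame(chrom = "1", pos = 50e6, a = 1)
  for (seed in 1:3) {
    cfg <- sim_config(pop_size = 600, generations = 6, n_selected = 30,
                      n_control = 60, h2 = 0.5, seed = seed)
    sim <- simulate_bsa(map, qtl, cfg)
    j <- which.min(abs(sim$truth$true_freqs$pos - 50e6))
    dq <- sim$truth$true_freqs$high_freq[j] - sim$truth$true_freqs$low_freq[j]
    expect_gt(dq, 0)
  }
})

test_that("simulation is exactly reproducible from the master seed", {
  map <- small_map(50)
  cfg <- sim_config(pop_size = 100, generations = 3, seed = 42)
  a <- simulate_bsa(map, data.frame(chrom = "1", pos = 50e6, a = 1), cfg)
  b <- simulate_bsa(map, data.frame(chrom = "1", pos = 50e6, a = 1), cfg)
  expect_identical(as.data.frame(a$counts), as.data.frame(b$counts))
  expect_identical(a$pools, b$pools)
})
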