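test_that("outlier threshold follows the nearest-rank rule", {
  expect_equal(outlier_threshold(0:999, q = 0.005), 994)  # rank 995
  expect_equal(outlier_threshold(rep(3, 50)), 3)
  expect_equal(outlier_threshold(c(5, 1, 9, 2), q = 0), 9)
  expect_error(outlier_threshold(numeric(0)), "no finite")
  # matches a brute-force sort-and-index on random vectors
  set.seed(14)
  for (rep in 1:20) {
    x <- rnorm(sample(10:2000, 1))
    q <- runif(1, 0, 0.2)
    expect_equal(outlier_threshold(x, q),
                 sort(x)[max(1, ceiling((1 - q) * length(x)))])
  }
})

test_that("significant SNP count respects the quantile bound", {
  set.seed(2)
  x <- rnorm(5000)
  thr <- outlier_threshold(x, 0.005)
  expect_lte(sum(x > thr), 0.005 * length(x) + sum(x == thr))
})

# scan with SNPs at 1 Mb spacing and controllable significance
step_scan <- function(sig_idx, n = 30, spacing = 1e6, chrom = "1") {
  df <- data.frame(chrom = chrom, pos = as.integer(seq_len(n) * spacing),
                   z = 0, zprime = 0, p = 1, neglogp = 0, wdiff = 0.01,
                   stringsAsFactors = FALSE)
  df$neglogp[sig_idx] <- 10
  df$p[sig_idx] <- 1e-10
  df
}

test_that("a significant run is extended by seven scan SNPs each side", {
  sc <- step_scan(10:12)
  rs <- call_regions(sc, threshold = 5)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$left, 3e6)    # SNP 3
  expect_equal(rs$right, 19e6)  # SNP 19
  expect_equal(rs$peak_pos, 10e6)  # leftmost of the tied peak SNPs
  expect_equal(rs$direction, "+")
  expect_equal(rs$n_snps, 17L)
})

test_that("extension clips at chromosome ends", {
  sc <- step_scan(2)
  rs <- call_regions(sc, threshold = 5)
  expect_equal(rs$left, 1e6)
  expect_equal(rs$right, 9e6)
})

test_that("regions closer than the merge distance fuse", {
  # runs at SNPs 10 and 24: post-extension boundaries 17 Mb and 17 Mb,
  # gap 0 < 5 Mb -> merged
  sc <- step_scan(c(10, 20))
  rs <- call_regions(sc, threshold = 5)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$left, 3e6)
  expect_equal(rs$right, 27e6)

  # far-apart runs stay separate
  sc2 <- step_scan(c(10, 40), n = 60)
  rs2 <- call_regions(sc2, threshold = 5)
  expect_equal(nrow(rs2), 2L)
  # and their boundary gap is at least the merge distance
  expect_gte(rs2$left[2] - rs2$right[1], 5e6)
})

test_that("merging iterates until stable across a chain of regions", {
  # three runs, each within 5 Mb of the next after extension
  sc <- step_scan(c(10, 20, 30), n = 45)
  rs <- call_regions(sc, threshold = 5)
  expect_equal(nrow(rs), 1L)
})

test_that("no significant SNPs yields an empty region set", {
  rs <- call_regions(step_scan(integer(0)), threshold = 5)
  expect_equal(nrow(rs), 0L)
  expect_s3_class(rs, "region_set")
})

test_that("windows never leak across chromosomes in region calling", {
  sc <- rbind(step_scan(28:30, chrom = "1"), step_scan(1:2, chrom = "2"))
  rs <- call_regions(sc, threshold = 5)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$chrom, c("1", "2"))
})

test_that("region sets satisfy their structural invariants on random scans", {
  set.seed(31)
  for (rep in 1:20) {
    sc <- random_scan(sample(100:800, 1))
    thr <- outlier_threshold(sc$neglogp, 0.01)
    merge_bp <- sample(c(0, 1e6, 5e6), 1)
    rs <- call_regions(sc, thr, merge_bp = merge_bp)
    if (nrow(rs) == 0) next
    expect_true(all(rs$left <= rs$peak_pos & rs$peak_pos <= rs$right))
    expect_true(all(rs$neglogp > thr))
    for (ch in unique(rs$chrom)) {
      r <- rs[rs$chrom == ch, ]
      if (nrow(r) > 1) {
        expect_true(all(diff(r$left) > 0))
        expect_true(all(r$left[-1] - r$right[-nrow(r)] >= merge_bp))
      }
    }
  }
})

test_that("raising the threshold nests regions (pre-merge)", {
  set.seed(8)
  sc <- random_scan(600)
  t_low <- outlier_threshold(sc$neglogp, 0.05)
  t_high <- outlier_threshold(sc$neglogp, 0.005)
  expect_lte(sum(sc$neglogp > t_high), sum(sc$neglogp > t_low))
  lo <- call_regions(sc, t_low, merge_bp = 0)
  hi <- call_regions(sc, t_high, merge_bp = 0)
  for (i in seq_len(nrow(hi))) {
    inside <- any(lo$chrom == hi$chrom[i] &
                    lo$left <= hi$left[i] & lo$right >= hi$right[i])
    expect_true(inside)
  }
})

test_that("region summaries reproduce published interval lengths", {
  pub <- read.table(region_fixture_path(), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  smry <- summarize_regions(pub)
  expect_equal(smry$length_kb, pub$length_kb)
  # spot checks, including sub-kb rounding (10,335 bp -> 10 kb and
  # 15,867 bp -> 16 kb)
  expect_equal(smry$length_kb[pub$left == 123504621], 18857L)
  expect_equal(smry$length_kb[pub$left == 205171472], 21157L)
  expect_equal(smry$length_kb[pub$left == 27603027], 10L)
  expect_equal(smry$length_kb[pub$left == 19435989], 16L)
})

test_that("interval comparison classifies overlap relationships", {
  a <- data.frame(chrom = "8", left = 5e6, right = 10e6)
  b <- data.frame(chrom = "8", left = 8e6, right = 20e6)
  rep1 <- compare_region_sets(a, b)
  expect_equal(rep1$relationship, "partial-overlap")
  expect_equal(rep1$overlap_bp, 2e6)
  expect_true(rep1$shared)

  disj <- compare_region_sets(a, data.frame(chrom = "8", left = 15e6,
                                            right = 20e6))
  expect_equal(disj$relationship, "disjoint")
  expect_equal(disj$overlap_bp, 0)
  expect_false(disj$shared)

  # different chromosomes produce no row
  expect_equal(nrow(compare_region_sets(
    a, data.frame(chrom = "9", left = 5e6, right = 10e6))), 0L)

  # every region contains itself
  self <- compare_region_sets(a, a)
  expect_equal(self$relationship, "a-contains-b")
})

test_that("the chr8 linkage interval is contained in the scan region", {
  bsas <- data.frame(chrom = "8", left = 123504621, right = 142361278)
  lod15 <- data.frame(chrom = "8", left = 127700000, right = 133050000)
  rep <- compare_region_sets(bsas, lod15)
  expect_equal(rep$relationship, "a-contains-b")
  expect_true(rep$shared)
})

test_that("recovery metrics score containment with slack", {
  called <- structure(data.frame(chrom = "1", left = 45e6, right = 60e6,
                                 peak_pos = 52e6),
                      class = c("region_set", "data.frame"))
  truth <- data.frame(chrom = "1", pos = 50e6)
  m <- recovery_metrics(called, truth, slack_bp = 0)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$false_regions, 0L)
  expect_equal(m$peak_offset_bp, 2e6)

  none <- called[0, ]
  m0 <- recovery_metrics(none, truth, slack_bp = 0)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$false_regions, 0L)

  # slack rescues a near miss; an unrelated region counts as false
  called2 <- data.frame(chrom = c("1", "2"),
                        left = c(52e6, 10e6), right = c(60e6, 12e6),
                        peak_pos = c(55e6, 11e6))
  m2 <- recovery_metrics(called2, truth, slack_bp = 5e6)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$false_regions, 1L)
})
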