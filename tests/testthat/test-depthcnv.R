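test_that("region depth is a masked arithmetic mean", {
  cov <- rep(10, 100)
  expect_equal(region_depth(cov, c(1, 100)), 10)
  cov2 <- c(rep(0, 50), rep(20, 50))
  expect_equal(region_depth(cov2, c(1, 100)), 10)
  # masked bases leave numerator and denominator
  expect_equal(region_depth(cov2, c(1, 100), mask = data.frame(start = 1, end = 50)), 20)
  # masking twice equals masking once
  m1 <- region_depth(cov2, c(1, 100), mask = data.frame(start = 1, end = 50))
  m2 <- region_depth(cov2, c(1, 100),
                     mask = data.frame(start = c(1, 1), end = c(50, 50)))
  expect_identical(m1, m2)
  expect_error(region_depth(cov, c(1, 50), mask = data.frame(start = 1, end = 50)),
               "fully masked")
  expect_error(region_depth(cov, c(1, 101)), "region")
  # data.frame input equivalent to vector input
  df <- data.frame(pos = 1:100, depth = cov2)
  expect_equal(region_depth(df, c(1, 100)), 10)
})

test_that("depth normalization records its mode and rejects a zero baseline", {
  nd <- normalize_depth(16, 8, "autosome")
  expect_equal(nd$value, 2)
  expect_equal(nd$mode, "autosome")
  expect_equal(normalize_depth(5, 5, "chrXIX")$value, 1)
  expect_equal(normalize_depth(5, 5, "chrXIX")$mode, "chrXIX")
  expect_error(normalize_depth(1, 0), "baseline")
})

test_that("BAM coverage honours MAPQ and primary-alignment filters", {
  dir <- withr::local_tempdir()
  ref <- strrep("ACGT", 100)  # 400 bp reference
  sam <- file.path(dir, "toy.sam")
  read <- substr(ref, 11, 60)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ref\tLN:400",
    sprintf("good\t0\tref\t11\t30\t50M\t*\t0\t0\t%s\t%s", read, strrep("I", 50)),
    sprintf("lowmq\t0\tref\t11\t2\t50M\t*\t0\t0\t%s\t%s", read, strrep("I", 50)),
    sprintf("secondary\t256\tref\t11\t30\t50M\t*\t0\t0\t%s\t%s", read, strrep("I", 50))
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE)
  cov <- coverage_from_bam(bam, "ref", min_mapq = 3, primary_only = TRUE)
  expect_length(cov, 400)
  expect_equal(mean(cov[11:60]), 1)   # only the good primary read counts
  expect_equal(sum(cov), 50)
  cov_all <- coverage_from_bam(bam, "ref", min_mapq = 0, primary_only = FALSE)
  expect_equal(sum(cov_all), 150)
})

test_that("calibration table scales with copy number and validates input", {
  specs <- function(cc, seed) haplotype_spec(
    "freshwater", cc, gene_length_bp = 5000, dup_region_length_bp = 17600,
    intergenic_length_bp = 3000, crossover_pos = if (cc >= 5) 8000, seed = seed)
  haps <- list(`3` = forge_haplotype(specs(3, 1)), `4` = forge_haplotype(specs(4, 1)))
  tab <- build_call_table(haps, read_sim_params(depth_x = 8, seed = 2), n_reps = 2)
  expect_equal(tab$copy_count, c(3, 4))
  # one vs two C3 gene copies: entry ratio ~ 2 within sampling error
  expect_lt(abs(tab$expected_depth[2] / tab$expected_depth[1] - 2), 0.2)
  expect_error(build_call_table(haps["3"], read_sim_params(depth_x = 8)),
               "at least 2")
})

test_that("copy-number calls are nearest-entry with ties toward the lower count", {
  tab <- data.frame(copy_count = c(1, 2, 4), expected_depth = c(1, 2, 4))
  expect_equal(call_copy_number(2.0, tab)$copy_count, 2)
  expect_equal(call_copy_number(2.0, tab)$distance, 0)
  expect_equal(call_copy_number(1.5, tab)$copy_count, 1)  # tie toward lower
  expect_equal(call_copy_number(3.9, tab)$copy_count, 4)
  g <- call_genotype(3.0, data.frame(copy_count = 3:6, expected_depth = 1:4))
  expect_equal(g$total, 10)      # genotype mean 3 = (1+... e.g. 2+4)/2
  expect_equal(sum(g$genotype), g$total)
  # exact tie between (3,3) at 1.0 and (3,4) at 1.5 breaks toward lower total
  gt <- call_genotype(1.25, data.frame(copy_count = 3:6, expected_depth = 1:4))
  expect_equal(gt$total, 6)
})

test_that("Mann-Kendall trend matches the exhaustive permutation law", {
  mk <- mann_kendall_trend(c(1, 2, 3, 4, 5))
  expect_equal(mk$S, 10)
  expect_equal(mk$p_one_sided, 1 / 120)
  expect_equal(mk$method, "exact permutation")
  const <- mann_kendall_trend(c(2, 2, 2, 2), exact_max = 0)
  expect_equal(const$S, 0)
  expect_gte(const$p_one_sided, 0.5)
  rev <- mann_kendall_trend(c(5, 4, 3, 2, 1))
  expect_equal(rev$S, -10)
  expect_gt(rev$p_one_sided, 0.99)
  expect_error(mann_kendall_trend(c(1, 2)), "n >= 3")
  # |S| bound
  for (seed in 1:5) {
    x <- with_seed(seed, rnorm(7))
    m <- mann_kendall_trend(x)
    expect_lte(abs(m$S), 7 * 6 / 2)
  }
})

test_that("exact and normal-approximation Mann-Kendall p agree for n in 6..8", {
  for (n in 6:8) {
    for (seed in 1:8) {
      x <- with_seed(100 * n + seed, rnorm(n))
      ex <- mann_kendall_trend(x, exact_max = 8)
      ap <- mann_kendall_trend(x, exact_max = 0)
      expect_lt(abs(ex$p_one_sided - ap$p_one_sided), 0.02,
                label = sprintf("exact/approx gap (n=%d seed=%d)", n, seed))
    }
  }
})

test_that("rank-sum group comparison reproduces the exact enumeration law", {
  gd <- group_difference(c(1, 2, 3, 4, 5, 6), rep(c("m", "f"), each = 3))
  expect_equal(gd$p_value, 0.1)
  # enumeration oracle: all C(6,3)=20 label assignments of fixed values
  vals <- c(1, 2, 3, 4, 5, 6)
  combs <- utils::combn(6, 3)
  ranksum <- apply(combs, 2, function(idx) sum(rank(vals)[idx]))
  obs <- sum(rank(vals)[1:3])
  p_oracle <- mean(abs(ranksum - mean(range(ranksum))) >=
                     abs(obs - mean(range(ranksum))))
  expect_equal(gd$p_value, p_oracle)
  same <- group_difference(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  expect_error(group_difference(1:3, c("a", "a", "a")), "two groups")
})

test_that("Pearson depth-latitude correlation behaves at its edges", {
  expect_equal(depth_latitude_correlation(1:10, 2 * (1:10) + 3)$r, 1)
  expect_equal(depth_latitude_correlation(1:10, -(1:10))$r, -1)
  n <- 400
  x <- with_seed(9, rnorm(n)); y <- with_seed(10, rnorm(n))
  expect_lt(abs(depth_latitude_correlation(x, y)$r), 3 / sqrt(n))
  expect_error(depth_latitude_correlation(rep(1, 5), 1:5), "variance")
  expect_error(depth_latitude_correlation(1:2, 1:2), "n >= 3")
})

test_that("collapsed coverage is proportional to copy number on noise-free input", {
  h3 <- build_base_haplotype(haplotype_spec("freshwater", 3, seed = 11))
  h5 <- forge_haplotype(haplotype_spec("freshwater", 5, crossover_pos = 1000, seed = 11))
  pool <- weighted_pool(c("a", "b"), c(h3$sequence, h5$sequence))
  pr <- simulate_paired_reads(pool, read_sim_params(n_pairs = 30000, seed = 12))
  cov <- collapsed_coverage(pr, list(a = h3, b = h5))
  lay <- h3$layout
  unit_mean <- mean(cov[lay$units$start[1]:lay$units$end[1]])
  base_mean <- mean(cov[300:3000])
  # diploid carries 1 + 3 = 4 unit copies over 2 baseline copies
  expect_lt(abs(unit_mean / base_mean - 2), 0.15)
})
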