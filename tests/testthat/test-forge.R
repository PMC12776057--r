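test_that("spec validation names the offending field", {
  expect_error(haplotype_spec(copy_count = 2), "copy_count")
  expect_error(haplotype_spec(copy_count = 7), "copy_count")
  expect_error(haplotype_spec(gene_length_bp = 0), "gene_length_bp")
  expect_error(haplotype_spec(snp_divergence_rate = 1), "snp_divergence_rate")
  expect_error(haplotype_spec(microhomology_len_bp = -1), "microhomology_len_bp")
  expect_error(haplotype_spec(copy_count = 3, crossover_pos = 100), "crossover_pos")
  expect_error(haplotype_spec(microhomology_len_bp = 2000,
                              dup_region_length_bp = 2000), "microhomology_len_bp")
})

test_that("3-copy base haplotype has the ancestral structure and is deterministic", {
  spec <- haplotype_spec("marine", 3, seed = 1)
  h <- build_base_haplotype(spec)
  expect_equal(h$copies$label, c("C1", "C2", "C3A"))
  expect_length(h$junctions, 0)
  expect_identical(h$sequence, build_base_haplotype(spec)$sequence)
  expect_false(is.unsorted(h$copies$start))
  # copy intervals non-overlapping
  expect_true(all(head(h$copies$end, -1) < tail(h$copies$start, -1)))
})

test_that("ecotype pairs from one seed differ exactly at the SNP table", {
  for (seed in c(1, 5, 11)) {
    hm <- build_base_haplotype(haplotype_spec("marine", 3, seed = seed))
    hf <- build_base_haplotype(haplotype_spec("freshwater", 3, seed = seed))
    diff <- which(strsplit(hm$sequence, "")[[1]] != strsplit(hf$sequence, "")[[1]])
    expect_identical(diff, hm$snp_table$pos)
    expect_identical(hm$snp_table, hf$snp_table)
    # the recorded alleles are the actual bases
    mch <- strsplit(hm$sequence, "")[[1]][hm$snp_table$pos]
    fch <- strsplit(hf$sequence, "")[[1]][hf$snp_table$pos]
    expect_identical(unname(mch), hm$snp_table$marine)
    expect_identical(unname(fch), hm$snp_table$freshwater)
  }
})

test_that("MMBIR expansion adds one unit and plants recoverable microhomology", {
  h3 <- build_base_haplotype(haplotype_spec("freshwater", 3, seed = 2))
  h4 <- expand_mmbir(h3, 4)
  expect_equal(nchar(h4$sequence) - nchar(h3$sequence),
               h3$spec$dup_region_length_bp)
  expect_equal(nrow(h4$copies), 4)
  expect_length(h4$junctions, 1)
  # roundtrip with the detection oracle, for every planted length
  for (k in c(0, 2, 4, 8)) {
    for (seed in c(3, 7)) {
      hk <- expand_mmbir(build_base_haplotype(haplotype_spec("freshwater", 3, seed = seed)), k)
      mh <- junction_microhomology(junction_context(hk))
      expect_equal(mh$perfect_len, k,
                   label = sprintf("perfect_len (k=%d, seed=%d)", k, seed))
      expect_identical(hk$planted_microhomology_bp, as.integer(k))
    }
  }
  expect_error(expand_mmbir(h3, h3$spec$dup_region_length_bp), "smaller")
})

test_that("successive expansions keep junction count = copies - 3", {
  h <- build_base_haplotype(haplotype_spec("freshwater", 3, seed = 4))
  for (i in 1:3) {
    h <- expand_mmbir(h)
    expect_length(h$junctions, nrow(h$copies) - 3)
    # all junctions carry the same planted microhomology
    mh <- junction_microhomology(junction_context(h))
    expect_equal(mh$perfect_len, h$planted_microhomology_bp)
  }
})

test_that("NAHR produces reciprocal products and conserves copies", {
  h4 <- expand_mmbir(build_base_haplotype(haplotype_spec("freshwater", 3, seed = 5)))
  pr <- recombine_nahr(h4, h4, c("C3A", "C3L"), 1000)
  expect_equal(nrow(pr$duplication$copies), 5)
  expect_equal(nrow(pr$deletion$copies), 3)
  expect_equal(nrow(pr$duplication$copies) + nrow(pr$deletion$copies),
               nrow(h4$copies) + nrow(h4$copies))
  # sequence mass conserved too
  expect_equal(nchar(pr$duplication$sequence) + nchar(pr$deletion$sequence),
               2 * nchar(h4$sequence))
  h5 <- pr$duplication
  pr2 <- recombine_nahr(h5, h5, c("C3A", "C3B"), 700)
  expect_equal(nrow(pr2$duplication$copies), 6)
  expect_equal(nrow(pr2$deletion$copies), 4)
  expect_error(recombine_nahr(h4, h4, c("C3A", "C3L"), 99999), "crossover_pos")
  expect_error(recombine_nahr(h4, h4, c("C3A", "C3X"), 100), "pairing")
})

test_that("the NAHR intermediate unit is an L-prefix / A-suffix mosaic", {
  h4 <- expand_mmbir(build_base_haplotype(haplotype_spec("freshwater", 3, seed = 6)))
  o <- 900
  h5 <- recombine_nahr(h4, h4, c("C3A", "C3L"), o)$duplication
  unit_seq <- function(h, lab) {
    iv <- h$units[h$units$label == lab, ]
    substr(h$sequence, iv$start, iv$end)
  }
  a <- unit_seq(h5, "C3A"); l <- unit_seq(h5, "C3L"); b <- unit_seq(h5, "C3B")
  expect_identical(substr(b, 1, o - 1), substr(l, 1, o - 1))
  expect_identical(substr(b, o, nchar(b)), substr(a, o, nchar(a)))
  # planted crossover interval brackets the crossover and bounds the
  # surrounding identity interval between divergent offsets
  xo <- h5$planted_crossover_interval
  expect_true(xo["lo"] < o && o <= xo["hi"])
  ach <- strsplit(a, "")[[1]]; lch <- strsplit(l, "")[[1]]
  div <- which(ach != lch)
  expect_true(xo["lo"] %in% div && xo["hi"] %in% div)
  expect_false(any(div > xo["lo"] & div < xo["hi"]))
})

test_that("paired-read simulation honours count, length and determinism contracts", {
  pool <- weighted_pool("x", with_seed(1, paste(sample(c("A", "C", "G", "T"),
                                                       5000, TRUE), collapse = "")))
  p <- read_sim_params(n_pairs = 1000, seed = 3)
  pr <- simulate_paired_reads(pool, p)
  expect_length(pr$r1, 1000)
  expect_length(pr$r2, 1000)
  expect_true(all(nchar(pr$r1) == 76) && all(nchar(pr$r2) == 76))
  pr2 <- simulate_paired_reads(pool, p)
  expect_identical(pr$r1, pr2$r1)
  expect_identical(pr$r2, pr2$r2)
  # mates are reverse complements of fragment ends: check one noise-free pair
  i <- 1
  frag <- substr(pool$sequence[1], pr$info$start[i], pr$info$end[i])
  if (pr$info$strand[i] == "-") frag <- revcomp(frag)
  expect_identical(pr$r1[[i]], substr(frag, 1, 76))
  expect_identical(pr$r2[[i]], revcomp(substr(frag, nchar(frag) - 75, nchar(frag))))
  expect_error(simulate_paired_reads(weighted_pool("s", "ACGT"), p), "read_len")
})

test_that("simulated depth and source weights match binomial/multinomial expectation", {
  seqlen <- 100000
  s <- with_seed(2, paste(sample(c("A", "C", "G", "T"), seqlen, TRUE), collapse = ""))
  pr <- simulate_paired_reads(weighted_pool("x", s),
                              read_sim_params(depth_x = 8, seed = 4))
  realized <- sum(nchar(pr$r1) + nchar(pr$r2)) / seqlen
  n_pairs <- length(pr$r1)
  se <- 8 / sqrt(n_pairs)
  expect_lt(abs(realized - 8), 3 * se + 2 * 152 / seqlen)
  # weights 3:1 on equal-length entries
  s2 <- with_seed(3, paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = ""))
  s3 <- with_seed(4, paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = ""))
  pr2 <- simulate_paired_reads(weighted_pool(c("a", "b"), c(s2, s3), c(3, 1)),
                               read_sim_params(n_pairs = 4000, seed = 5))
  p_hat <- mean(pr2$info$label == "a")
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
})

test_that("long-read simulation respects weights and truncation", {
  s1 <- with_seed(5, paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""))
  s2 <- with_seed(6, paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""))
  pool <- weighted_pool(c("a", "b"), c(s1, s2))
  empty <- simulate_long_reads(pool, 0)
  expect_length(empty$reads, 0)
  lr <- simulate_long_reads(pool, 10000, seed = 7)
  expect_lt(abs(mean(lr$info$label == "a") - 0.5), 3 * sqrt(0.25 / 10000))
  lrt <- simulate_long_reads(pool, 2000, seed = 8, truncation_rate = 0.5)
  frac_short <- mean(nchar(lrt$reads) < 1500)
  expect_lt(abs(frac_short - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("weighted_pool and read_sim_params validate their inputs", {
  expect_error(weighted_pool(c("a", "a"), c("ACGT", "ACGT")), "unique")
  expect_error(weighted_pool("a", "ACGT", -1), "weights")
  expect_error(weighted_pool(c("a", "b"), c("ACGT", "ACGT"), c(0, 0)), "weights")
  expect_error(read_sim_params(read_len_bp = 200, frag_mu_bp = 150), "frag_mu_bp")
  expect_error(read_sim_params(per_base_error = 1), "per_base_error")
  expect_error(read_sim_params(depth_x = 8, n_pairs = 10), "exactly one")
  expect_error(read_sim_params(), "exactly one")
})
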