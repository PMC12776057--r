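test_that("column classification is exhaustive and exclusive", {
  aln <- paralog_alignment(
    c("ACGTA", "ACGTA",   # copy K1, alleles 1/2
      "AGGTC", "AGCTC"),  # copy K2, alleles 1/2
    copy = c("K1", "K1", "K2", "K2"),
    allele = c("a1", "a2", "a1", "a2"))
  cls <- classify_columns(aln)
  # col1 invariant; col2 copy (C vs G); col3 allele (K2 alleles G/C);
  # col4 invariant; col5 copy (A vs C)
  expect_equal(cls, c("invariant", "copy", "allele", "invariant", "copy"))
  gap <- paralog_alignment(c("A-G", "ACG"), c("K1", "K2"), c("a1", "a1"))
  expect_equal(classify_columns(gap)[2], "gap")
})

test_that("MCE design matches a brute-force window scan", {
  aln <- toy_paralog_alignment(len = 120, copy_col = 50, allele_col = 60)
  k <- 27
  sets <- design_kmers(aln, "MCE", k = k, keep_overlapping = TRUE)
  # oracle: windows that contain column 50 but not column 60
  starts <- vapply(sets, `[[`, numeric(1), "window")
  oracle <- Filter(function(s) s <= 50 && 50 <= s + k - 1 &&
                     !(s <= 60 && 60 <= s + k - 1), seq_len(120 - k + 1))
  expect_setequal(starts, oracle)
  # members are mutually distinct and 27 bp
  for (s in sets) {
    expect_equal(unique(nchar(unlist(s$members))), 27)
    expect_false(anyDuplicated(unlist(s$members)) > 0)
  }
  # greedy selection keeps non-overlapping windows only
  g <- design_kmers(aln, "MCE", k = k)
  gs <- sort(vapply(g, `[[`, numeric(1), "window"))
  if (length(gs) > 1) expect_true(all(diff(gs) >= k))
})

test_that("ASE candidates require both diagnostic columns within one window", {
  # copy variant at 50, allele variant at 60: 10 bp apart -> candidates exist
  aln <- toy_paralog_alignment(copy_col = 50, allele_col = 60)
  sets <- design_kmers(aln, "ASE", k = 27, target = "K2", keep_overlapping = TRUE)
  expect_gt(length(sets), 0)
  for (s in sets) {
    expect_true(s$window <= 50 && 50 <= s$window + 26)
    expect_true(s$window <= 60 && 60 <= s$window + 26)
    expect_equal(sort(names(s$members)), c("al1", "al2"))
    expect_false(identical(s$members[["al1"]], s$members[["al2"]]))
  }
  # allele variant with no copy variant within 26 bp -> no candidate
  far <- toy_paralog_alignment(copy_col = 30, allele_col = 60)
  expect_length(design_kmers(far, "ASE", k = 27, target = "K2",
                             keep_overlapping = TRUE), 0)
})

test_that("screening drops off-target, near-target and transcript-end k-mers", {
  aln <- toy_paralog_alignment(len = 300, copy_col = 150, allele_col = 160)
  sets <- design_kmers(aln, "ASE", k = 27, target = "K2")
  expect_gt(length(sets), 0)
  km <- sets[[1]]$members[[1]]
  locus <- paste0(strrep("T", 400), km, strrep("G", 400))
  # genome containing the k-mer only inside the declared on-target interval
  ok <- screen_kmers(sets[1], c(chr1 = locus),
                     on_target = data.frame(seqname = "chr1", start = 401,
                                            end = 400 + 27),
                     max_one_mismatch = 5)
  expect_length(ok, 1)
  # a second perfect copy elsewhere is off-target -> removed
  bad <- screen_kmers(sets[1], c(chr1 = locus, chr2 = paste0(strrep("A", 50), km)),
                      on_target = data.frame(seqname = "chr1", start = 401,
                                             end = 400 + 27))
  expect_length(bad, 0)
  expect_match(attr(bad, "screen")$reason[1], "perfect off-target")
  # 6 one-mismatch off-target hits -> removed; 5 -> retained
  mut <- function(x) { substr(x, 14, 14) <- setdiff(c("A","C","G","T"),
                                                    substr(x, 14, 14))[1]; x }
  near <- mut(km)
  mk_genome <- function(n) c(chr1 = locus,
    chr2 = paste(c(rep(near, n)), collapse = strrep("T", 30)))
  expect_length(screen_kmers(sets[1], mk_genome(6),
                             on_target = data.frame(seqname = "chr1", start = 401,
                                                    end = 427)), 0)
  expect_length(screen_kmers(sets[1], mk_genome(5),
                             on_target = data.frame(seqname = "chr1", start = 401,
                                                    end = 427)), 1)
})

test_that("transcript-end distance rule removes k-mers closer than 100 bp", {
  # k-mer window starting at column 100 of a 300-col alignment:
  # 99 bp before it -> removed; shift the variant to start at 101 -> retained
  for (cc in c(100, 101)) {
    aln <- toy_paralog_alignment(len = 300, copy_col = cc + 10, allele_col = cc + 12)
    sets <- design_kmers(aln, "ASE", k = 27, target = "K2", keep_overlapping = TRUE)
    sets <- Filter(function(s) s$window == cc, sets)
    expect_length(sets, 1)
    kept <- screen_kmers(sets, genomes = character(0), aln = aln,
                         min_end_dist = 100)
    expect_length(kept, if (cc == 100) 0 else 1)
    if (cc == 100) expect_match(attr(kept, "screen")$reason[1], "transcript end")
  }
})

test_that("pair counting equals the brute-force scan on synthetic pairs", {
  aln <- toy_paralog_alignment(len = 200, copy_col = 90, allele_col = 100)
  sets <- c(design_kmers(aln, "MCE", k = 27),
            design_kmers(aln, "ASE", k = 27, target = "K2"))
  expect_gt(length(sets), 1)
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  pool <- weighted_pool(paste0("t", 1:4), seqs, c(2, 1, 1, 2))
  pr <- simulate_paired_reads(pool, read_sim_params(
    read_len_bp = 50, frag_mu_bp = 80, frag_sd_bp = 20, n_pairs = 1000,
    per_base_error = 0.002, seed = 21))
  counts <- count_pairs(pr$r1, pr$r2, sets)
  kmers <- unlist(lapply(sets, function(s) unlist(s$members)), use.names = FALSE)
  oracle <- oracle_count_pairs(pr$r1, pr$r2, kmers)
  expect_identical(counts$counts$count, unname(oracle))
  expect_equal(counts$total_pairs, 1000)
  # stranded mode agrees with the stranded oracle too
  c2 <- count_pairs(pr$r1, pr$r2, sets, both_orientations = FALSE)
  o2 <- oracle_count_pairs(pr$r1, pr$r2, kmers, both_orientations = FALSE)
  expect_identical(c2$counts$count, unname(o2))
})

test_that("a pair is counted once however many mates match, and only exactly", {
  aln <- toy_paralog_alignment(len = 80, copy_col = 30, allele_col = 40)
  sets <- design_kmers(aln, "ASE", k = 27, target = "K2")
  km <- sets[[1]]$members[[1]]
  both <- count_pairs(paste0("AAAA", km), paste0(km, "TTTT"), sets[1])
  expect_equal(sum(both$counts$count[both$counts$member == names(sets[[1]]$members)[1]]), 1)
  mm <- km; substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm, 5, 5))[1]
  near <- count_pairs(paste0("AAAA", mm), "ACGTACGTACGTACGTACGTACGTACGTACG", sets[1])
  expect_equal(sum(near$counts$count), 0)
  expect_error(count_pairs(c("ACGT", "ACGT"), "ACGT", sets[1]), "desynchronized")
})

test_that("RPM follows the detections-per-million formula and averages per copy", {
  fake <- structure(list(
    counts = data.frame(set_id = c("s1", "s1", "s2", "s2"),
                        mode = "MCE", copy = NA,
                        member = c("K1", "K2", "K1", "K2"),
                        count = c(50L, 10L, 150L, 30L)),
    total_pairs = 1000000L), class = "kmer_counts")
  rpm <- mce_rpm(fake)
  expect_equal(rpm$rpm[rpm$copy == "K1"], (50 + 150) / 2)
  expect_equal(rpm$rpm[rpm$copy == "K2"], (10 + 30) / 2)
  fake$counts$count <- c(0L, 0L, 0L, 0L)
  expect_true(all(mce_rpm(fake)$rpm == 0))
  fake$total_pairs <- 0L
  expect_error(mce_rpm(fake), "total_pairs")
  # linearity: doubling detections doubles RPM
  a <- structure(list(counts = data.frame(set_id = "s", mode = "MCE", copy = NA,
                                          member = "K1", count = 7L),
                      total_pairs = 1000L), class = "kmer_counts")
  b <- a; b$counts$count <- 14L
  expect_equal(mce_rpm(b)$rpm, 2 * mce_rpm(a)$rpm)
})

test_that("ASE proportion applies the QC gauntlet before averaging", {
  mk_counts <- function(a1, a2) structure(list(
    counts = data.frame(set_id = rep(paste0("s", seq_along(a1)), each = 2),
                        mode = "ASE", copy = "C3",
                        member = rep(c("B", "R"), length(a1)),
                        count = as.integer(rbind(a1, a2))),
    total_pairs = 100000L), class = "kmer_counts")
  r <- ase_proportion(mk_counts(75, 25), "B")
  expect_true(r$qc_pass)
  expect_equal(r$proportion_allele1, 0.75)
  low <- ase_proportion(mk_counts(74, 25), "B")   # 99 total
  expect_false(low$qc_pass)
  expect_equal(low$reason, "min total reads")
  zero <- ase_proportion(mk_counts(150, 0), "B")
  expect_false(zero$qc_pass)
  expect_equal(zero$reason, "min reads per allele")
  # one of two sets undetected
  und <- ase_proportion(mk_counts(c(100, 0), c(50, 0)), "B")
  expect_false(und$qc_pass)
  expect_equal(und$reason, "k-mer set undetected")
  # averaging across sets, not pooling counts
  two <- ase_proportion(mk_counts(c(90, 60), c(10, 40)), "B")
  expect_equal(two$proportion_allele1, mean(c(0.9, 0.6)))
  expect_equal(two$n_sets_used, 2L)
})

test_that("ASE significance testing matches the exact signed-rank law", {
  x <- c(0.6, 0.7, 0.8, 0.65, 0.75, 0.9)
  r <- ase_test(x, mu = 0.5)
  expect_equal(r$p_value, 2 / 64)  # all six above mu: 2 of 2^6 sign patterns
  sym <- ase_test(c(0.4, 0.6, 0.3, 0.7), mu = 0.5)
  expect_equal(sym$p_value, 1)
  one <- ase_test(0.8, mu = 0.5)
  expect_equal(one$p_value, 1)
  expect_match(one$flag, "single replicate")
  expect_warning(deg <- ase_test(rep(0.5, 4), mu = 0.5), "equal mu")
  expect_equal(deg$p_value, 1)
  # two-group contrast path
  tg <- ase_test(c(0.6, 0.62, 0.65), y = c(0.7, 0.75, 0.8))
  expect_lt(tg$p_value, 0.2)
})

test_that("retained ASE sets never count the wrong allele on pure input", {
  aln <- toy_paralog_alignment(len = 400, copy_col = 190, allele_col = 200)
  sets <- design_kmers(aln, "ASE", k = 27, target = "K2")
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  # reads purely from K2 allele 1 (row 3)
  pr <- simulate_paired_reads(weighted_pool("only", seqs[3]),
                              read_sim_params(read_len_bp = 60, frag_mu_bp = 90,
                                              frag_sd_bp = 15, n_pairs = 500, seed = 30))
  counts <- count_pairs(pr$r1, pr$r2, sets)
  al2 <- counts$counts[counts$counts$member == "al2", ]
  expect_true(all(al2$count == 0))
  al1 <- counts$counts[counts$counts$member == "al1", ]
  expect_gt(sum(al1$count), 0)
})

test_that("the dosage prediction is copy-proportional", {
  expect_equal(dosage_expected_proportion(3, 1), 0.75)
  expect_equal(dosage_expected_proportion(1, 1), 0.5)
  expect_equal(dosage_expected_proportion(4, 1), 0.8)
  expect_error(dosage_expected_proportion(0, 0), "copy counts")
})
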