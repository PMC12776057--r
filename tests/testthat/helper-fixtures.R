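# Shared fixtures, all generated in code.

# toy transcript alignment: 2 copies x 2 alleles over a common backbone,
# with planted copy- and allele-diagnostic columns
toy_paralog_alignment <- function(len = 120, copy_col = 50, allele_col = 60,
                                  seed = 1) {
  base <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                collapse = ""))
  put <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  c1 <- put(base, copy_col, "A")       # copy 1, both alleles
  c2 <- put(base, copy_col, "G")       # copy 2, both alleles
  paralog_alignment(
    c(c1, c1, put(c2, allele_col, "C"), put(c2, allele_col, "T")),
    copy = c("K1", "K1", "K2", "K2"),
    allele = c("al1", "al2", "al1", "al2"))
}

# junction context with an explicit planted match pattern around the junction:
# `pattern` is a logical vector, index i = agreement of donors at the i-th
# base after the junction; `pre` likewise before the junction (reversed order)
planted_junction <- function(pattern, pre = logical(0), flank = 30, seed = 99) {
  with_seed(seed, {
    n <- flank
    dl <- sample(c("A", "C", "G", "T"), 2 * n, replace = TRUE)
    dr <- sample(c("A", "C", "G", "T"), 2 * n, replace = TRUE)
    fix <- function(i_rel, want) {
      # i_rel > 0: bases after junction; i_rel <= 0: before
      il <- n + i_rel; ir <- n + i_rel
      if (want) dr[ir] <<- dl[il]
      else if (dr[ir] == dl[il]) dr[ir] <<- setdiff(c("A", "C", "G", "T"), dl[il])[1]
    }
    for (i in seq_along(pattern)) fix(i, pattern[i])
    if (length(pattern) < n) fix(length(pattern) + 1L, FALSE)
    for (i in seq_along(pre)) fix(1L - i, pre[i])
    if (length(pre) < n) fix(-length(pre), FALSE)
    junction_context_raw(paste(dl, collapse = ""), n,
                         paste(dr, collapse = ""), n, flank_window = n)
  })
}

# brute-force pair-counting oracle: naive substring scan per k-mer per mate
oracle_count_pairs <- function(r1, r2, kmers, both_orientations = TRUE) {
  vapply(kmers, function(km) {
    pats <- c(km, if (both_orientations) revcomp(km))
    hits <- mapply(function(a, b)
      any(vapply(pats, function(p)
        grepl(p, a, fixed = TRUE) || grepl(p, b, fixed = TRUE), logical(1))),
      r1, r2)
    sum(hits)
  }, integer(1))
}

# brute-force single-changepoint oracle over L/A labels
oracle_changepoint <- function(lab) {
  n <- length(lab)
  mism <- vapply(0:n, function(cp)
    sum(lab[seq_len(cp)] == "A") + sum(lab[setdiff(seq_len(n), seq_len(cp))] == "L"),
    numeric(1))
  rev_mism <- vapply(0:n, function(cp)
    sum(lab[seq_len(cp)] == "L") + sum(lab[setdiff(seq_len(n), seq_len(cp))] == "A"),
    numeric(1))
  list(best = min(mism), opt = which(mism == min(mism)) - 1L,
       rev_best = min(rev_mism))
}
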