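# Discriminating k-mer quantification of copy-level (MCE) and allele-level
# (ASE) expression of near-identical tandem paralogs.  Reference mapping of
# short RNA reads mismaps between copies; exact matching of designed 27-mers
# against raw read pairs avoids the reference bias entirely.

#' Multiple alignment of paralog transcript sequences for both alleles
#'
#' @param seqs character vector of aligned sequences ("-" for gaps), equal
#'   lengths
#' @param copy copy label per sequence (e.g. "C1", "C2", "C3")
#' @param allele allele label per sequence (e.g. "BEPA", "RABS")
#' @return object of class `paralog_alignment`
#' @export
paralog_alignment <- function(seqs, copy, allele) {
  if (length(unique(nchar(seqs))) != 1L) stop("aligned sequences must have equal length")
  if (length(seqs) != length(copy) || length(seqs) != length(allele))
    stop("copy and allele labels must match the number of sequences")
  if (anyDuplicated(paste(copy, allele))) stop("duplicate (copy, allele) rows")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  structure(list(mat = mat,
                 rows = data.frame(copy = copy, allele = allele,
                                   stringsAsFactors = FALSE)),
            class = "paralog_alignment")
}

#' Classify alignment columns
#'
#' Exhaustive, exclusive per-column classes: `gap` (any row gapped),
#' `invariant` (all bases equal), `copy` (copies differ, alleles within every
#' copy agree), `allele` (some copy's alleles differ, copies otherwise agree),
#' `other` (both kinds of variation).
#'
#' @param aln a `paralog_alignment`
#' @return character vector of classes, one per column
#' @export
classify_columns <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  copies <- aln$rows$copy
  apply(aln$mat, 2L, function(col) {
    if (any(col == "-")) return("gap")
    if (length(unique(col)) == 1L) return("invariant")
    per_copy <- split(col, copies)
    within <- any(vapply(per_copy, function(b) length(unique(b)) > 1L, logical(1)))
    consistent <- vapply(per_copy[!vapply(per_copy, function(b)
      length(unique(b)) > 1L, logical(1))], `[`, character(1), 1L)
    between <- length(unique(consistent)) > 1L
    if (!within && between) "copy"
    else if (within && !between) "allele"
    else "other"
  })
}

## does `col` carry a base unique to `target` copy vs all other copies
## (alleles of each copy agreeing)?
copy_diagnostic_for <- function(aln, col, target) {
  bases <- split(aln$mat[, col], aln$rows$copy)
  if (any(vapply(bases, function(b) length(unique(b)) > 1L, logical(1)))) return(FALSE)
  tb <- bases[[target]][1L]
  all(vapply(bases[names(bases) != target], function(b) b[1L] != tb, logical(1)))
}

## does `col` distinguish the two alleles of `target` copy?
allele_diagnostic_for <- function(aln, col, target) {
  sel <- aln$rows$copy == target
  length(unique(aln$mat[sel, col])) > 1L
}

new_kmer_set <- function(id, mode, copy, members, columns, window,
                         src = list()) {
  structure(list(id = id, mode = mode, copy = copy, k = nchar(members[[1L]]),
                 members = members, columns = columns, window = window,
                 src = src),
            class = "kmer_set")
}

#' Design discriminating k-mer sets from a paralog alignment
#'
#' MCE ("copy expression") sets are gap-free windows that target the
#' homologous position in every copy: they contain at least one
#' copy-discriminating column, no allele or mixed columns, and their per-copy
#' k-mers are pairwise distinct.  ASE sets target one copy and contain at
#' least one column distinguishing that copy's two alleles plus at least one
#' column distinguishing the copy from all others; members are the target
#' copy's per-allele k-mers.  Every qualifying window is enumerated, then
#' non-overlapping windows are kept greedily (left to right) per target.
#'
#' @param aln a `paralog_alignment`
#' @param mode "MCE" or "ASE"
#' @param k k-mer length (default 27)
#' @param target copy label for ASE design (default: every copy in turn)
#' @param keep_overlapping keep all qualifying windows instead of the greedy
#'   non-overlapping subset
#' @param min_gap minimum gap (bp) between retained windows; set it near the
#'   RNA fragment length to make set counts approximately independent
#' @return list of `kmer_set` objects (possibly empty)
#' @export
design_kmers <- function(aln, mode = c("MCE", "ASE"), k = 27L, target = NULL,
                         keep_overlapping = FALSE, min_gap = 0L) {
  mode <- match.arg(mode)
  cls <- classify_columns(aln)
  nc <- ncol(aln$mat)
  if (nc < k) return(list())
  gapfree_ok <- !vapply(seq_len(nc - k + 1L), function(s)
    any(cls[s:(s + k - 1L)] == "gap"), logical(1))
  sets <- list()
  row_kmer <- function(r, s) paste(aln$mat[r, s:(s + k - 1L)], collapse = "")
  if (mode == "MCE") {
    cand <- integer(0)
    for (s in which(gapfree_ok)) {
      win <- s:(s + k - 1L)
      if (!any(cls[win] == "copy")) next
      if (any(cls[win] %in% c("allele", "other"))) next
      cand <- c(cand, s)
    }
    keep <- if (keep_overlapping) cand else greedy_nonoverlap(cand, k, min_gap)
    for (s in keep) {
      win <- s:(s + k - 1L)
      copies <- unique(aln$rows$copy)
      members <- vapply(copies, function(cp)
        row_kmer(which(aln$rows$copy == cp)[1L], s), character(1))
      if (anyDuplicated(members)) next  # must distinguish all copies pairwise
      sets[[length(sets) + 1L]] <- new_kmer_set(
        id = sprintf("MCE_%04d", s), mode = "MCE", copy = NA_character_,
        members = as.list(members), columns = win[cls[win] == "copy"],
        window = s,
        src = list(rows = vapply(copies, function(cp)
          which(aln$rows$copy == cp)[1L], integer(1))))
    }
  } else {
    targets <- if (is.null(target)) unique(aln$rows$copy) else target
    for (tg in targets) {
      alleles <- aln$rows$allele[aln$rows$copy == tg]
      if (length(alleles) < 2L) next
      cand <- integer(0)
      for (s in which(gapfree_ok)) {
        win <- s:(s + k - 1L)
        has_allele <- any(vapply(win, function(cc)
          allele_diagnostic_for(aln, cc, tg), logical(1)))
        has_copy <- any(vapply(win, function(cc)
          copy_diagnostic_for(aln, cc, tg), logical(1)))
        if (has_allele && has_copy) cand <- c(cand, s)
      }
      keep <- if (keep_overlapping) cand else greedy_nonoverlap(cand, k, min_gap)
      for (s in keep) {
        win <- s:(s + k - 1L)
        rows <- which(aln$rows$copy == tg)
        members <- setNames(lapply(rows, row_kmer, s = s), aln$rows$allele[rows])
        if (length(unique(unlist(members))) < 2L) next
        sets[[length(sets) + 1L]] <- new_kmer_set(
          id = sprintf("ASE_%s_%04d", tg, s), mode = "ASE", copy = tg,
          members = members, columns = win, window = s,
          src = list(rows = setNames(rows, aln$rows$allele[rows])))
      }
    }
  }
  sets
}

greedy_nonoverlap <- function(starts, k, min_gap = 0L) {
  starts <- sort(starts)
  keep <- integer(0); last_end <- -Inf
  for (s in starts) {
    if (s > last_end + min_gap) { keep <- c(keep, s); last_end <- s + k - 1L }
  }
  keep
}

## ungapped coordinate of aligned column `col` within row `r` (NA if gapped)
ungapped_pos <- function(aln, r, col) {
  if (aln$mat[r, col] == "-") return(NA_integer_)
  sum(aln$mat[r, seq_len(col)] != "-")
}

#' Screen candidate k-mer sets against reference genomes and transcript ends
#'
#' A set is retained only if every member has zero perfect off-target matches
#' and at most `max_one_mismatch` off-target matches with a single mismatch
#' (both strands searched), and lies at least `min_end_dist` bp from both ends
#' of its source transcript.  Matches falling inside `on_target` intervals --
#' the homologous positions of the cluster across copies and alleles -- are
#' not counted as off-target.
#'
#' @param sets list of `kmer_set`
#' @param genomes named character vector (or DNAStringSet) of reference
#'   sequences
#' @param on_target data.frame with columns `seqname`, `start`, `end`
#'   (1-based inclusive) marking the paralog cluster in each genome
#' @param aln the source `paralog_alignment` (for transcript-end distances);
#'   NULL skips the end-distance rule
#' @param max_one_mismatch maximum tolerated 1-mismatch off-target matches
#' @param min_end_dist minimum distance from either transcript end (bp)
#' @return the retained subset of `sets`, with a `screen` attribute holding
#'   the per-set decision table
#' @export
screen_kmers <- function(sets, genomes, on_target = NULL, aln = NULL,
                         max_one_mismatch = 5L, min_end_dist = 100L) {
  gen <- if (inherits(genomes, "DNAStringSet")) genomes
         else Biostrings::DNAStringSet(genomes)
  decisions <- lapply(sets, function(set) {
    for (mi in seq_along(set$members)) {
      km <- set$members[[mi]]
      hits0 <- off_target_hits(km, gen, on_target, max_mismatch = 0L)
      if (hits0 > 0L) return(list(keep = FALSE, reason = "perfect off-target match"))
      hits1 <- off_target_hits(km, gen, on_target, max_mismatch = 1L) - hits0
      if (hits1 > max_one_mismatch)
        return(list(keep = FALSE, reason = sprintf("%d one-mismatch off-target matches", hits1)))
    }
    if (!is.null(aln)) {
      for (r in unique(unlist(set$src$rows))) {
        s_un <- ungapped_pos(aln, r, set$window)
        e_un <- ungapped_pos(aln, r, set$window + set$k - 1L)
        tlen <- sum(aln$mat[r, ] != "-")
        if (is.na(s_un) || is.na(e_un)) return(list(keep = FALSE, reason = "gapped member"))
        if ((s_un - 1L) < min_end_dist || (tlen - e_un) < min_end_dist)
          return(list(keep = FALSE, reason = "too close to transcript end"))
      }
    }
    list(keep = TRUE, reason = "pass")
  })
  keep <- vapply(decisions, `[[`, logical(1), "keep")
  out <- sets[keep]
  attr(out, "screen") <- data.frame(
    id = vapply(sets, `[[`, character(1), "id"),
    keep = keep,
    reason = vapply(decisions, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  out
}

## count matches of `km` in `gen` (both strands) outside on_target intervals
off_target_hits <- function(km, gen, on_target, max_mismatch = 0L) {
  total <- 0L
  pats <- c(km, revcomp(km))
  for (si in seq_along(gen)) {
    sn <- names(gen)[si]
    iv <- if (!is.null(on_target)) on_target[on_target$seqname == sn, , drop = FALSE]
    for (p in unique(pats)) {
      m <- Biostrings::matchPattern(p, gen[[si]], max.mismatch = max_mismatch)
      if (length(m) == 0L) next
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      if (!is.null(iv) && nrow(iv)) {
        inside <- rep(FALSE, length(st))
        for (j in seq_len(nrow(iv)))
          inside <- inside | (st >= iv$start[j] & en <= iv$end[j])
        total <- total + sum(!inside)
      } else total <- total + length(st)
    }
  }
  total
}

#' Count read pairs matching k-mer set members
#'
#' Exact substring matching of every member against each mate (and, by
#' default, its reverse complement).  A pair increments a member's count at
#' most once, however many times or in however many mates the k-mer occurs.
#'
#' @param r1,r2 synchronized mate sequences (equal length character vectors)
#' @param sets list of `kmer_set`
#' @param both_orientations also search reverse complements (default TRUE;
#'   set FALSE for strand-specific matching)
#' @return object of class `kmer_counts`: list with `counts` data.frame
#'   (set_id, mode, copy, member, count) and `total_pairs`
#' @export
count_pairs <- function(r1, r2, sets, both_orientations = TRUE) {
  if (length(r1) != length(r2)) stop("desynchronized mate files: unequal pair counts")
  members <- unlist(lapply(sets, function(s) unlist(s$members)), use.names = FALSE)
  meta <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_id = s$id, mode = s$mode, copy = s$copy,
               member = names(s$members), stringsAsFactors = FALSE)))
  n <- length(r1)
  if (n == 0L || length(members) == 0L)
    return(structure(list(counts = cbind(meta, count = integer(nrow(meta))),
                          total_pairs = n), class = "kmer_counts"))
  hit <- matrix(FALSE, length(members), n)
  dicts <- list(members)
  if (both_orientations) dicts <- c(dicts, list(revcomp(members)))
  for (mate in list(r1, r2)) {
    subj <- Biostrings::DNAStringSet(mate)
    for (d in dicts) {
      pd <- Biostrings::PDict(d)
      cnt <- Biostrings::vcountPDict(pd, subj)
      hit <- hit | (cnt > 0L)
    }
  }
  structure(list(counts = cbind(meta, count = as.integer(rowSums(hit))),
                 total_pairs = n),
            class = "kmer_counts")
}

#' Reads-per-million expression per copy from MCE k-mer counts
#'
#' RPM = detections / total pairs x 1e6 per set, then averaged across sets.
#' MCE sets quantify each copy through its own member, so the per-copy RPM is
#' the mean of that copy's member RPMs over all sets.
#'
#' @param counts a `kmer_counts` from MCE sets
#' @return data.frame with copy, rpm, n_sets
#' @export
mce_rpm <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (counts$total_pairs <= 0L) stop("total_pairs must be > 0")
  df <- counts$counts[counts$counts$mode == "MCE", , drop = FALSE]
  df$rpm <- df$count / counts$total_pairs * 1e6
  agg <- stats::aggregate(rpm ~ member, df, mean)
  nst <- stats::aggregate(rpm ~ member, df, length)
  data.frame(copy = agg$member, rpm = agg$rpm, n_sets = nst$rpm,
             stringsAsFactors = FALSE)
}

#' Allele-specific expression proportion with QC
#'
#' Per copy: every set must be detected (total count >= 1), both alleles must
#' have at least `min_each` reads overall, and the grand total must reach
#' `min_total`; otherwise the QC fails with a recorded reason.  On pass, the
#' per-set proportion allele1 / (allele1 + allele2) is averaged across sets.
#'
#' @param counts a `kmer_counts` from ASE sets
#' @param allele1 name of the focal allele (numerator)
#' @param min_total minimum summed reads per copy (default 100)
#' @param min_each minimum reads per allele (default 1)
#' @return data.frame per copy: proportion_allele1, qc_pass, reason,
#'   n_sets_used, total_reads
#' @export
ase_proportion <- function(counts, allele1, min_total = 100L, min_each = 1L) {
  stopifnot(inherits(counts, "kmer_counts"))
  df <- counts$counts[counts$counts$mode == "ASE", , drop = FALSE]
  out <- lapply(split(df, df$copy), function(d) {
    copy <- d$copy[1L]
    alleles <- unique(d$member)
    a2 <- setdiff(alleles, allele1)
    if (!allele1 %in% alleles || length(a2) != 1L)
      return(data.frame(copy = copy, proportion_allele1 = NA_real_,
                        qc_pass = FALSE, reason = "allele labels not resolvable",
                        n_sets_used = 0L, total_reads = sum(d$count)))
    set_tot <- tapply(d$count, d$set_id, sum)
    tot1 <- sum(d$count[d$member == allele1])
    tot2 <- sum(d$count[d$member == a2])
    reason <- if (tot1 + tot2 < min_total) "min total reads"
      else if (tot1 < min_each || tot2 < min_each) "min reads per allele"
      else if (any(set_tot < 1L)) "k-mer set undetected"
      else NA_character_
    if (!is.na(reason))
      return(data.frame(copy = copy, proportion_allele1 = NA_real_,
                        qc_pass = FALSE, reason = reason,
                        n_sets_used = 0L, total_reads = tot1 + tot2))
    per_set <- vapply(split(d, d$set_id), function(s)
      s$count[s$member == allele1] / sum(s$count), numeric(1))
    data.frame(copy = copy, proportion_allele1 = mean(per_set),
               qc_pass = TRUE, reason = NA_character_,
               n_sets_used = length(per_set), total_reads = tot1 + tot2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Test allele-specific expression proportions against a null
#'
#' One-sample Wilcoxon signed-rank test of replicate proportions against
#' `mu` (default 0.5, no allelic imbalance); exact for n <= 15.  With `y`
#' supplied, a two-sample rank-sum comparison between conditions is run
#' instead.
#'
#' @param x numeric proportions across replicates
#' @param mu null proportion for the one-sample test
#' @param y optional second condition for a two-sample comparison
#' @param alternative test sidedness
#' @return list with p_value, statistic, n, method, flag
#' @export
ase_test <- function(x, mu = 0.5, y = NULL, alternative = "two.sided") {
  x <- x[is.finite(x)]
  if (length(x) < 1L) stop("at least one finite proportion required")
  if (!is.null(y)) {
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                              exact = length(x) <= 15L && length(y) <= 15L))
    return(list(p_value = ht$p.value, statistic = unname(ht$statistic),
                n = c(length(x), length(y)), method = ht$method, flag = NA_character_))
  }
  if (all(x == mu)) {
    warning("all values equal mu; test uninformative")
    return(list(p_value = 1, statistic = NA_real_, n = length(x),
                method = "signed rank (degenerate)", flag = "all values equal mu"))
  }
  flag <- if (length(x) == 1L) "single replicate: uninformative" else NA_character_
  ht <- suppressWarnings(stats::wilcox.test(x, mu = mu, alternative = alternative,
                                            exact = length(x) <= 15L))
  list(p_value = ht$p.value, statistic = unname(ht$statistic), n = length(x),
       method = ht$method, flag = flag)
}

#' Expected allele proportion under copy-proportional expression
#'
#' If each gene copy contributes equally, an allele carrying `n1` copies in a
#' diploid with `n2` copies on the other allele is expected at
#' n1 / (n1 + n2) of transcripts: the dosage prediction against which
#' measured ASE is compared (3:1 copies -> 75%).
#'
#' @param copies_allele1,copies_allele2 copy counts on each allele
#' @return expected proportion of allele 1
#' @export
dosage_expected_proportion <- function(copies_allele1, copies_allele2) {
  if (copies_allele1 < 0 || copies_allele2 < 0 || copies_allele1 + copies_allele2 == 0)
    stop("copy counts must be non-negative and not both zero")
  copies_allele1 / (copies_allele1 + copies_allele2)
}
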