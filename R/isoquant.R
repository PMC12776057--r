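# Attribution of full-length transcript reads to individual near-identical
# gene copies via an ordered key of informative variants, with a full-span
# requirement: a read counts only if it covers the whole keyed interval and
# matches exactly one copy's base profile at every key position.

#' Build a variant key distinguishing gene copies
#'
#' Collects every column of the (gap-free, equal-length) copy alignment
#' within the span interval at which at least two copies differ, and verifies
#' that the resulting profiles distinguish every pair of copies.
#'
#' @param copy_seqs named character vector of aligned copy sequences
#' @param span c(lo, hi), 1-based inclusive interval a read must fully cover
#'   (defaults to the whole alignment)
#' @return object of class `variant_key`: positions, per-copy profile matrix,
#'   span
#' @export
informative_variants <- function(copy_seqs, span = NULL) {
  if (length(copy_seqs) < 2L) stop("at least two copies required")
  if (length(unique(nchar(copy_seqs))) != 1L) stop("copies must be aligned to equal length")
  n <- nchar(copy_seqs[1L])
  if (is.null(span)) span <- c(1L, n)
  span <- as.integer(span)
  if (span[1] < 1L || span[2] > n || span[1] > span[2]) stop("span outside the alignment")
  mat <- do.call(rbind, strsplit(toupper(copy_seqs), "", fixed = TRUE))
  rownames(mat) <- names(copy_seqs)
  if (any(mat[, span[1]:span[2]] == "-")) stop("keyed interval must be gap-free")
  cols <- span[1]:span[2]
  pos <- cols[apply(mat[, cols, drop = FALSE], 2L, function(cc) length(unique(cc)) > 1L)]
  prof <- mat[, pos, drop = FALSE]
  cps <- rownames(prof)
  for (i in seq_len(length(cps) - 1L)) for (j in seq(i + 1L, length(cps))) {
    if (all(prof[i, ] == prof[j, ]))
      stop(sprintf("copies %s and %s are indistinguishable within the span",
                   cps[i], cps[j]))
  }
  structure(list(positions = pos, profiles = prof, span = span,
                 copy_seqs = copy_seqs),
            class = "variant_key")
}

#' Largest span whose flanks can serve as copy-invariant anchors
#'
#' Shrinks the full alignment inward until the first and last `anchor_len`
#' columns of the span are identical across copies, so coordinate-free
#' anchored matching can locate reads.  Variants falling outside the span are
#' not keyed.
#'
#' @param copy_seqs named character vector of aligned copy sequences
#' @param anchor_len anchor length (default 20)
#' @return c(lo, hi), 1-based inclusive
#' @export
span_with_anchors <- function(copy_seqs, anchor_len = 20L) {
  mat <- do.call(rbind, strsplit(toupper(copy_seqs), "", fixed = TRUE))
  inv <- apply(mat, 2L, function(cc) length(unique(cc)) == 1L && cc[1L] != "-")
  n <- length(inv)
  run_ok <- function(s) all(inv[s:(s + anchor_len - 1L)])
  lo <- 1L
  while (lo + anchor_len - 1L <= n && !run_ok(lo)) lo <- lo + 1L
  hi <- n
  while (hi - anchor_len + 1L >= lo && !run_ok(hi - anchor_len + 1L)) hi <- hi - 1L
  if (lo + 2L * anchor_len - 1L > hi) stop("no span with invariant flanks found")
  c(lo, hi)
}

## locate the span within a read by exact anchored search: the anchors are the
## copy-invariant flanks of the span.  Returns the read index of span lo, or
## NA if the read does not (fully and colinearly) contain the span.
locate_span <- function(read, key, anchor_len) {
  lo <- key$span[1]; hi <- key$span[2]
  a5 <- substr(key$copy_seqs[1L], lo, lo + anchor_len - 1L)
  a3 <- substr(key$copy_seqs[1L], hi - anchor_len + 1L, hi)
  p5 <- regexpr(a5, read, fixed = TRUE)
  if (p5 < 0L) return(NA_integer_)
  expected3 <- p5 + (hi - anchor_len + 1L) - lo
  if (expected3 + anchor_len - 1L > nchar(read)) return(NA_integer_)
  if (substr(read, expected3, expected3 + anchor_len - 1L) != a3) return(NA_integer_)
  as.integer(p5)
}

#' Attribute full-length reads to gene copies
#'
#' A read is assigned to a copy iff it fully spans the keyed interval and its
#' bases at all key positions match exactly one copy's profile (allowing up
#' to `max_key_mismatch` mismatches, default 0: a read failing even one key
#' position is "conflicting", not rescued).  Reads are located in the keyed
#' coordinate system by exact anchored search of the span's copy-invariant
#' flanks; both orientations are tried.
#'
#' @param reads character vector of long reads
#' @param key a `variant_key`
#' @param require_full_span drop reads not covering the span (always recorded
#'   under reason "not spanning")
#' @param max_key_mismatch tolerated profile mismatches for an assignment
#' @param anchor_len anchor length for span location; the span flanks of this
#'   length must be copy-invariant
#' @param both_orientations also try the reverse complement of each read
#' @return object of class `attribution_counts`: per-copy counts, unassigned
#'   counts by reason, proportions over assigned reads, per-read table
#' @export
attribute_reads <- function(reads, key, require_full_span = TRUE,
                            max_key_mismatch = 0L, anchor_len = 20L,
                            both_orientations = TRUE) {
  stopifnot(inherits(key, "variant_key"))
  lo <- key$span[1]; hi <- key$span[2]
  if (hi - lo + 1L < 2L * anchor_len) stop("span too short for the anchors")
  mat <- do.call(rbind, strsplit(toupper(key$copy_seqs), "", fixed = TRUE))
  flank5 <- lo:(lo + anchor_len - 1L); flank3 <- (hi - anchor_len + 1L):hi
  inv5 <- all(apply(mat[, flank5, drop = FALSE], 2L, function(cc) length(unique(cc)) == 1L))
  inv3 <- all(apply(mat[, flank3, drop = FALSE], 2L, function(cc) length(unique(cc)) == 1L))
  if (!inv5 || !inv3)
    stop("span flanks are not copy-invariant; choose a different span or anchor_len")
  copies <- rownames(key$profiles)
  assign_one <- function(read) {
    cand <- c(read, if (both_orientations) revcomp(read))
    for (r in cand) {
      at <- locate_span(r, key, anchor_len)
      if (is.na(at)) next
      bases <- substring(r, at + key$positions - lo, at + key$positions - lo)
      mm <- apply(key$profiles, 1L, function(p) sum(p != bases))
      hits <- which(mm <= max_key_mismatch)
      if (length(hits) == 1L) return(copies[hits])
      if (length(hits) > 1L) return("__ambiguous")
      return("__conflicting")
    }
    "__not_spanning"
  }
  res <- vapply(reads, assign_one, character(1), USE.NAMES = FALSE)
  assigned <- res[!startsWith(res, "__")]
  counts <- table(factor(assigned, levels = copies))
  unassigned <- c(`not spanning` = sum(res == "__not_spanning"),
                  ambiguous = sum(res == "__ambiguous"),
                  conflicting = sum(res == "__conflicting"))
  props <- if (length(assigned)) as.numeric(counts) / length(assigned) else
    rep(NA_real_, length(copies))
  structure(list(counts = setNames(as.integer(counts), copies),
                 unassigned = unassigned,
                 proportions = setNames(props, copies),
                 n_total = length(reads), n_assigned = length(assigned),
                 reads = data.frame(read = seq_along(reads), result = res,
                                    stringsAsFactors = FALSE)),
            class = "attribution_counts")
}
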