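# Mechanistic inference of copy-number expansion: microhomology at
# MMBIR-style junctions, and NAHR crossover windows from the L/A mosaic
# structure of intermediate duplication copies.

#' Junction context for microhomology analysis
#'
#' Describes a duplication junction through its two donor loci: the left
#' donor carries the sequence the junction's 5' side derives from (with the
#' homologous junction offset: number of donor bases before the junction) and
#' the right donor likewise for the 3' side.
#'
#' @param donor_left,donor_right donor sequences (character scalars)
#' @param offset_left,offset_right bases of each donor preceding the junction
#' @param flank_window how far the scan may extend on each side (default: to
#'   the donor limits)
#' @return object of class `junction_context`
#' @export
junction_context_raw <- function(donor_left, offset_left, donor_right,
                                 offset_right, flank_window = NULL) {
  if (nchar(donor_left) == 0L || nchar(donor_right) == 0L) stop("empty donor sequence")
  if (offset_left < 0L || offset_left > nchar(donor_left) ||
      offset_right < 0L || offset_right > nchar(donor_right))
    stop("donor offsets must lie within the donors")
  if (!is.null(flank_window) && flank_window < 1L) stop("flank_window must be >= 1")
  structure(list(donor_left = donor_left, offset_left = as.integer(offset_left),
                 donor_right = donor_right, offset_right = as.integer(offset_right),
                 flank_window = flank_window),
            class = "junction_context")
}

#' Junction context from a forged haplotype truth record
#'
#' Builds the SYT19/C2 fusion-junction context of an expanded haplotype: the
#' left donor is the natural SYT19 locus (unit end running into the SYT19
#' tail), the right donor the natural C2 locus (C2 head running into the unit
#' start).
#'
#' @param hap a `haplotype_truth` with at least one junction
#' @param flank bases of context taken on each side
#' @return a `junction_context`
#' @export
junction_context <- function(hap, flank = 40L) {
  stopifnot(inherits(hap, "haplotype_truth"))
  if (length(hap$junctions) == 0L) stop("haplotype has no junction")
  u <- nrow(hap$units)
  last_end <- hap$units$end[u]          # SYT19 tail starts after this
  first_start <- hap$units$start[1L]    # C2 head ends before this
  dl <- substr(hap$sequence, last_end - flank + 1L, last_end + flank)
  dr <- substr(hap$sequence, first_start - flank, first_start + flank - 1L)
  junction_context_raw(dl, flank, dr, flank, flank_window = flank)
}

#' Microhomology at a duplication junction
#'
#' `perfect_len` is the length of the maximal window spanning the junction
#' over which the two donors are identical; `imperfect_len` the length of the
#' maximal window containing the perfect core with at most `mismatch_budget`
#' mismatches.  Both are found by exhaustive window scan over the flank
#' window.
#'
#' @param ctx a `junction_context`
#' @param mismatch_budget mismatches allowed in the imperfect window
#' @return list: perfect_len, imperfect_len, mismatch_budget, perfect_core
#'   and imperfect_window in junction-relative coordinates (position 1 is the
#'   first base after the junction, 0 the last before it)
#' @export
junction_microhomology <- function(ctx, mismatch_budget = 1L) {
  stopifnot(inherits(ctx, "junction_context"))
  back <- min(ctx$offset_left, ctx$offset_right)
  fwd <- min(nchar(ctx$donor_left) - ctx$offset_left,
             nchar(ctx$donor_right) - ctx$offset_right)
  if (!is.null(ctx$flank_window)) {
    back <- min(back, ctx$flank_window); fwd <- min(fwd, ctx$flank_window)
  }
  if (back + fwd == 0L) stop("no comparable bases around the junction")
  dl <- seq_chars(ctx$donor_left); dr <- seq_chars(ctx$donor_right)
  ii <- seq.int(1L - back, fwd)                       # 0 = last pre-junction base
  m <- dl[ctx$offset_left + ii] == dr[ctx$offset_right + ii]
  names(m) <- ii
  at <- function(i) m[[as.character(i)]]
  b <- 0L; while (b < back && at(-b)) b <- b + 1L
  f <- 0L; while (f < fwd && at(f + 1L)) f <- f + 1L
  perfect <- b + f
  core <- c(1L - b, f)                                # empty iff perfect == 0
  best_len <- perfect; best_win <- core
  ## the window must contain the perfect core; with an empty core it must
  ## still straddle the junction (at least one base on each side)
  a_max <- if (perfect == 0L) 0L else 1L - b
  c_min <- if (perfect == 0L) 1L else f
  for (a in seq.int(1L - back, a_max)) {
    for (cc in seq.int(c_min, fwd)) {
      if (cc < a) next
      win <- seq.int(a, cc)
      if (sum(!m[as.character(win)]) <= mismatch_budget && length(win) > best_len) {
        best_len <- length(win); best_win <- c(a, cc)
      }
    }
  }
  list(perfect_len = perfect, imperfect_len = best_len,
       mismatch_budget = as.integer(mismatch_budget),
       perfect_core = core, imperfect_window = best_win)
}

#' Columns at which the A and L duplication regions diverge
#'
#' Gap-containing columns are removed first; among the remaining columns
#' those where the A row differs from the L row are reported.  Columns where
#' only intermediates vary are uninformative and excluded by construction.
#'
#' @param aln named character vector of aligned duplication-region sequences;
#'   must contain rows named `A` and `L` (any other rows are intermediates)
#' @return data.frame: pos (position in the gap-removed alignment),
#'   pos_alignment (original column), a_base, l_base
#' @export
divergent_columns <- function(aln) {
  if (!all(c("A", "L") %in% names(aln))) stop("alignment must contain rows 'A' and 'L'")
  if (length(unique(nchar(aln))) != 1L) stop("rows must have equal aligned length")
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  no_gap <- colSums(mat == "-") == 0L
  kept <- which(no_gap)
  a <- mat["A", kept]; l <- mat["L", kept]
  sel <- a != l
  data.frame(pos = which(sel), pos_alignment = kept[sel],
             a_base = a[sel], l_base = l[sel], stringsAsFactors = FALSE)
}

#' Label intermediate-copy bases as A-like, L-like or other
#'
#' @param cols data.frame from [divergent_columns()]
#' @param aln the same alignment
#' @param row name of the intermediate row to classify
#' @return `cols` with added columns `base` and `label` in {"A","L","other"}
#' @export
classify_intermediate <- function(cols, aln, row) {
  if (!row %in% names(aln)) stop("row not in alignment: ", row)
  b <- seq_chars(toupper(aln[[row]]))[cols$pos_alignment]
  lab <- ifelse(b == cols$a_base, "A", ifelse(b == cols$l_base, "L", "other"))
  cbind(cols, base = b, label = lab, stringsAsFactors = FALSE)
}

#' Infer the NAHR crossover window from an L/A label sequence
#'
#' Fits a two-state single-changepoint model by exhaustive scan: positions up
#' to the changepoint are modelled L, positions after it A (the orientation
#' NAHR intermediates must show).  The window is bounded by the informative
#' columns adjacent to the optimal changepoint; with ties, it is the union
#' over all optimal changepoints.  Residual mismatches at the optimum are
#' reported as putative gene-conversion tracts.  Label sequences that fit the
#' reversed (A then L) model strictly better are flagged non-canonical; all-L
#' or all-A sequences give a degenerate window at the sequence end.
#'
#' @param labels character vector in {"A","L","other"} ("other" is excluded
#'   from the fit)
#' @param positions numeric positions of the labels (default 1..n)
#' @return object of class `crossover_window`: window c(lo, hi) (half-open,
#'   [lo, hi)), changepoints, mismatches, residual_positions, degenerate,
#'   orientation, labels
#' @export
infer_crossover_window <- function(labels, positions = seq_along(labels)) {
  if (length(labels) != length(positions)) stop("labels/positions length mismatch")
  keep <- labels %in% c("A", "L")
  lab <- labels[keep]; pos <- positions[keep]
  n <- length(lab)
  if (n < 2L) stop("at least 2 informative labels required")
  isA <- cumsum(lab == "A"); isL <- cumsum(lab == "L")
  mism <- vapply(0:n, function(cp)      # A's in the L segment + L's in the A segment
    (if (cp > 0L) isA[cp] else 0L) + (isL[n] - (if (cp > 0L) isL[cp] else 0L)),
    numeric(1))
  rev_mism <- vapply(0:n, function(cp)
    (if (cp > 0L) isL[cp] else 0L) + (isA[n] - (if (cp > 0L) isA[cp] else 0L)),
    numeric(1))
  best <- min(mism)
  if (min(rev_mism) < best) {
    return(structure(list(window = NULL, changepoints = integer(0),
                          mismatches = NA_integer_, residual_positions = numeric(0),
                          degenerate = FALSE, orientation = "non-canonical",
                          labels = data.frame(position = pos, label = lab)),
                     class = "crossover_window"))
  }
  opt <- which(mism == best) - 1L       # changepoint = count of leading-L slots
  degenerate <- all(opt == 0L) || all(opt == n)
  lo <- if (min(opt) >= 1L) pos[min(opt)] else pos[1L]
  hi <- if (max(opt) < n) pos[max(opt) + 1L] else pos[n]
  cp0 <- opt[1L]
  resid <- pos[c(which(lab[seq_len(cp0)] == "A"),
                 if (cp0 < n) cp0 + which(lab[seq.int(cp0 + 1L, n)] == "L"))]
  structure(list(window = c(lo = lo, hi = hi), changepoints = opt,
                 mismatches = best, residual_positions = resid,
                 degenerate = degenerate, orientation = "canonical",
                 labels = data.frame(position = pos, label = lab)),
            class = "crossover_window")
}

#' Group assemblies by shared crossover windows
#'
#' Assemblies whose windows overlap (transitively) form one group; the number
#' of groups is the inferred minimum number of independent expansion events.
#'
#' @param windows named list of c(lo, hi) windows (or `crossover_window`
#'   objects) in a common alignment coordinate system
#' @return list with `groups` (data.frame assembly, group) and `n_events`
#' @export
compare_crossovers <- function(windows) {
  w <- lapply(windows, function(x) if (inherits(x, "crossover_window")) x$window else x)
  if (any(vapply(w, is.null, logical(1)))) stop("non-canonical window cannot be compared")
  n <- length(w)
  if (n == 0L) stop("no windows supplied")
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && w[[i]][1] < w[[j]][2] && w[[j]][1] < w[[i]][2])
      grp[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- match(root, unique(root))
  list(groups = data.frame(assembly = names(windows), group = ids,
                           stringsAsFactors = FALSE),
       n_events = length(unique(ids)))
}
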