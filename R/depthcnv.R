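# Read-depth copy-number estimation over a masked duplication cluster,
# calibrated against simulated haplotype read sets, plus the ecotype /
# latitude / time-trend statistics applied to normalized depths.

as_coverage <- function(coverage) {
  if (is.data.frame(coverage)) {
    if (!all(c("pos", "depth") %in% names(coverage)))
      stop("coverage data.frame needs columns 'pos' and 'depth'")
    v <- numeric(max(coverage$pos))
    v[coverage$pos] <- coverage$depth
    v
  } else as.numeric(coverage)
}

mask_positions <- function(mask, n) {
  if (is.null(mask)) return(integer(0))
  if (is.data.frame(mask)) {
    if (any(mask$start < 1L) || any(mask$end > n))
      stop("mask intervals outside sequence bounds")
    unlist(Map(seq.int, mask$start, mask$end))
  } else stop("mask must be NULL or a data.frame with start/end")
}

#' Mean read depth over a region, excluding masked positions
#'
#' Masked bases are excluded from both the numerator and the denominator, the
#' equivalent of hard-masking before coverage accumulation.  Masking is
#' idempotent: masking an interval twice equals masking it once.
#'
#' @param coverage per-base coverage: numeric vector (index = position) or a
#'   data.frame with columns `pos`, `depth`
#' @param region c(start, end), 1-based inclusive
#' @param mask optional data.frame of intervals (`start`, `end`) to exclude
#' @return mean per-base coverage (numeric scalar)
#' @export
region_depth <- function(coverage, region, mask = NULL) {
  v <- as_coverage(coverage)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > length(v) || region[1] > region[2])
    stop("region outside the coverage track")
  pos <- setdiff(seq.int(region[1], region[2]), mask_positions(mask, length(v)))
  if (length(pos) == 0L) stop("region fully masked: mean depth undefined")
  mean(v[pos])
}

#' Normalize a region depth by a baseline depth
#'
#' The baseline is the mean autosomal depth for individual samples, or the
#' mean ChrXIX depth for pooled samples with unknown sex ratios; the mode is
#' recorded with the value.
#'
#' @param region_mean mean depth over the target region
#' @param baseline_mean mean baseline depth (> 0)
#' @param mode "autosome" or "chrXIX"
#' @return list with `value` and `mode`, class `normalized_depth`
#' @export
normalize_depth <- function(region_mean, baseline_mean, mode = c("autosome", "chrXIX")) {
  mode <- match.arg(mode)
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be > 0")
  structure(list(value = region_mean / baseline_mean, mode = mode),
            class = "normalized_depth")
}

## project positions on a multi-unit haplotype onto the collapsed reference in
## which all duplication units pile onto unit 1 (the in-silico equivalent of
## hard-masking the extra duplication regions before remapping)
project_positions <- function(pos, hap) {
  u <- nrow(hap$units); L <- hap$layout$unit_len
  first <- hap$units$start[1L]; last <- hap$units$end[u]
  out <- pos
  inunit <- pos >= first & pos <= last
  out[inunit] <- first + (pos[inunit] - first) %% L
  after <- pos > last
  out[after] <- pos[after] - (u - 1L) * L
  out
}

#' Collapsed-reference coverage of simulated pairs
#'
#' Projects every simulated read of a pair set onto the collapsed (3-copy
#' layout) reference of its source haplotype and accumulates per-base
#' coverage.  All haplotypes in `haps` must share the base layout.
#'
#' @param pairs a `read_pairs` whose info labels match names of `haps`
#' @param haps named list of `haplotype_truth` objects (one per pool label)
#' @return numeric per-base coverage over the collapsed reference
#' @export
collapsed_coverage <- function(pairs, haps) {
  stopifnot(inherits(pairs, "read_pairs"))
  ref_len <- unique(vapply(haps, function(h)
    nchar(h$sequence) - (nrow(h$units) - 1L) * h$layout$unit_len, numeric(1)))
  if (length(ref_len) != 1L) stop("haplotypes do not share a collapsed layout")
  rl <- pairs$params$read_len_bp
  cov <- numeric(ref_len)
  for (lab in unique(pairs$info$label)) {
    hap <- haps[[lab]]
    if (is.null(hap)) stop("no haplotype truth for pool label ", lab)
    info <- pairs$info[pairs$info$label == lab, , drop = FALSE]
    s <- c(info$start, info$end - rl + 1L)
    e <- c(info$start + rl - 1L, info$end)
    pos <- unlist(Map(seq.int, s, e), use.names = FALSE)
    pos <- project_positions(pos, hap)
    cov <- cov + tabulate(pos, nbins = ref_len)
  }
  cov
}

## C3-vs-baseline normalized depth of a simulated genome (1 or 2 haplotypes).
## The baseline is every single-copy position of the collapsed reference (the
## analogue of mean autosomal / mean chromosome depth), with a short margin
## trimmed at the sequence ends where fragment placement thins coverage.
hap_norm_depth <- function(haps, params, mode = c("autosome", "chrXIX"),
                           edge_margin = 200L) {
  mode <- match.arg(mode)
  haps <- if (inherits(haps, "haplotype_truth")) list(haps) else haps
  names(haps) <- paste0("hap", seq_along(haps))
  pool <- weighted_pool(names(haps),
                        vapply(haps, function(h) h$sequence, character(1)))
  pairs <- simulate_paired_reads(pool, params)
  cov <- collapsed_coverage(pairs, haps)
  lay <- forge_layout(haps[[1L]]$spec, 1L)
  c3 <- unlist(lay$copies[lay$copies$label == "C3A", c("start", "end")])
  base_region <- c(edge_margin, lay$total - edge_margin)
  base_mask <- data.frame(start = lay$units$start[1L], end = lay$units$end[1L])
  normalize_depth(region_depth(cov, c3),
                  region_depth(cov, base_region, mask = base_mask), mode)$value
}

#' Build a copy-number calibration table from simulated haplotype depths
#'
#' For each provided copy count, reads are simulated from each haplotype,
#' depth over the C3 gene is normalized by the baseline region through the
#' same depth path used for samples, and values are averaged across the
#' haplotypes of that count.  A non-monotone table signals a masking or
#' projection misconfiguration and is an error.
#'
#' @param haps_by_count named list: copy count -> list of `haplotype_truth`
#' @param sim_params a `read_sim_params` template (seed is offset per entry)
#' @param mode baseline mode, see [normalize_depth()]
#' @param n_reps simulation replicates per haplotype, averaged into the entry
#' @return data.frame with columns copy_count, expected_depth, n_haplotypes
#' @export
build_call_table <- function(haps_by_count, sim_params,
                             mode = c("autosome", "chrXIX"), n_reps = 1L) {
  mode <- match.arg(mode)
  if (length(haps_by_count) < 2L)
    stop("at least 2 distinct copy counts are required to calibrate")
  counts <- as.integer(names(haps_by_count))
  if (anyNA(counts)) stop("haps_by_count must be named by copy count")
  ord <- order(counts)
  rows <- lapply(seq_along(counts), function(i) {
    hl <- haps_by_count[[i]]
    if (inherits(hl, "haplotype_truth")) hl <- list(hl)
    vals <- vapply(seq_along(hl), function(j) {
      mean(vapply(seq_len(n_reps), function(r) {
        p <- sim_params
        p$seed <- sim_params$seed + 131L * i + 17L * j + r
        hap_norm_depth(hl[[j]], p, mode)
      }, numeric(1)))
    }, numeric(1))
    data.frame(copy_count = counts[i], expected_depth = mean(vals),
               n_haplotypes = length(hl))
  })
  tab <- do.call(rbind, rows)[ord, , drop = FALSE]
  if (any(diff(tab$expected_depth) <= 0))
    stop("calibration table is not strictly increasing in copy count")
  rownames(tab) <- NULL
  tab
}

#' Call copy number from a normalized depth
#'
#' Nearest-entry assignment against the calibration table; ties break toward
#' the lower copy count (the ancestral state).  The distance to the nearest
#' entry is reported so borderline calls can be flagged.
#'
#' @param norm_depth normalized depth value (or `normalized_depth`)
#' @param table calibration table from [build_call_table()]
#' @return list with `copy_count` and `distance`
#' @export
call_copy_number <- function(norm_depth, table) {
  v <- if (inherits(norm_depth, "normalized_depth")) norm_depth$value else norm_depth
  d <- abs(table$expected_depth - v)
  i <- order(d, table$copy_count)[1L]
  list(copy_count = table$copy_count[i], distance = d[i])
}

#' Call a diploid genotype total from a normalized depth
#'
#' Enumerates unordered haplotype pairs from the calibration table; the
#' expected diploid depth of a genotype is the mean of its two haplotype
#' entries.  Ties break toward the lower total.
#'
#' @inheritParams call_copy_number
#' @return list with `total` (summed haplotype copy count), `genotype`
#'   (c(low, high)) and `distance`
#' @export
call_genotype <- function(norm_depth, table) {
  v <- if (inherits(norm_depth, "normalized_depth")) norm_depth$value else norm_depth
  idx <- which(upper.tri(diag(nrow(table)), diag = TRUE), arr.ind = TRUE)
  exp_d <- (table$expected_depth[idx[, 1]] + table$expected_depth[idx[, 2]]) / 2
  tot <- table$copy_count[idx[, 1]] + table$copy_count[idx[, 2]]
  d <- abs(exp_d - v)
  i <- order(d, tot)[1L]
  list(total = tot[i],
       genotype = sort(c(table$copy_count[idx[i, 1]], table$copy_count[idx[i, 2]])),
       distance = d[i])
}

mk_score <- function(x) {
  n <- length(x)
  sum(sign(outer(x, x, "-"))[lower.tri(matrix(0, n, n))])
}

#' One-sided Mann-Kendall trend test
#'
#' Tests for a monotone increase over a time-ordered series (alternative:
#' true Kendall score S > 0).  Uses the tie-corrected variance with a +/-1
#' continuity correction for the normal approximation; for n <= `exact_max`
#' the one-sided p is computed exactly by enumerating all permutations of the
#' observed values.
#'
#' @param x numeric series ordered by time (n >= 3)
#' @param exact_max largest n for which the exact permutation p is computed
#' @return list with S, var_S, z, p_one_sided, method, n
#' @export
mann_kendall_trend <- function(x, exact_max = 8L) {
  n <- length(x)
  if (n < 3L) stop("mann_kendall_trend requires n >= 3")
  S <- mk_score(x)
  tt <- table(x)
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  ## upper-tail continuity correction: achievable S values are 2 apart, so
  ## P(S' >= s) ~ 1 - Phi((s - 1) / sd) uniformly in s
  z <- (S - 1) / sqrt(var_S)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    Sp <- apply(perms, 1L, function(idx) mk_score(x[idx]))
    p <- mean(Sp >= S)
    method <- "exact permutation"
  } else {
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(S = S, var_S = var_S, z = z, p_one_sided = p, method = method, n = n)
}

## all permutations of 1..n as a matrix (n! rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Two-group rank-sum comparison of normalized depths
#'
#' Wilcoxon rank sum test; exact p for small groups (both n <= 10, no ties),
#' normal approximation otherwise.
#'
#' @param values numeric vector
#' @param groups grouping vector with exactly two levels
#' @param alternative "two.sided" (default), "less" or "greater"
#' @return list with W, p_value, n per group, method
#' @export
group_difference <- function(values, groups, alternative = "two.sided") {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  x <- values[g == levels(g)[1L]]; y <- values[g == levels(g)[2L]]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  exact <- length(x) <= 10L && length(y) <= 10L
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact))
  list(W = unname(ht$statistic), p_value = ht$p.value,
       n = c(length(x), length(y)), groups = levels(g), method = ht$method)
}

#' Pearson correlation of depth with latitude
#' @param depth,latitude numeric vectors of equal length (n >= 3)
#' @return list with r, p_value, n
#' @export
depth_latitude_correlation <- function(depth, latitude) {
  if (length(depth) != length(latitude)) stop("lengths differ")
  if (length(depth) < 3L) stop("n >= 3 required")
  if (stats::sd(depth) == 0 || stats::sd(latitude) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(depth, latitude, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(depth))
}

#' Per-base coverage from a BAM file with MAPQ and primary-alignment filters
#'
#' @param bam path to an indexed BAM
#' @param seqname reference sequence name
#' @param min_mapq minimum mapping quality (default 3)
#' @param primary_only drop secondary and supplementary alignments
#' @return numeric per-base coverage over the full reference sequence
#' @export
coverage_from_bam <- function(bam, seqname, min_mapq = 3L, primary_only = TRUE) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!seqname %in% names(hdr)) stop("seqname not in BAM header")
  n <- hdr[[seqname]]
  flag <- if (primary_only)
    Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isUnmappedQuery = FALSE)
  else Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  sbp <- Rsamtools::ScanBamParam(
    flag = flag,
    which = GenomicRanges::GRanges(seqname, IRanges::IRanges(1L, n)))
  pp <- Rsamtools::PileupParam(max_depth = 10000L, min_base_quality = 0L,
                               min_mapq = as.integer(min_mapq),
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  cov <- numeric(n)
  if (nrow(p)) cov[p$pos] <- p$count
  cov
}
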