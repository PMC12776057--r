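# Read simulation over weighted pools of source sequences.

#' Weighted pool of source sequences
#' @param labels unique labels
#' @param sequences DNA sequences (character)
#' @param weights non-negative weights, at least one positive
#' @export
weighted_pool <- function(labels, sequences, weights = rep(1, length(labels))) {
  if (anyDuplicated(labels)) stop_field("labels", "must be unique")
  if (length(labels) != length(sequences) || length(labels) != length(weights))
    stop_field("entries", "labels, sequences and weights must have equal length")
  if (length(labels) == 0L) stop_field("entries", "pool is empty")
  if (any(weights < 0) || !any(weights > 0))
    stop_field("weights", "must be non-negative with at least one positive")
  structure(data.frame(label = labels, sequence = as.character(sequences),
                       weight = weights, stringsAsFactors = FALSE),
            class = c("weighted_pool", "data.frame"))
}

#' Paired-end read simulation parameters
#'
#' Defaults reproduce a HiSeq2000-style simulation: 76 bp paired-end reads,
#' fragment length normal with mean 150 bp and sd 50 bp (truncated to the
#' feasible range), at a chosen depth.
#'
#' @param read_len_bp read length
#' @param frag_mu_bp,frag_sd_bp fragment-length normal parameters
#' @param per_base_error i.i.d. substitution error probability in [0, 1)
#' @param depth_x target mean depth over the pool (exactly one of `depth_x`
#'   and `n_pairs`)
#' @param n_pairs exact number of mate pairs to emit
#' @param seed RNG seed
#' @export
read_sim_params <- function(read_len_bp = 76L, frag_mu_bp = 150, frag_sd_bp = 50,
                            per_base_error = 0, depth_x = NULL, n_pairs = NULL,
                            seed = 1L) {
  if (read_len_bp <= 0) stop_field("read_len_bp", "must be > 0")
  if (read_len_bp > frag_mu_bp)
    stop_field("frag_mu_bp", "must be >= read_len_bp")
  if (per_base_error < 0 || per_base_error >= 1)
    stop_field("per_base_error", "must be in [0, 1)")
  if (is.null(depth_x) == is.null(n_pairs))
    stop_field("depth_x/n_pairs", "exactly one must be set")
  structure(list(read_len_bp = as.integer(read_len_bp), frag_mu_bp = frag_mu_bp,
                 frag_sd_bp = frag_sd_bp, per_base_error = per_base_error,
                 depth_x = depth_x, n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

apply_seq_errors <- function(reads, e) {
  if (e <= 0) return(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, e)
  hit <- which(n_err > 0L)
  for (i in hit) {
    ch <- seq_chars(reads[i])
    ch <- mutate_bases(ch, sample.int(rl[i], n_err[i]))
    reads[i] <- chars_seq(ch)
  }
  reads
}

#' Simulate paired-end reads from a weighted pool
#'
#' Source sequences are chosen proportional to weight x length; fragment
#' lengths are drawn from a normal truncated to [read length, source length];
#' fragments come off either strand; the inner mate is reverse-complemented
#' (FR orientation); substitution errors are i.i.d. per base.  The returned
#' record keeps the true source label and fragment coordinates for every pair.
#'
#' @param pool a `weighted_pool`
#' @param params a `read_sim_params`
#' @return object of class `read_pairs`: list with `r1`, `r2` (character),
#'   `info` (data.frame: label, start, end, strand) and `params`
#' @export
simulate_paired_reads <- function(pool, params) {
  stopifnot(inherits(pool, "weighted_pool"), inherits(params, "read_sim_params"))
  rl <- params$read_len_bp
  lens <- nchar(pool$sequence)
  ok <- lens >= rl & pool$weight > 0
  if (!any(ok)) stop("no pool sequence is at least read_len_bp long")
  pool <- pool[ok, , drop = FALSE]; lens <- lens[ok]
  n <- if (!is.null(params$n_pairs)) params$n_pairs else
    max(1L, round(params$depth_x * sum(lens) / (2 * rl)))
  with_seed(params$seed, {
    src <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight * lens)
    fl <- pmax(rl, pmin(lens[src], round(rnorm(n, params$frag_mu_bp, params$frag_sd_bp))))
    for (r in 1:50) {  # rejection rounds for the truncated normal
      bad <- which(fl < rl | fl > lens[src])
      if (!length(bad)) break
      fl[bad] <- round(rnorm(length(bad), params$frag_mu_bp, params$frag_sd_bp))
    }
    fl <- pmax(rl, pmin(lens[src], fl))
    start <- floor(runif(n) * (lens[src] - fl + 1)) + 1L
    end <- start + fl - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- substr(pool$sequence[src], start, end)
    neg <- strand == "-"
    if (any(neg)) frag[neg] <- revcomp(frag[neg])
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp(substr(frag, fl - rl + 1L, fl))
    r1 <- apply_seq_errors(r1, params$per_base_error)
    r2 <- apply_seq_errors(r2, params$per_base_error)
    ids <- sprintf("pair_%06d", seq_len(n))
    structure(list(r1 = setNames(r1, ids), r2 = setNames(r2, ids),
                   info = data.frame(id = ids, label = pool$label[src],
                                     start = start, end = end, strand = strand,
                                     stringsAsFactors = FALSE),
                   params = params),
              class = "read_pairs")
  })
}

#' Write simulated pairs as FASTQ files
#' @param pairs a `read_pairs`
#' @param prefix output prefix; writes `<prefix>_1.fastq[.gz]` and `_2`
#' @param quality_char constant base quality character
#' @param gzip compress output
#' @return character(2) of paths
#' @export
write_paired_fastq <- function(pairs, prefix, quality_char = "I", gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (i in 1:2) {
    reads <- if (i == 1) pairs$r1 else pairs$r2
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq", qualities = q,
                                compress = gzip)
  }
  paths
}

#' Simulate full-length (long) transcript reads
#'
#' Emits `n` copies of pool entries sampled proportional to weight.  With
#' probability `truncation_rate` a read is truncated from a random end at a
#' uniform cut point, exercising downstream full-span filters.
#'
#' @param pool a `weighted_pool`
#' @param n number of reads
#' @param seed RNG seed
#' @param truncation_rate probability a read is truncated
#' @return list with `reads` (named character) and `info` data.frame
#' @export
simulate_long_reads <- function(pool, n, seed = 1L, truncation_rate = 0) {
  stopifnot(inherits(pool, "weighted_pool"), n >= 0)
  if (n == 0L)
    return(list(reads = setNames(character(0), character(0)),
                info = data.frame(id = character(0), label = character(0),
                                  truncated = logical(0))))
  with_seed(seed, {
    src <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
    reads <- pool$sequence[src]
    trunc <- runif(n) < truncation_rate
    for (i in which(trunc)) {
      len <- nchar(reads[i])
      cut <- sample.int(len - 1L, 1L)
      reads[i] <- if (runif(1) < 0.5) substr(reads[i], cut + 1L, len)
                  else substr(reads[i], 1L, cut)
    }
    ids <- sprintf("read_%06d", seq_len(n))
    list(reads = setNames(reads, ids),
         info = data.frame(id = ids, label = pool$label[src], truncated = trunc,
                           stringsAsFactors = FALSE))
  })
}
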