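#' @importFrom stats rnorm runif setNames complete.cases
#' @importFrom utils write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package internals do
#' not perturb user code.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## substitute each flagged base with a uniformly chosen different base
mutate_bases <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  cur <- chars[idx]
  alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  chars[idx] <- alt
  chars
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_seq <- function(ch) paste(ch, collapse = "")

#' Write sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input path
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write intervals as BED (0-based half-open at I/O)
#'
#' Internally the package uses 1-based inclusive coordinates; this converts
#' on output.
#' @param df data.frame with columns chrom, start, end (1-based inclusive) and
#'   optionally name
#' @param path output path
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
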