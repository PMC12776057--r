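# Protein-level divergence among gene copies and between ecotypes:
# pairwise identity, consistently divergent sites, domain enrichment
# (exact hypergeometric upper tail) and truncation status from CDS.

#' Percent identity of two aligned sequences
#'
#' 100 x identical columns / columns where neither sequence has a gap.
#'
#' @param seq_a,seq_b aligned sequences of equal length
#' @return percent identity (numeric)
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal aligned length")
  a <- seq_chars(toupper(seq_a)); b <- seq_chars(toupper(seq_b))
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("no comparable (gap-free) columns")
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Sites consistently divergent between ecotypes
#'
#' A column qualifies iff the set of residues seen in every freshwater
#' sequence and the set seen in every marine sequence are disjoint (the
#' strictest reading of "changed in all freshwater compared to marine").
#' Columns with a gap in any sequence are excluded.
#'
#' @param seqs named character vector of aligned protein sequences
#' @param ecotype character vector ("marine"/"freshwater") per sequence
#' @return integer positions (1-based alignment columns)
#' @export
ecotype_divergent_sites <- function(seqs, ecotype) {
  if (length(seqs) != length(ecotype)) stop("ecotype labels must match sequences")
  groups <- split(seq_along(seqs), ecotype)
  if (!all(c("marine", "freshwater") %in% names(groups)))
    stop("both ecotype groups must be non-empty")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must have equal aligned length")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  which(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return(FALSE)
    length(intersect(col[groups$marine], col[groups$freshwater])) == 0L
  }, logical(1)))
}

#' Most abundant sequence in a set
#'
#' The reference convention for per-sequence divergence: the exact sequence
#' string occurring most often (ties broken by first occurrence).
#'
#' @param seqs character vector of sequences
#' @return the most abundant sequence (character scalar)
#' @export
most_abundant_seq <- function(seqs) {
  tab <- table(factor(seqs, levels = unique(seqs)))
  names(tab)[which.max(tab)]
}

#' Divergent sites of each sequence relative to a reference
#' @param seqs named character vector of aligned sequences
#' @param ref aligned reference sequence (default: most abundant in `seqs`)
#' @return named list of integer positions per sequence
#' @export
per_sequence_divergence <- function(seqs, ref = most_abundant_seq(seqs)) {
  rc <- seq_chars(toupper(ref))
  lapply(seqs, function(s) {
    sc <- seq_chars(toupper(s))
    which(sc != rc & sc != "-" & rc != "-")
  })
}

#' Hypergeometric enrichment of divergent sites in a protein domain
#'
#' With N residues in the protein, K of them in the domain, and n divergent
#' sites of which k fall inside the domain, computes the exact upper-tail
#' probability P(X >= k) for X ~ Hypergeometric(N, K, n).
#'
#' @param positions integer residue positions of divergent sites (1-based)
#' @param domain c(start, end), 1-based inclusive residue coordinates
#' @param protein_len protein length N
#' @return list with N, K, n, k, p_upper
#' @export
domain_enrichment <- function(positions, domain, protein_len) {
  domain <- as.integer(domain)
  if (domain[1] < 1L || domain[2] > protein_len || domain[1] > domain[2])
    stop("domain outside [1, protein_len]")
  if (any(positions < 1L | positions > protein_len))
    stop("divergent positions outside [1, protein_len]")
  N <- as.integer(protein_len)
  K <- domain[2] - domain[1] + 1L
  n <- length(positions)
  k <- sum(positions >= domain[1] & positions <= domain[2])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p_upper = p)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Coding-sequence integrity relative to a reference CDS
#'
#' Classifies a CDS as `intact`, `nonsense-truncated` (internal stop in
#' frame), `frameshift-truncated` (length difference vs the reference not a
#' multiple of 3; truncation at the first out-of-frame stop) or
#' `in-frame-deletion` (3n shorter without an internal stop).
#'
#' @param cds coding sequence beginning at the start codon
#' @param reference_cds intact reference coding frame
#' @return list with `status` and `truncation_residue` (NA unless truncated)
#' @export
cds_integrity <- function(cds, reference_cds) {
  cds <- toupper(cds); reference_cds <- toupper(reference_cds)
  codons <- codon_split(cds)
  n <- length(codons)
  internal_stop <- which(codons %in% STOP_CODONS)
  internal_stop <- internal_stop[internal_stop < n]   # terminal stop is normal
  dlen <- nchar(cds) - nchar(reference_cds)
  if (dlen %% 3L != 0L) {
    first_stop <- which(codons %in% STOP_CODONS)[1L]
    return(list(status = "frameshift-truncated",
                truncation_residue = if (is.na(first_stop)) NA_integer_ else first_stop))
  }
  if (length(internal_stop))
    return(list(status = "nonsense-truncated",
                truncation_residue = internal_stop[1L]))
  if (dlen < 0L)
    return(list(status = "in-frame-deletion", truncation_residue = NA_integer_))
  list(status = "intact", truncation_residue = NA_integer_)
}
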