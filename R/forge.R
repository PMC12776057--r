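# Synthetic tandem-duplication haplotypes with planted ground truth.
#
# The emulated locus mirrors a myosin heavy chain cluster: two single-copy
# genes (C1, C2) followed by a tandemly repeated duplication unit that carries
# a full C3 gene plus partial fragments of C2 (5') and of the downstream gene
# SYT19 (3').  Junctions between units therefore fuse SYT19- and C2-derived
# sequence, the signature of the microhomology-mediated (MMBIR) expansion.
# Unequal crossover (NAHR) between misaligned units yields reciprocal
# duplication/deletion products whose new intermediate unit is a 5' L-like /
# 3' A-like mosaic.

# internal layout constants (bp)
FORGE_FRAG <- 300L          # C2 / SYT19 fragment length inside the unit
FORGE_PAD <- 100L           # spacer between fragments and the C3 gene
FORGE_BOUNDARY_EXCL <- 60L  # no SNPs / unit divergence this close to a unit boundary

#' Specification of a synthetic tandem-duplication haplotype
#'
#' @param ecotype "marine" or "freshwater"; the two ecotypes share an
#'   ancestral backbone and differ only at the positions of a shared SNP table.
#' @param copy_count total myosin gene copies (C1 + C2 + C3 copies), 3..6.
#' @param gene_length_bp length of the C1/C2 gene bodies (toy default 1200).
#' @param dup_region_length_bp length of the tandem duplication unit
#'   (toy default 2000; the real unit is ~17.6 kb).
#' @param intergenic_length_bp spacer length between genes.
#' @param snp_divergence_rate fraction of positions diverged between the
#'   marine and freshwater backbones.
#' @param microhomology_len_bp perfect microhomology planted at unit junctions.
#' @param crossover_pos unit offset (1-based) of the unequal-crossover point
#'   used when forging 5- and 6-copy haplotypes; NULL otherwise.
#' @param unit_divergence_rate substitution rate between duplication units
#'   (gives the A/L divergent columns the crossover analysis reads).
#' @param seed integer seed; identical (spec, seed) gives identical output.
#' @return object of class `haplotype_spec`
#' @export
haplotype_spec <- function(ecotype = c("marine", "freshwater"),
                           copy_count = 3L,
                           gene_length_bp = 1200L,
                           dup_region_length_bp = 2000L,
                           intergenic_length_bp = 500L,
                           snp_divergence_rate = 0.01,
                           microhomology_len_bp = 4L,
                           crossover_pos = NULL,
                           unit_divergence_rate = 0.01,
                           seed = 1L) {
  ecotype <- match.arg(ecotype)
  copy_count <- as.integer(copy_count)
  if (is.na(copy_count) || copy_count < 3L || copy_count > 6L)
    stop_field("copy_count", "must be an integer in [3, 6]")
  for (f in c("gene_length_bp", "dup_region_length_bp", "intergenic_length_bp")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) stop_field(f, "must be > 0")
  }
  if (gene_length_bp <= FORGE_FRAG)
    stop_field("gene_length_bp", sprintf("must exceed the in-unit fragment (%d bp)", FORGE_FRAG))
  if (dup_region_length_bp < 2L * FORGE_FRAG + 2L * FORGE_PAD + 100L)
    stop_field("dup_region_length_bp",
               "too short to hold the C2/SYT19 fragments plus a C3 gene")
  if (snp_divergence_rate < 0 || snp_divergence_rate >= 1)
    stop_field("snp_divergence_rate", "must be in [0, 1)")
  if (microhomology_len_bp < 0 || microhomology_len_bp >= dup_region_length_bp)
    stop_field("microhomology_len_bp", "must be >= 0 and < dup_region_length_bp")
  if (copy_count == 3L && !is.null(crossover_pos))
    stop_field("crossover_pos", "must be absent for a 3-copy haplotype")
  if (!is.null(crossover_pos) &&
      (crossover_pos < 1L || crossover_pos > dup_region_length_bp))
    stop_field("crossover_pos", "must lie within the duplication unit")
  structure(list(ecotype = ecotype,
                 copy_count = copy_count,
                 gene_length_bp = as.integer(gene_length_bp),
                 dup_region_length_bp = as.integer(dup_region_length_bp),
                 intergenic_length_bp = as.integer(intergenic_length_bp),
                 snp_divergence_rate = snp_divergence_rate,
                 microhomology_len_bp = as.integer(microhomology_len_bp),
                 crossover_pos = if (is.null(crossover_pos)) NULL else as.integer(crossover_pos),
                 unit_divergence_rate = unit_divergence_rate,
                 seed = as.integer(seed)),
            class = "haplotype_spec")
}

c3_labels <- function(u) {
  if (u == 1L) return("C3A")
  c("C3A", if (u > 2L) paste0("C3", LETTERS[seq(2L, u - 1L)]), "C3L")
}

## recompute gene/unit coordinate tables for a haplotype with u units
forge_layout <- function(spec, u) {
  gl <- spec$gene_length_bp; ig <- spec$intergenic_length_bp
  L <- spec$dup_region_length_bp
  frag <- FORGE_FRAG; pad <- FORGE_PAD
  c3_len <- L - 2L * frag - 2L * pad
  prefix_len <- ig + gl + ig + (gl - frag)
  unit_start <- prefix_len + (seq_len(u) - 1L) * L + 1L
  unit_end <- unit_start + L - 1L
  total <- prefix_len + u * L + (gl - frag) + ig
  copies <- data.frame(
    label = c("C1", "C2", c3_labels(u)),
    start = c(ig + 1L, ig + gl + ig + 1L, unit_start + frag + pad),
    end = c(ig + gl, prefix_len + frag, unit_start + frag + pad + c3_len - 1L),
    stringsAsFactors = FALSE)
  units <- data.frame(label = c3_labels(u), start = unit_start, end = unit_end,
                      stringsAsFactors = FALSE)
  list(total = total, prefix_len = prefix_len, unit_len = L, c3_len = c3_len,
       frag = frag, pad = pad, copies = copies, units = units,
       syt19 = c(unit_end[u] - frag + 1L, unit_end[u] + (gl - frag)),
       junctions = if (u > 1L) unit_end[seq_len(u - 1L)] else integer(0))
}

new_truth <- function(sequence, spec, u, snp_table,
                      planted_microhomology_bp = 0L,
                      planted_imperfect_bp = 0L,
                      planted_crossover_interval = NULL) {
  lay <- forge_layout(spec, u)
  stopifnot(nchar(sequence) == lay$total)
  structure(list(sequence = sequence, spec = spec,
                 copies = lay$copies, units = lay$units,
                 syt19 = lay$syt19, junctions = lay$junctions,
                 layout = lay, snp_table = snp_table,
                 planted_microhomology_bp = planted_microhomology_bp,
                 planted_imperfect_bp = planted_imperfect_bp,
                 planted_crossover_interval = planted_crossover_interval),
            class = "haplotype_truth")
}

#' Number of myosin gene copies in a haplotype truth record
#' @param hap a `haplotype_truth`
#' @export
copy_count <- function(hap) nrow(hap$copies)

#' Build the 3-copy ancestral haplotype
#'
#' Generates the ancestral backbone deterministically from the seed, draws a
#' shared marine/freshwater SNP table (SNPs are excluded from unit-boundary
#' windows so junction microhomology stays independent of SNP noise), and
#' applies the requested ecotype's alleles.  Marine and freshwater haplotypes
#' built from the same seed differ exactly at the SNP table positions.
#'
#' @param spec a `haplotype_spec`
#' @return a `haplotype_truth` with copies C1, C2, C3A and no junctions
#' @export
build_base_haplotype <- function(spec) {
  if (!inherits(spec, "haplotype_spec")) stop("spec must be a haplotype_spec")
  lay <- forge_layout(spec, 1L)
  with_seed(spec$seed, {
    anc <- seq_chars(random_dna(lay$total))
    excl <- integer(0)
    for (i in seq_len(nrow(lay$units))) {
      excl <- c(excl,
                seq(lay$units$start[i] - FORGE_BOUNDARY_EXCL, lay$units$start[i] + FORGE_BOUNDARY_EXCL - 1L),
                seq(lay$units$end[i] - FORGE_BOUNDARY_EXCL + 1L, lay$units$end[i] + FORGE_BOUNDARY_EXCL))
    }
    eligible <- setdiff(seq_len(lay$total), excl)
    n_snp <- round(spec$snp_divergence_rate * lay$total)
    pos <- sort(sample(eligible, min(n_snp, length(eligible))))
    marine <- anc[pos]
    fresh <- vapply(marine, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    snp_table <- data.frame(pos = pos, marine = unname(marine),
                            freshwater = unname(fresh), stringsAsFactors = FALSE)
    if (spec$ecotype == "freshwater") anc[pos] <- fresh
    new_truth(chars_seq(anc), spec, 1L, snp_table)
  })
}

## shift/duplicate SNP table positions when a unit copy is inserted after
## position `ins_after` (the copied unit spans [copy_lo, ins_after])
remap_snps_insert <- function(snp, copy_lo, ins_after, L) {
  dup <- snp[snp$pos >= copy_lo & snp$pos <= ins_after, , drop = FALSE]
  dup$pos <- dup$pos + L
  snp$pos[snp$pos > ins_after] <- snp$pos[snp$pos > ins_after] + L
  out <- rbind(snp, dup)
  out[order(out$pos), , drop = FALSE]
}

#' Expand a haplotype by one tandem duplication unit (MMBIR-style)
#'
#' Duplicates the last duplication unit in place, creating a new SYT19/C2
#' fusion junction between consecutive units, and plants an exact stretch of
#' shared microhomology across the junction by editing the donor flanks.  An
#' imperfect (single-mismatch) microhomology window of `imperfect_len_bp` can
#' be planted around the perfect core.  The new unit is then diverged from the
#' older units at `unit_divergence_rate` (away from boundaries and SNPs).
#'
#' @param hap a `haplotype_truth` with >= 3 copies
#' @param microhomology_len_bp exact shared bases across the junction
#' @param imperfect_len_bp total homology window length containing the perfect
#'   core with one internal mismatch; defaults to the perfect length
#' @param unit_divergence_rate substitution rate applied to the new unit
#' @param seed RNG seed for the divergence edits (derived from the spec seed
#'   and the new unit index by default)
#' @return a `haplotype_truth` with one more copy
#' @export
expand_mmbir <- function(hap, microhomology_len_bp = hap$spec$microhomology_len_bp,
                         imperfect_len_bp = microhomology_len_bp,
                         unit_divergence_rate = hap$spec$unit_divergence_rate,
                         seed = NULL) {
  stopifnot(inherits(hap, "haplotype_truth"))
  u <- nrow(hap$units)
  L <- hap$layout$unit_len
  k <- as.integer(microhomology_len_bp)
  m <- as.integer(imperfect_len_bp)
  if (k >= L) stop("microhomology_len_bp must be smaller than the duplication unit")
  if (m < k) stop("imperfect_len_bp must be >= microhomology_len_bp")
  if (m >= FORGE_BOUNDARY_EXCL - 2L) stop("planted homology exceeds the boundary window")
  if (is.null(seed)) seed <- hap$spec$seed + 7919L * (u + 1L)

  ch <- seq_chars(hap$sequence)
  with_seed(seed, {
    ## --- plant junction homology on the donor flanks -----------------------
    ## right donor: C2 context; junction continuation = first bases of a unit.
    ## left donor: SYT19 context; natural continuation = SYT19 tail.
    st <- hap$units$end[u] + 1L                 # SYT19 tail start
    unit_starts <- hap$units$start
    want_match <- rep(FALSE, m + 1L)
    if (k > 0L) want_match[seq_len(k)] <- TRUE
    if (m > k) want_match[seq(k + 2L, m)] <- TRUE
    for (i in seq_len(m + 1L)) {
      tail_b <- ch[st + i - 1L]
      if (want_match[i]) {
        ch[unit_starts + i - 1L] <- tail_b      # all units stay identical here
      } else if (ch[unit_starts[1L] + i - 1L] == tail_b) {
        nb <- sample(setdiff(DNA_BASES, tail_b), 1L)
        ch[unit_starts + i - 1L] <- nb
      }
    }
    ## pre-junction mismatch: last base of the unit vs last base of C2 head
    pre_c2 <- unit_starts[1L] - 1L
    unit_last <- hap$units$end
    if (ch[pre_c2] == ch[unit_last[u]])
      ch[pre_c2] <- sample(setdiff(DNA_BASES, ch[unit_last[u]]), 1L)

    ## --- duplicate the last unit ------------------------------------------
    lo <- hap$units$start[u]; hi <- hap$units$end[u]
    new_ch <- c(ch[1:hi], ch[lo:hi], ch[(hi + 1L):length(ch)])
    snp <- remap_snps_insert(hap$snp_table, lo, hi, L)

    ## --- diverge the new unit ---------------------------------------------
    new_lo <- hi + 1L
    offs <- seq(FORGE_BOUNDARY_EXCL + 1L, L - FORGE_BOUNDARY_EXCL)
    offs <- offs[!((new_lo + offs - 1L) %in% snp$pos)]
    n_mut <- round(unit_divergence_rate * length(offs))
    if (n_mut > 0L) {
      mut <- sample(offs, n_mut)
      new_ch <- mutate_bases(new_ch, new_lo + mut - 1L)
    }

    spec2 <- hap$spec
    spec2$copy_count <- hap$spec$copy_count + 1L
    new_truth(chars_seq(new_ch), spec2, u + 1L, snp,
              planted_microhomology_bp = k,
              planted_imperfect_bp = m,
              planted_crossover_interval = hap$planted_crossover_interval)
  })
}

## offsets (1-based, within-unit) at which two units of a haplotype differ
unit_divergent_offsets <- function(hap_a, unit_a, hap_b, unit_b) {
  ia <- hap_a$units[hap_a$units$label == unit_a, ]
  ib <- hap_b$units[hap_b$units$label == unit_b, ]
  if (nrow(ia) != 1L || nrow(ib) != 1L) stop("unknown unit label")
  a <- seq_chars(substr(hap_a$sequence, ia$start, ia$end))
  b <- seq_chars(substr(hap_b$sequence, ib$start, ib$end))
  which(a != b)
}

#' Unequal crossover (NAHR) between misaligned duplication units
#'
#' Models non-allelic homologous recombination between two haplotypes whose
#' duplication units have mispaired: `pairing[1]` names the unit of `hap1`
#' aligned against unit `pairing[2]` of `hap2`.  The exchange at
#' `crossover_pos` (1-based unit offset; positions before it come from the
#' hap2 unit, positions from it onward from the hap1 unit) yields reciprocal
#' duplication and deletion products.  The new intermediate unit of the
#' duplication product is hap2-derived (L-like) at the 5' end and hap1-derived
#' (A-like) at the 3' end.  The planted crossover interval recorded in the
#' truth is the maximal identity interval around the crossover, bounded by the
#' nearest divergent offsets of the two donor units.
#'
#' @param hap1,hap2 `haplotype_truth` objects sharing the duplication-unit length
#' @param pairing character(2): unit label in hap1, unit label in hap2
#' @param crossover_pos unit offset in 1..unit_length
#' @return list with elements `duplication` and `deletion` (`haplotype_truth`)
#' @export
recombine_nahr <- function(hap1, hap2, pairing = c("C3A", "C3L"), crossover_pos) {
  stopifnot(inherits(hap1, "haplotype_truth"), inherits(hap2, "haplotype_truth"))
  L <- hap1$layout$unit_len
  if (hap2$layout$unit_len != L) stop("haplotypes must share the duplication-unit length")
  o <- as.integer(crossover_pos)
  if (is.na(o) || o < 1L || o > L) stop("crossover_pos outside the duplication unit")
  i1 <- match(pairing[1], hap1$units$label)
  i2 <- match(pairing[2], hap2$units$label)
  if (is.na(i1) || is.na(i2)) stop("pairing must name a unit in each haplotype")
  n1 <- nrow(hap1$units); n2 <- nrow(hap2$units)

  div <- unit_divergent_offsets(hap2, pairing[2], hap1, pairing[1])
  lo <- if (any(div <= o - 1L)) max(div[div <= o - 1L]) else NA_integer_
  hi <- if (any(div >= o)) min(div[div >= o]) else NA_integer_
  xover <- c(lo = lo, hi = hi)

  splice <- function(pre_hap, pre_unit_idx, suf_hap, suf_unit_idx) {
    pu <- pre_hap$units[pre_unit_idx, ]; su <- suf_hap$units[suf_unit_idx, ]
    cut_pre <- pu$start + o - 2L            # last kept base of the prefix donor
    cut_suf <- su$start + o - 1L            # first kept base of the suffix donor
    seqs <- paste0(substr(pre_hap$sequence, 1L, cut_pre),
                   substr(suf_hap$sequence, cut_suf, nchar(suf_hap$sequence)))
    u_out <- (pre_unit_idx - 1L) + 1L + (nrow(suf_hap$units) - suf_unit_idx)
    shift <- cut_pre - (cut_suf - 1L)
    snp_pre <- pre_hap$snp_table[pre_hap$snp_table$pos <= cut_pre, , drop = FALSE]
    snp_suf <- suf_hap$snp_table[suf_hap$snp_table$pos >= cut_suf, , drop = FALSE]
    snp_suf$pos <- snp_suf$pos + shift
    snp <- rbind(snp_pre, snp_suf)
    snp <- snp[!duplicated(snp$pos), , drop = FALSE]
    snp <- snp[order(snp$pos), , drop = FALSE]
    spec2 <- suf_hap$spec
    spec2$copy_count <- u_out + 2L
    spec2$crossover_pos <- if (u_out >= 2L) o else NULL
    new_truth(seqs, spec2, u_out, snp,
              planted_microhomology_bp = suf_hap$planted_microhomology_bp,
              planted_imperfect_bp = suf_hap$planted_imperfect_bp,
              planted_crossover_interval = if (u_out >= 3L) xover else NULL)
  }

  list(duplication = splice(hap2, i2, hap1, i1),
       deletion = splice(hap1, i1, hap2, i2))
}

#' Forge a complete haplotype from a spec
#'
#' 3-copy haplotypes come straight from the ancestral builder; the 4th copy is
#' added by an MMBIR-style tandem duplication (planting the spec's
#' microhomology); 5- and 6-copy haplotypes arise by unequal crossover of the
#' haplotype with itself at `crossover_pos`, so their intermediate units are
#' genuine L/A mosaics.
#' @param spec a `haplotype_spec`
#' @return a `haplotype_truth`
#' @export
forge_haplotype <- function(spec) {
  h <- build_base_haplotype(spec)
  if (spec$copy_count == 3L) return(h)
  h <- expand_mmbir(h)
  if (spec$copy_count == 4L) return(h)
  if (is.null(spec$crossover_pos))
    stop_field("crossover_pos", "required for 5- and 6-copy haplotypes")
  h5 <- recombine_nahr(h, h, c("C3A", "C3L"), spec$crossover_pos)$duplication
  if (spec$copy_count == 5L) return(h5)
  recombine_nahr(h5, h5, c("C3A", "C3B"), spec$crossover_pos)$duplication
}

#' Truth record tables for export
#'
#' @param hap a `haplotype_truth`
#' @param name sequence name used in the BED chrom column
#' @return list of data.frames: `features` (copies, units, junctions; 1-based
#'   inclusive), `snps`
#' @export
truth_tables <- function(hap, name = "hap") {
  feats <- rbind(
    data.frame(chrom = name, start = hap$copies$start, end = hap$copies$end,
               name = paste0("gene_", hap$copies$label)),
    data.frame(chrom = name, start = hap$units$start, end = hap$units$end,
               name = paste0("unit_", hap$units$label)),
    if (length(hap$junctions))
      data.frame(chrom = name, start = hap$junctions, end = hap$junctions + 1L,
                 name = "junction"))
  list(features = feats, snps = hap$snp_table)
}
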