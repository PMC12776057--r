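---
title: "Methods: copy number, expression and mechanism at near-identical tandem duplicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy number, expression and mechanism at near-identical tandem duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter choices
and limitations. The running system is a tandem myosin heavy chain cluster:
two single-copy genes (C1, C2) followed by one to four copies of a C3-bearing
duplication unit whose boundaries fall inside C2 (upstream) and the
neighbouring gene SYT19 (downstream). Marine haplotypes carry one C3 copy;
freshwater haplotypes carry up to four.

## The synthetic locus

`haplotype_spec()` + `forge_haplotype()` build haplotypes from an ancestral
random backbone. Layout, 5' to 3': intergenic — C1 — intergenic — C2 head —
[duplication unit]×u — SYT19 tail — intergenic, where each unit is
C2-tail-fragment (300 bp) / pad / C3 gene / pad / SYT19-head-fragment
(300 bp). Because the unit must contain a whole C3 gene plus the two flanking
gene fragments, the toy defaults are a 2,000 bp unit with a 1,200 bp C3 gene
and 1,200 bp C1/C2 genes; every length is configurable up to the real scale
(~17.6 kb units), and the read-depth analyses run at that scale (see below).

*Ecotype divergence.* Marine and freshwater haplotypes share one ancestral
backbone and differ exactly at a shared SNP table (default rate 1% of
positions, reflecting the strong marine/freshwater divergence of this locus).
SNPs are excluded from 60 bp windows around unit boundaries so junction
microhomology is never confounded with SNP noise.

*Duplication.* `expand_mmbir()` duplicates the last unit in place, creating a
SYT19/C2 fusion junction between consecutive units, and plants microhomology
by copying the first *k* bases of the SYT19 tail onto the unit start (all
units edited consistently) while forcing mismatches at the window edges; an
"imperfect" window of length *m* > *k* adds matched bases beyond one planted
internal mismatch. The new unit is then diverged from the older units at 1%
of interior positions — the near-complete identity expected of recently
duplicated C3 copies — which
supplies the A/L divergent columns the crossover analysis reads.

*Unequal crossover.* `recombine_nahr(hap1, hap2, pairing, crossover_pos)`
splices the two haplotypes inside the mispaired units, returning the
reciprocal duplication and deletion products (copy number is conserved:
4+4 → 5+3, 5+5 → 6+4). The intermediate unit of the duplication product is
prefix-donor (L-like) before the crossover and suffix-donor (A-like) after
it; the truth record stores the maximal identity interval around the
crossover, bounded by the nearest divergent offsets — exactly what any
sequence-based method can hope to recover.

*Reads.* `simulate_paired_reads()` draws sources proportional to
weight × length, fragment lengths from a normal truncated to the feasible
range, both strands, FR orientation, i.i.d. substitution errors, constant
quality strings (downstream methods use exact matching, not qualities).
Defaults are the HiSeq2000-style 76 bp pairs with 150 ± 50 bp fragments.
`simulate_long_reads()` emits full-length copies of pool entries with an
optional truncation rate to exercise full-span filters. Identical
(spec, seed) inputs give byte-identical outputs.

## Read-depth copy number

With the redundant duplication units hard-masked, reads from every unit map
to the one remaining copy, so mean depth over the C3 region divided by mean
depth over single-copy sequence estimates the per-genome C3 copy count.
The package accepts real coverage (per-base tables or BAMs via
`coverage_from_bam()`, MAPQ ≥ 3, primary alignments only) and, for simulated
reads, performs the masking analytically: each simulated read's true
coordinates are projected onto a collapsed reference in which all units
overlay unit 1 (`collapsed_coverage()`). This projection is the noise-free
equivalent of re-mapping against a reference with the extra units masked and
keeps the statistical path testable without an aligner, which is outside the
package's scope.

The baseline is every single-copy position of the collapsed reference with a
200 bp margin trimmed at the sequence ends (fragment placement thins coverage
there). Two normalization modes are recorded with every value: `autosome`
(individual samples) and `chrXIX` (pooled samples with unknown sex ratios);
on the single-locus synthetic reference both evaluate the same regions, and
the mode is provenance.

`build_call_table()` simulates reads from haplotypes of each copy count,
averages replicate depths, and requires the table to be strictly increasing
(a non-monotone table means the masking or projection is misconfigured).
`call_copy_number()` / `call_genotype()` assign the nearest entry, breaking
ties toward the lower count — the ancestral state, which is the conservative
call. The distance to the nearest entry is reported so borderline calls can
be flagged.

*Scale matters.* At the toy 2 kb unit, an 8× genome gives only ~100 fragments
over the C3 region and Poisson noise swamps the 0.5-unit spacing between
diploid genotypes. The depth analyses therefore run at the locus's real
geometry — 17.6 kb units, 5 kb genes, 3 kb intergenic — where 8× depth yields
the 2–3% precision that makes read-depth genotyping reliable (the copy-number
recovery property uses exactly these conditions). Sequence-level modules stay
at toy scale for speed.

*Statistics.* The Mann-Kendall trend test is implemented in-package:
S = Σ_{i<j} sign(x_j − x_i), tie-corrected variance, and a one-sided upper
tail. For n ≤ 8 the p-value is exact (all n! orderings); otherwise a normal
approximation with the uniform upper-tail continuity correction
z = (S−1)/σ is used — chosen over the sign-dependent correction because only
the uniform version tracks the exact permutation law across the whole support
(within 0.01 for n 6–8). Rank-sum contrasts and Pearson correlations delegate
to `stats::wilcox.test()` / `stats::cor.test()`.

## Discriminating k-mers (MCE / ASE)

`paralog_alignment()` holds one aligned transcript row per (copy, allele);
`classify_columns()` partitions columns into invariant / copy-discriminating
(copies differ, alleles within every copy agree) / allele-discriminating
(some copy's alleles differ, copies otherwise agree) / other (both kinds of
variation; such columns disqualify MCE windows).

`design_kmers()` enumerates every gap-free 27-column window that qualifies —
MCE: ≥1 copy column, no allele/other columns, per-copy 27-mers pairwise
distinct; ASE: ≥1 column distinguishing the target copy's alleles and ≥1
giving the target copy a base unique among copies — then keeps windows
greedily left-to-right. The `min_gap` option spaces retained windows; setting
it near the RNA fragment length (150 bp) makes set counts approximately
independent, which the ASE calibration analyses rely on (adjacent windows
share fragments and would otherwise correlate). k = 27 and the enumeration
grid are configurable; whether the original design centred or tiled windows
is unknowable from counts alone, so tiling-then-selection is used.

`screen_kmers()` drops a set if any member has a perfect off-target match or
more than 5 one-mismatch off-target matches (both strands, exact
Biostrings search), or lies within 100 bp of a transcript end (coverage is
unreliable there). Matches at the homologous positions across copies/alleles
— declared as on-target intervals — do not count as off-target, the only
sensible reading of "off-target" at a multi-copy locus.

`count_pairs()` does exact substring matching of every member against both
mates and, by default, their reverse complements (the library's strandedness
is configurable via `both_orientations = FALSE`); a pair increments a member
at most once. MCE quantification is RPM = detections / total pairs × 10⁶ per
set, averaged across sets per copy. ASE passes a per-copy QC — every set
detected, both alleles seen, ≥100 total reads — and then averages per-set
proportions a₁/(a₁+a₂); QC failure is a value with a reason, never an error.
`ase_test()` wraps the exact signed-rank test against μ = 0.5 (and a
two-sample rank-sum for condition contrasts); degenerate inputs (single
replicate, all values at μ) return p = 1 with a flag.

## Long-read attribution

`informative_variants()` collects all columns within a span interval at which
≥2 copies differ and refuses keys that leave any copy pair indistinguishable.
`attribute_reads()` locates the span in each read (either orientation) by
exact anchored search of the span's copy-invariant flanks
(`span_with_anchors()` derives the widest usable span), then reads the bases
at every key position. A read is assigned only if it covers the span entirely
and matches exactly one copy profile; failures are counted as not spanning /
ambiguous / conflicting. A read erring at even one key position is
"conflicting" by default — there is no principled rescue rule for
near-identical copies — and `max_key_mismatch` relaxes this explicitly; note
that at toy divergence a single allowed mismatch often makes two copies
tie, which is reported as "ambiguous", not silently assigned.

## Mechanism inference

*Microhomology.* A junction is described by its two donor loci and their
junction offsets. `junction_microhomology()` computes `perfect_len` — the
maximal window spanning the junction over which the donors are identical —
by extending from the junction in both directions, and `imperfect_len` — the
maximal window containing the perfect core with at most `mismatch_budget`
(default 1) mismatches — by exhaustive window scan. With an empty perfect
core the imperfect window must still straddle the junction. The 1-mismatch
default formalizes "imperfect microhomology" in the sense of descriptions
such as 4 bp perfect within 8 bp imperfect homology; the budget is a
parameter because no standard definition exists.

*Crossover windows.* `divergent_columns()` removes gap-containing columns and
reports columns where the A row differs from the L row (columns varying only
in intermediates are uninformative and never appear).
`classify_intermediate()` labels the intermediate's base per column as A, L
or other (other is excluded from the fit). `infer_crossover_window()` fits a
two-state single-changepoint model — L before, A after — by exhaustive scan,
preferring it over an HMM because it is directly oracle-verifiable and
matches the qualitative "transition" being modelled. The window is bounded by
the informative columns adjacent to the optimal changepoint; with ties it is
the union over all optima, mirroring how such windows are reported as ranges.
Residual mismatches are flagged as putative gene-conversion tracts, not
modelled. All-A-then-L sequences fit the reversed model better and are
flagged non-canonical with no window; all-one-label sequences give a
degenerate window at the sequence end. `compare_crossovers()` groups
assemblies by transitive window overlap; the number of groups is the minimum
number of independent expansion events.

## Protein divergence

Identity is 100 × identical / gap-free columns. "Divergent between ecotypes"
is formalized as residue-set disjointness per column — the strictest reading
of "changed in all freshwater relative to marine", and the only one that is
invariant to row order and duplication. Domain enrichment is the exact
hypergeometric upper tail P(X ≥ k) with N = protein length, K = domain
length, n = divergent sites, k = sites in the domain; for the myosin-scale
worked case (N = 1931, K = 51 for residues 33–83, n = 18, k = 3) it evaluates
to 0.0107, i.e. 0.01 at reporting precision. The in-domain count k = 3
follows the three charged-residue substitutions described for that domain;
the computation is correct for any k. `cds_integrity()` classifies a CDS
against a reference frame: internal stop → nonsense-truncated (at that
residue), length difference not divisible by 3 → frameshift-truncated (at the
first stop in the shifted frame), clean 3n deletion → in-frame deletion, else
intact.

## Numerical and testing choices

Coordinates are 1-based inclusive internally (the Bioconductor convention);
BED output converts to 0-based half-open. All randomness flows through
`with_seed()`, which restores the caller's RNG state. Problem sizes in the
test-suite properties: copy-number recovery uses 100 seeded diploids over
3–6-copy haplotypes at 8× and 17.6 kb units; ASE calibration uses 100
replicates of 1,200 pairs per truth value p ∈ {0.5, 0.6, 0.75} with
fragment-spaced sets; crossover containment uses 100 NAHR products at 2 kb
units; the changepoint fit is checked against brute force on every L/A string
of length ≤ 12; k-mer counting is checked exactly against a quadratic scan on
1,000 error-bearing pairs.

## What the synthetic data does not emulate

Substitution-only divergence (no indels at junctions or between units, so
alignment-coordinate drift is absent); uniform base composition; no
base-quality structure, PCR duplicates or platform error profiles; no
mappability variation outside the duplication units — the collapsed-coverage
projection is an idealized aligner. Passing tests therefore demonstrate the
estimators' correctness and calibration under their stated models, not
robustness to alignment artefacts in real data; on real data the package
expects upstream alignment and consumes coverage tracks, BAMs, alignments
and sequences through the same interfaces.
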