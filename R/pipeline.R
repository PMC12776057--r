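# End-to-end orchestration: forge a diploid fixture, calibrate and call copy
# number, quantify copy/allele expression with k-mers, and infer mechanism.
# Every stage writes plain-text outputs plus a checksum manifest; identical
# configs reproduce identical files.

#' Pipeline configuration
#'
#' Central configuration for [run_pipeline()].  Every parameter defaults to
#' the study convention: k = 27 k-mers, MAPQ >= 3 depth filtering, 76 bp
#' paired reads (fragment 150 +/- 50) at 8x depth, ASE quality thresholds of
#' 100 total reads with both alleles seen and every k-mer detected.
#'
#' @param seed master seed; stage seeds are derived from it
#' @param genotype haplotype copy counts of the simulated diploid, c(low, high)
#' @param crossover_pos unit offset of the planted unequal crossover
#' @param microhomology_len_bp planted perfect microhomology
#' @param depth_x simulated DNA depth
#' @param n_rna_pairs simulated RNA pairs
#' @param k k-mer length
#' @param min_ase_total,min_ase_each ASE QC thresholds
#' @param stages character vector of stages to run, a subset of
#'   c("forge", "depth", "kmer", "mech")
#' @export
pipeline_config <- function(seed = 1L, genotype = c(3L, 5L),
                            crossover_pos = 1000L, microhomology_len_bp = 4L,
                            depth_x = 8, n_rna_pairs = 20000L, k = 27L,
                            min_ase_total = 100L, min_ase_each = 1L,
                            stages = c("forge", "depth", "kmer", "mech")) {
  required <- c("seed", "genotype", "crossover_pos")
  for (f in required) if (is.null(get(f))) stop_field(f, "is required")
  if (length(genotype) != 2L || any(genotype < 3L) || any(genotype > 6L))
    stop_field("genotype", "must be two haplotype copy counts in [3, 6]")
  bad <- setdiff(stages, c("forge", "depth", "kmer", "mech"))
  if (length(bad)) stop_field("stages", paste("unknown stage:", bad[1]))
  structure(list(seed = as.integer(seed), genotype = sort(as.integer(genotype)),
                 crossover_pos = as.integer(crossover_pos),
                 microhomology_len_bp = as.integer(microhomology_len_bp),
                 depth_x = depth_x, n_rna_pairs = as.integer(n_rna_pairs),
                 k = as.integer(k), min_ase_total = as.integer(min_ase_total),
                 min_ase_each = as.integer(min_ase_each), stages = stages),
            class = "pipeline_config")
}

forge_pair <- function(cc, seed, crossover_pos, microhomology_len_bp, ecotype) {
  spec <- haplotype_spec(ecotype = ecotype, copy_count = cc,
                         crossover_pos = if (cc >= 5L) crossover_pos,
                         microhomology_len_bp = microhomology_len_bp,
                         seed = seed)
  forge_haplotype(spec)
}

#' Run the pipeline end to end
#'
#' Stages run in dependency order and write their outputs under `out_dir`:
#' `forge` (haplotype FASTA + truth TSV/BED), `depth` (calibration table and
#' the diploid's normalized depth and genotype call), `kmer` (designed k-mer
#' sets, counts, RPM and ASE tables from simulated RNA pairs) and `mech`
#' (junction microhomology and crossover-window tables).  A manifest with an
#' md5 checksum per output closes the run.
#'
#' @param config a `pipeline_config`
#' @param out_dir run directory (created if needed)
#' @return named list of stage results (invisibly also written as files)
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p); written <<- c(written, p); p
  }
  message("[forge] building diploid genotype ",
          paste(config$genotype, collapse = "/"))
  h1 <- forge_pair(config$genotype[1], config$seed, config$crossover_pos,
                   config$microhomology_len_bp, "marine")
  h2 <- forge_pair(config$genotype[2], config$seed, config$crossover_pos,
                   config$microhomology_len_bp, "freshwater")
  res$haplotypes <- list(h1 = h1, h2 = h2)
  if ("forge" %in% config$stages) {
    p <- file.path(out_dir, "haplotypes.fasta")
    write_fasta(c(hap1 = h1$sequence, hap2 = h2$sequence), p)
    written <- c(written, p)
    for (nm in c("h1", "h2")) {
      tt <- truth_tables(res$haplotypes[[nm]], nm)
      emit(tt$features, paste0("truth_", nm, "_features.tsv"))
      emit(tt$snps, paste0("truth_", nm, "_snps.tsv"))
      p <- file.path(out_dir, paste0("truth_", nm, ".bed"))
      write_bed(tt$features, p); written <- c(written, p)
    }
  }
  if ("depth" %in% config$stages) {
    message("[depth] calibrating copy-number table and calling the diploid")
    ## depth runs at near-real locus scale (~17.6 kb units): at WGS depths the
    ## precision of a read-depth genotype comes from the unit length
    depth_spec <- function(cc, ecotype, seed) haplotype_spec(
      ecotype, cc, gene_length_bp = 5000L, dup_region_length_bp = 17600L,
      intergenic_length_bp = 3000L,
      crossover_pos = if (cc >= 5L) config$crossover_pos,
      microhomology_len_bp = config$microhomology_len_bp, seed = seed)
    cal <- lapply(3:6, function(cc)
      forge_haplotype(depth_spec(cc, "freshwater", config$seed + 17L)))
    names(cal) <- 3:6
    params <- read_sim_params(depth_x = config$depth_x, seed = config$seed + 29L)
    tab <- build_call_table(cal, params, n_reps = 2L)
    d1 <- forge_haplotype(depth_spec(config$genotype[1], "marine", config$seed))
    d2 <- forge_haplotype(depth_spec(config$genotype[2], "freshwater", config$seed))
    nd <- hap_norm_depth(list(d1, d2),
                         read_sim_params(depth_x = config$depth_x,
                                         seed = config$seed + 31L))
    call <- call_genotype(nd, tab)
    res$depth <- list(table = tab, norm_depth = nd, call = call)
    emit(tab, "call_table.tsv")
    emit(data.frame(norm_depth = nd, called_total = call$total,
                    true_total = sum(config$genotype), distance = call$distance),
         "genotype_call.tsv")
  }
  if ("kmer" %in% config$stages) {
    message("[kmer] designing and counting discriminating k-mers")
    kq <- pipeline_kmer_stage(h1, h2, config)
    res$kmer <- kq
    emit(kq$sets_table, "kmer_sets.tsv")
    emit(kq$counts$counts, "kmer_counts.tsv")
    emit(kq$ase, "ase.tsv")
  }
  if ("mech" %in% config$stages) {
    message("[mech] junction microhomology and crossover window")
    mh <- junction_microhomology(junction_context(h2))
    res$mech <- list(microhomology = mh)
    mech_df <- data.frame(perfect_len = mh$perfect_len,
                          imperfect_len = mh$imperfect_len,
                          planted = h2$planted_microhomology_bp)
    if (!is.null(h2$planted_crossover_interval) && nrow(h2$units) >= 3L) {
      aln <- c(A = substr(h2$sequence, h2$units$start[1], h2$units$end[1]),
               B = substr(h2$sequence, h2$units$start[2], h2$units$end[2]),
               L = substr(h2$sequence, h2$units$start[nrow(h2$units)],
                          h2$units$end[nrow(h2$units)]))
      cols <- divergent_columns(aln)
      lab <- classify_intermediate(cols, aln, "B")
      cw <- infer_crossover_window(lab$label, lab$pos_alignment)
      res$mech$crossover <- cw
      mech_df$window_lo <- cw$window[1]; mech_df$window_hi <- cw$window[2]
      mech_df$planted_lo <- h2$planted_crossover_interval[1]
      mech_df$planted_hi <- h2$planted_crossover_interval[2]
    }
    emit(mech_df, "mechanism.tsv")
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}

## RNA k-mer quantification over a 2-allele diploid: transcripts are the C3
## gene copies of each haplotype, expressed equally per copy.
pipeline_kmer_stage <- function(h1, h2, config) {
  tx <- function(h, allele) {
    c3 <- h$copies[grepl("^C3", h$copies$label), , drop = FALSE]
    setNames(substr(rep(h$sequence, nrow(c3)), c3$start, c3$end),
             paste0(allele, "_", c3$label))
  }
  t1 <- tx(h1, "A1"); t2 <- tx(h2, "A2")
  ## alignment rows: one consensus transcript per allele for the C3 "copy"
  ## (C3 copies within an allele are near-identical); plus flanking genes as
  ## distinct copies so k-mers must discriminate.
  gene_seq <- function(h, lab) {
    iv <- h$copies[h$copies$label == lab, ]
    substr(h$sequence, iv$start, iv$end)
  }
  aln <- paralog_alignment(
    c(gene_seq(h1, "C1"), gene_seq(h2, "C1"),
      gene_seq(h1, "C2"), gene_seq(h2, "C2"),
      t1[[1]], t2[[1]]),
    copy = c("C1", "C1", "C2", "C2", "C3", "C3"),
    allele = rep(c("A1", "A2"), 3))
  sets <- c(design_kmers(aln, "MCE", k = config$k),
            design_kmers(aln, "ASE", k = config$k, target = "C3"))
  ## confirm every member detects all transcripts of its intended target --
  ## C3 copies within an allele have diverged slightly, and a k-mer that has
  ## lost one of them would bias the counts
  detects_all <- function(km, txs)
    all(vapply(txs, function(t) grepl(km, t, fixed = TRUE), logical(1)))
  confirmed <- vapply(sets, function(s) {
    if (s$mode == "ASE" && identical(s$copy, "C3")) {
      detects_all(s$members[["A1"]], t1) && detects_all(s$members[["A2"]], t2)
    } else if (s$mode == "MCE") {
      detects_all(s$members[["C3"]], c(t1, t2))
    } else TRUE
  }, logical(1))
  sets <- sets[confirmed]
  pool <- weighted_pool(c(names(t1), names(t2)), c(t1, t2))
  pr <- simulate_paired_reads(pool, read_sim_params(
    n_pairs = config$n_rna_pairs, seed = config$seed + 41L))
  counts <- count_pairs(pr$r1, pr$r2, sets)
  ase <- ase_proportion(counts, allele1 = "A2",
                        min_total = config$min_ase_total,
                        min_each = config$min_ase_each)
  sets_table <- do.call(rbind, lapply(sets, function(s)
    data.frame(id = s$id, mode = s$mode, copy = s$copy, window = s$window,
               members = paste(unlist(s$members), collapse = ","),
               stringsAsFactors = FALSE)))
  list(sets = sets, sets_table = sets_table, counts = counts, ase = ase,
       expected_ase = dosage_expected_proportion(
         sum(grepl("^C3", h2$copies$label)), sum(grepl("^C3", h1$copies$label))))
}
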