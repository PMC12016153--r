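# Shared study configuration for the analysis scripts.
#
# The simulated study: one bacterial-sized replicon carrying a
# palindromic Dam-like GATC motif (6mA on both strands) and a bipartite
# Type I-like motif GAAANNNNNNG*GG (6mA / 4mC on opposite strands), a
# weakly supported GAAGAC-like motif, and a rarely methylated TCGA
# background motif; 100x per-strand coverage, per-read modified-call
# probability 0.9, 5% filter-failing and 5% mismatching reads, and
# methylation-induced G-to-A miscalls 5' of 6mA at rate 0.5.
#
# Scripts source this file from the repository root:
#   Rscript analysis/01_simulate.R

library(methylscope)

SIM_DIR <- "scratch/simdata"
RESULTS_DIR <- "results/analysis"
STUDY_SEED <- 20260924L

study_motifs <- function() {
  list(
    `GAT*C` = motif("GATC", c(1, 2), c("6mA", "6mA"), c(FALSE, TRUE)),
    `GAAANNNNNNG*GG` = motif("GAAANNNNNNGGG", c(3, 10), c("6mA", "4mC"),
                             c(FALSE, TRUE)),
    GAAGAC = motif("GAAGAC", 4, "6mA", FALSE),
    TCGA = motif("TCGA", 1, "5mC", FALSE))
}

study_config <- function(seed = STUDY_SEED, coverage = 100) {
  m <- study_motifs()
  simulation_config(
    genome_length = 120000, gc_content = 0.45, seed = seed,
    motifs = list(
      motif_spec(m[["GAT*C"]], planted_count = 250, p_site = 0.98),
      motif_spec(m[["GAAANNNNNNG*GG"]], planted_count = 120,
                 p_site = 0.95),
      # weak per-read support: the partially-methylated regime
      motif_spec(m[["GAAGAC"]], planted_count = 150, p_site = 0.95,
                 p_read = 0.6),
      # background-only motif, rarely methylated
      motif_spec(m[["TCGA"]], p_site = 0.05)),
    coverage = coverage, p_read = 0.9, p_fail = 0.05, p_diff = 0.05,
    background_call_rate = 2e-4,
    ambiguity_error_rate = 0.5)
}

ensure_bundle <- function() {
  if (!file.exists(file.path(SIM_DIR, "genome.fasta")))
    stop("simulated bundle missing; run analysis/01_simulate.R first")
  dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
  list(
    genome = read_fasta(file.path(SIM_DIR, "genome.fasta")),
    genes = read_gff3(file.path(SIM_DIR, "annotation.gff3")),
    pileup = read_bedmethyl(file.path(SIM_DIR, "pileup.bedmethyl")),
    counts = data.table::fread(file.path(SIM_DIR, "strand_counts.tsv"),
                               sep = "\t", data.table = FALSE),
    truth = list(
      methylated_sites = data.table::fread(
        file.path(SIM_DIR, "truth_methylated.tsv"), sep = "\t",
        data.table = FALSE),
      planted = data.table::fread(
        file.path(SIM_DIR, "truth_planted.tsv"), sep = "\t",
        data.table = FALSE),
      ambiguous_truth = data.table::fread(
        file.path(SIM_DIR, "truth_ambiguous.tsv"), sep = "\t",
        data.table = FALSE)))
}
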