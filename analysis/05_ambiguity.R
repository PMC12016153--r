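#!/usr/bin/env Rscript
# Methylation-induced strand-specific basecalling ambiguities: detect
# R/Y sites from strand-split counts, associate them with adjacent 6mA,
# count strand discordance at a lower error rate (the new-basecaller
# scenario), mask the genome and export the DNA-logo context matrix.

source("analysis/00_study_config.R")
d <- ensure_bundle()
calls <- call_methylation(d$pileup)

sites <- detect_ambiguous(d$counts, d$genome, min_cov = 10,
                          min_minor_frac = 0.2)
sites <- associate_ambiguous(sites, calls)
data.table::fwrite(sites, file.path(RESULTS_DIR, "ambiguous_sites.tsv"),
                   sep = "\t")
truth <- d$truth$ambiguous_truth
recovered <- mean(paste(truth$position, truth$code) %in%
                    paste(sites$position, sites$code))
message(sprintf("ambiguous sites: %d detected (%.1f%% of %d planted)",
                nrow(sites), 100 * recovered, nrow(truth)))
message(sprintf("associated with an adjacent methylated adenine: %.1f%%",
                100 * mean(sites$association_kind != "none")))

# improved-basecaller scenario: rerun the read-level error process at a
# 10x lower miscall rate on the same genome/truth
cfg_new <- study_config()
cfg_new$ambiguity_error_rate <- 0.05
gen <- list(genome = d$genome, truth = d$truth)
counts_new <- simulate_strand_counts(d$genome, d$truth, cfg_new)
n_old <- count_discordant(d$counts, d$genome, min_frac = 0.2)$n
n_new <- count_discordant(counts_new, d$genome, min_frac = 0.2)$n
message(sprintf("strand-discordant sites: %d (error rate 0.5) -> %d (0.05)",
                n_old, n_new))
data.table::fwrite(
  data.frame(error_rate = c(0.5, 0.05), discordant_sites = c(n_old, n_new)),
  file.path(RESULTS_DIR, "discordance_by_error_rate.tsv"), sep = "\t")

masked <- mask_genome(d$genome, sites)
write_fasta(masked, file.path(SIM_DIR, "masked_genome.fasta"))

pfm <- context_pfm(sites, d$genome, k = 5)
data.table::fwrite(data.frame(offset = rownames(pfm), pfm),
                   file.path(RESULTS_DIR, "context_pfm.tsv"), sep = "\t")
consensus <- apply(pfm, 1, function(r) c("A", "C", "G", "T")[which.max(r)])
message("context consensus 5'->3' on the erroneous strand: ",
        paste(consensus, collapse = ""))
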