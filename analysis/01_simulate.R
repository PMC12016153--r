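#!/usr/bin/env Rscript
# Generate the simulated study: genome with planted methylation motifs,
# Bakta-style annotation, bedMethyl pileup, strand-split base counts and
# ground-truth manifests. Everything downstream reads this bundle.

source("analysis/00_study_config.R")

cfg <- study_config()
message("simulating ", cfg$genome_length, " b genome with ",
        length(cfg$motifs), " motif systems at ", cfg$coverage,
        "x per-strand coverage (seed ", cfg$seed, ")")

b <- simulate_bundle(cfg, SIM_DIR)

message("planted occurrences:   ", nrow(b$truth$planted))
message("methylated truth sites: ", nrow(b$truth$methylated_sites))
message("discordance contexts:   ", nrow(b$truth$ambiguous_truth))
message("pileup records:         ", nrow(b$pileup))
message("annotated features:     ", nrow(b$genes))
message("bundle written under ", SIM_DIR)
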