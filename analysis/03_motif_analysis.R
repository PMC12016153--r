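#!/usr/bin/env Rscript
# Motif-level summaries: occurrence counts, fraction of occurrences
# methylated per methylated site (the heatmap matrix), threshold
# sensitivity for weakly supported motifs, fraction of 6mA explained,
# and de novo motif discovery compared against the planted truth.

source("analysis/00_study_config.R")
d <- ensure_bundle()
motifs <- study_motifs()
calls <- call_methylation(d$pileup)

summaries <- do.call(rbind, lapply(names(motifs), function(nm) {
  s5 <- evaluate_motif(d$genome, calls, motifs[[nm]], threshold = 0.5)
  s3 <- evaluate_motif(d$genome, calls, motifs[[nm]], threshold = 0.3)
  cbind(s5, frac_methylated_at_0.3 = s3$frac_methylated)
}))
data.table::fwrite(summaries, file.path(RESULTS_DIR, "motif_summary.tsv"),
                   sep = "\t")
message("per-site methylated fractions (threshold 0.5 vs 0.3):")
for (i in seq_len(nrow(summaries)))
  message(sprintf("  %-16s %s  %5.1f%% -> %5.1f%%  (n=%d)",
                  summaries$motif[i], summaries$mod_type[i],
                  100 * summaries$frac_methylated[i],
                  100 * summaries$frac_methylated_at_0.3[i],
                  summaries$n_occurrences[i]))

expl <- do.call(rbind, lapply(c("6mA", "5mC", "4mC"), function(mt)
  data.frame(mod_type = mt, fraction_explained = fraction_explained(
    calls, d$genome, motifs, mt))))
data.table::fwrite(expl, file.path(RESULTS_DIR, "fraction_explained.tsv"),
                   sep = "\t")
message(sprintf("6mA bases explained by motifs: %.1f%%",
                100 * expl$fraction_explained[expl$mod_type == "6mA"]))

found <- suppressWarnings(find_motifs_denovo(d$genome, calls, "6mA"))
message("de novo 6mA motifs: ",
        paste(vapply(found, motif_label, character(1)), collapse = ", "))
data.table::fwrite(
  data.frame(motif = vapply(found, motif_label, character(1)),
             pattern = vapply(found, function(m) m$pattern, character(1)),
             offset = vapply(found, function(m) m$meth_sites$offset[1],
                             integer(1))),
  file.path(RESULTS_DIR, "denovo_motifs.tsv"), sep = "\t")
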