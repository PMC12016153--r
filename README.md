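# methylscope

Bacterial methylome analysis from modified-base pileups.

Bacterial DNA methylation — N6-methyladenine (6mA), 5-methylcytosine
(5mC) and N4-methylcytosine (4mC) — is motif-driven: methyltransferases,
mostly from restriction–modification systems, methylate nearly every
occurrence of their recognition sequence (palindromes like `GATC`,
bipartite Type I targets like `GAAANNNNNNGGG`, short non-palindromic
Type III targets like `GAAGAC`). Nanopore sequencing reads these
modifications directly, and pileup tools aggregate them into a
per-position, per-strand count table (the 18-column bedMethyl dialect).
`methylscope` is an R package for everything downstream of that table,
written for microbial genomics groups analyzing bacterial methylomes:

- **Per-position statistics and calling.** For each position,
  *Fraction Modified* = `N_mod / N_valid_cov` and the stricter
  *Percent Modified* = `N_mod / (N_valid_cov + N_fail + N_diff)`, which
  counts confidence-filtered and mismatching reads in the denominator
  and therefore resists false positives at low valid coverage. A
  position is methylated when Percent Modified > 0.5 (strict; 0.3
  available for weakly supported motifs).
- **Motif machinery.** IUPAC motif scanning on both strands with full
  both-strand methylated-site bookkeeping and asterisk-notation
  rendering (`GAT*C`); per-motif summaries (fraction of occurrences
  methylated, mean Percent Modified); evaluation of candidate motifs;
  fraction of methylated bases explained by a motif set; and de novo
  motif discovery from methylated-base sequence contexts.
- **Genomic context.** Per-gene methylation density with COG grouping
  and deterministic top-5% flagging; mean raw Percent Modified in
  1000-base windows; Percent Modified histograms per feature class;
  strand-aware 40-base promoter / gene-start / gene-end regions, their
  union's genome fraction, and per-motif region proportions.
- **Basecalling-ambiguity detection.** Methylation-induced strand-specific
  errors (the G immediately 5' of a 6mA miscalled as A on the methylated
  strand) detected from strand-split base counts as IUPAC R/Y mixtures,
  associated with the adjacent methylated adenine, masked into the
  genome, and summarized as DNA-logo-ready context matrices.
- **A synthetic-data generator** that emits genome, annotation, pileup
  and strand counts with ground-truth manifests, so the entire pipeline
  is testable — and was tested — without sequencing data.

## Worked example

Simulate a 50 kb genome carrying a Dam-like `GATC` system, call
methylation, and summarize the motif:

```r
library(methylscope)

gatc <- motif("GATC", offsets = c(1, 2), mod_types = c("6mA", "6mA"),
              on_reverse = c(FALSE, TRUE))   # rendered "GAT*C"
cfg <- simulation_config(
  genome_length = 50000, seed = 42,
  motifs = list(motif_spec(gatc, planted_count = 150, p_site = 0.98)),
  coverage = 100, p_read = 0.9, p_fail = 0.05, p_diff = 0.05,
  ambiguity_error_rate = 0.5)

gen    <- generate_genome(cfg)
pileup <- simulate_pileup(gen$genome, gen$truth, cfg)
calls  <- call_methylation(pileup, threshold = 0.5)

evaluate_motif(gen$genome, calls, gatc)[
  , c("motif", "mod_type", "n_occurrences", "n_methylated",
      "frac_methylated", "mean_percent_modified")]
#>   motif mod_type n_occurrences n_methylated frac_methylated mean_percent_modified
#> 1 GAT*C      6mA           696          684       0.9827586             0.7938362
#> 2 GAT*C      6mA           696          684       0.9827586             0.7938362

fraction_explained(calls, gen$genome, list(gatc), "6mA")
#> [1] 1

counts <- simulate_strand_counts(gen$genome, gen$truth, cfg)
sites  <- associate_ambiguous(detect_ambiguous(counts, gen$genome), calls)
nrow(sites); mean(sites$association_kind != "none")
#> [1] 684
#> [1] 1
```

Reading the output: the genome ends up with 696 GATC occurrences per
strand (150 planted plus accidental matches — all of which the simulated
methyltransferase treats alike); 98.3% of them are methylated
(`p_site = 0.98`), one summary row per methylated site of the motif
(both rows of a palindrome cover the same duplex adenines). Mean Percent
Modified is 0.79 ≈ `p_read × (1 − p_fail − p_diff)`. Every methylated
6mA lies inside a GATC (no background signal was configured), and every
methylated adenine whose 5' neighbour is a G produces a detectable R/Y
ambiguity at a 50% miscall rate, each linked back to its adenine.

Real data enters through `read_fasta()`, `read_gff3()`,
`read_bedmethyl()` and a strand-count TSV; `run_pipeline(run_config(...))`
executes calling → motifs → genomic context → ambiguity end-to-end and
writes all stage TSVs, a motif table and a run log.

## The analysis workflow

The `analysis/` directory holds the study as numbered drivers, each a
thin narrative over the package functions, writing summary tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R          # genome + annotation + pileup + counts
Rscript analysis/02_call_methylation.R  # calls, threshold sensitivity
Rscript analysis/03_motif_analysis.R    # summaries, fraction explained, discovery
Rscript analysis/04_genomic_context.R   # gene/window density, regions
Rscript analysis/05_ambiguity.R         # R/Y detection, masking, logo matrix
Rscript analysis/06_replicates.R        # replicate agreement (Jaccard)
```

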