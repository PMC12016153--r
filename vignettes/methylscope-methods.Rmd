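---
title: "Bacterial methylome analysis from modified-base pileups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bacterial methylome analysis from modified-base pileups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscope)
```

## Scope and rationale

Bacterial genomes carry three common DNA modifications — N6-methyladenine
(6mA), 5-methylcytosine (5mC) and N4-methylcytosine (4mC) — laid down by
methyltransferases at short recognition motifs, most of them components of
restriction–modification (RM) systems. Nanopore sequencing detects these
modifications directly, and modern modified-base pileup tools aggregate
the per-read calls into a per-position, per-strand count table (the
18-column bedMethyl dialect). `methylscope` starts at that table and
answers the questions a bacterial methylome study asks of it:

1. Which positions are methylated, and how confidently?
2. Which sequence motifs carry the methylation, at what fraction of their
   occurrences, and how much of the signal do motifs explain?
3. How is methylation distributed over genes, COG functional categories,
   fixed-width windows, and the 40-base promoter/start/end regulatory
   regions?
4. Where does methylation break the basecaller — the strand-specific
   G-to-A miscalls immediately 5' of a 6mA that surface as IUPAC R/Y
   ambiguities — and how can those positions be masked?

Raw-signal processing, basecalling, assembly, alignment and annotation
are out of scope: the pipeline consumes a genome FASTA, a GFF3
annotation, a bedMethyl pileup, and (for the ambiguity module) a
strand-split base-count table. Because the original sequencing data
cannot be bundled, the package ships a synthetic-data generator that
emits all four inputs with known ground truth; every analysis stage is
tested against that truth.

## Per-position statistics

For a position with `n_mod` modified-call reads, `n_canonical`
canonical-call reads, `n_fail` reads failing the basecaller's confidence
filter and `n_diff` reads whose base differs from the canonical base,
the two statistics are

- **Fraction Modified** = `n_mod / n_valid_cov`, with
  `n_valid_cov = n_mod + n_canonical (+ n_other_mod)` — the upstream
  pileup tool's quantity. It is fragile at low valid coverage: three
  confident modified reads out of three give 1.0 even when thirty other
  reads failed the filter.
- **Percent Modified** = `n_mod / (n_valid_cov + n_fail + n_diff)` — the
  stricter statistic used for all calling here. Counting the filtered and
  mismatching reads in the denominator makes it a measure of agreement
  among *all* reads, so Percent Modified ≤ Fraction Modified always.
  Deletion reads are excluded from the denominator (whether they belong
  there is not determinable from the formula's definition; excluding them
  is the conservative choice and they are zero in the simulator anyway).

A position is **called methylated when Percent Modified is strictly
greater than the threshold** (default 0.5, i.e. more than half of all
reads support the modification). The strictness matters at the boundary:
PM = 0.5 exactly is not methylated. A relaxed threshold of 0.3 is
exposed throughout because motifs whose per-read support is weak
(mean PM 0.55–0.6) look "partially methylated" at 0.5 yet show >95% of
occurrences methylated at 0.3 — a threshold-sensitivity behaviour the
analysis scripts demonstrate. Positions with fewer than `min_total_reads`
(default 5) total reads are flagged `low_coverage` and left uncalled
rather than being allowed to produce confident-looking calls from a
handful of reads. The upstream filter threshold (0.75) that defines
which reads land in `n_fail` is metadata of the pileup, not a parameter
of this package; the simulator emulates its effect through `p_fail`.

All coordinates are 0-based half-open (BED convention) in memory and in
TSV outputs; GFF3 input/output converts to and from that format's
1-based inclusive convention.

## Motif model

A motif is an IUPAC pattern plus a list of methylated sites, each an
(offset, modification type, strand) triple; `on_reverse = TRUE` marks a
base methylated on the strand opposite the pattern's orientation, and is
rendered with a trailing asterisk (`GAT*C`, `CCWG*G`,
`GAAANNNNNNG*GG`). This carries the three RM-system geometries:
palindromes methylated symmetrically on both strands (Type II, GATC),
long bipartite patterns with one methylated base per strand (Type I,
GAAANNNNNNGGG with 6mA at offset 3 and 4mC opposite offset 10), and
short non-palindromic patterns (Type III, GAAGAC).

**Scanning.** The scanner reports every plus-strand match of the pattern
and every plus-strand match of its reverse complement (reported as
strand "−"); palindromic motifs therefore yield one occurrence per
strand at the same start, deliberately, because the two orientations
carry distinct methylated-base coordinates. Overlapping occurrences are
all reported. Matching is implemented as a bit-mask comparison (A=1,
C=2, G=4, T=8; a pattern character's mask is the union of its
expansion). One semantic choice departs from the usual
ambiguity-intersection rule: a non-A/C/G/T letter in the *genome* (an
R/Y-masked base from the ambiguity module, or an assembly N) matches
**only** pattern N. On a masked assembly this is the conservative
behaviour — a masked base should never satisfy a specific pattern
position. The scanner is validated exhaustively against two independent
oracles (a character-by-character matcher and `Biostrings::matchPattern`
with `fixed = FALSE`) over hundreds of random sequences and all the RM
motif patterns exercised in the tests.

**Summaries.** `summarize_motif` produces one row per methylated site of
the motif (so a bipartite motif yields two rows, and a palindrome's
single 6mA row counts both strands' adenines). An occurrence counts as
methylated when its methylatable base's call has PM above the threshold;
occurrences with no call are counted as unmethylated *and* tallied
separately as `n_no_data`, and both denominators (all occurrences /
occurrences with data) are reported, since the convention is not
universal. `fraction_explained` is the complementary genome-wide view:
of all positions called methylated for a modification type, the fraction
coinciding with some motif's methylatable base.

## De novo motif discovery

The discovery procedure is the package's own design (the established
tools' algorithms are not public in reusable form). It operates on the
reference context ±`context_k` (default 10) around each methylated base,
reverse-complemented for minus-strand calls so the modified base is
centered and canonically oriented:

1. **Seed**: among remaining contexts, find the most frequent 4-mer in
   the four windows anchored at the center. Motif-family members share
   their fixed bases around the modified position, so the top word
   selects one family even when several motifs coexist. If the top word
   has fewer than `min_sites` supporters the whole remaining set is used
   (this rescues families whose near-center columns are degenerate).
2. **Refine**: compute a column-wise consensus of the subset — per
   column, the smallest IUPAC set covering at least `cover` (default
   0.9) of sites; columns needing all four bases become N — then
   re-match all remaining contexts against the specific columns and
   iterate until the support set stabilizes.
3. **Emit** the span from the outermost specific columns if it has at
   least two fully determined flanking bases, `min_sites` (default 50)
   supporters, and fold enrichment at least `min_fold` (default 4),
   where fold is the support rate divided by the genome-background
   probability of matching the pattern by chance (strand-symmetrized
   base frequencies). Supporters are peeled off and the next round
   begins.
4. **Merge**: discovered motifs of equal length and methylated offset
   differing in exactly one column are merged by widening that column's
   IUPAC code, to a fixpoint.

The merge step is what keeps degenerate columns honest: a motif like
CAGDAC is discovered as three single-base variants (CAGAAC, CAGGAC,
CAGTAC) and merged to D — it is *not* widened to N, because no
C-variant support exists. The 90% column-coverage default tolerates the
few percent of background contexts that leak into a family while keeping
random columns (top-3 bases cover only ~78% of sites) out of the
pattern. Known limitations: bipartite motifs whose two half-sites both
sit far from the modified base can fail the seeding step; motifs rarer
than `min_sites` are not reported (by design — the tests document this
with a 200-occurrence motif against `min_sites = 250`); and discovery
reports motifs in the canonical orientation of the methylated base only.

## Genomic context

- **Per-gene density** = methylated bases (both strands, each
  (position, strand) once) overlapping the gene interval, divided by
  annotated gene length. Genes are grouped by COG category downstream;
  the origin of replication is carried as an ordinary feature row. The
  top 5% flag selects exactly `ceiling(0.05 N)` genes by density, ties
  broken lexicographically by gene id so the flagging is deterministic.
- **Windowed density** averages *raw* Percent Modified values (no
  threshold) in tiling 1000-base windows, over positions that have a
  value — not over all bases; zero-filling absent positions would
  conflate missing data with canonical bases. Empty windows are emitted
  with an undefined mean so downstream plots show gaps rather than
  zeros. The final partial window is included.
- **PM histograms** per feature class cover the display range 0.1–1;
  values below 0.1 (the canonical-base bulk) are excluded, and
  proportions are normalized within each class.
- **Regulatory regions**: promoter = 40 bases upstream of the gene
  (strand-aware; wide enough to span the bacterial core promoter's −10
  and −35 elements), gene start = first 40 bases, gene end = last 40
  bases; minus-strand genes mirror; everything is clipped to contig
  bounds, and genes shorter than 80 bases have start/end regions
  truncated to the gene (they may overlap each other). The genome
  fraction covered is computed on the interval *union*, so overlapping
  regions of adjacent genes are counted once. Motif-level region
  proportions classify each *methylated base position* (not the motif
  span) into the three categories; a base may count in several
  categories and the categories are reported separately.

## Strand-specific ambiguity detection

The error pattern being modelled: the strand carrying a 6mA tends to
miscall the G immediately 5' of the methylated adenine as A. On the plus
strand this produces an A/G mixture (IUPAC R) one base before the 6mA;
the mirrored minus-strand case surfaces in plus-strand base space as a
C/T mixture (Y) one base after the (plus-coordinate of the) methylated
adenine. Strand-split counts are kept in reference orientation per
strand of origin — the standard pileup convention — which makes the R/Y
classification directly readable.

`detect_ambiguous` flags a position when, on a strand with depth at
least `min_cov` (default 10), the two most frequent bases are {A,G} or
{C,T} and the minor base reaches `min_minor_frac` (default 0.2) of the
strand's depth. The defaults are set so that binomial sequencing noise
at 100× with a ~1% error floor essentially never reaches the minor-base
bar, while a genuine methylation-induced miscall rate of 0.5 at the same
depth exceeds it with probability ~1 (P[Bin(100, 0.5) < 20] ≈ 1e-10).
Other mixtures (A/C etc.) are reported on a diagnostics channel but
never masked, since only R and Y carry the methylation signature.
`associate` links an R at p to a methylated 6mA call at p+1 on the plus
strand, and a Y at q to a 6mA on the minus strand at q−1 — exactly one
position, no windowed search, because the error is strictly adjacent.
`count_discordant` is the call-free analogue: a position is discordant
when the fraction of one strand's reads not supporting the other
strand's consensus reaches `min_frac`. (A majority-vs-majority rule
would miss half the sites at a 50% error rate, where the erroneous
strand's majority is a coin flip.) `mask_genome` substitutes the R/Y
code at each site after validating it against the reference base, and
`context_pfm` stacks the ±k reference windows (reverse-complemented for
minus-strand sites, so the context always reads 5'→3' on the erroneous
strand) into a position frequency matrix ready for DNA-logo rendering.

## The synthetic study

The generator emits the statistical structure the analysis assumes and
nothing more:

- **Genome**: i.i.d. bases at the configured GC content (default 0.5 in
  the package, 0.45 in the analysis scripts); no repeat structure, since
  none of the analyses depend on genome realism. Planted motif
  occurrences are placed uniformly at random without overlap, each a
  concrete instantiation of the IUPAC pattern on a random strand.
- **Methylation truth**: every occurrence of every configured motif in
  the emitted genome — planted or accidental — has each methylatable
  base drawn methylated independently with probability `p_site`
  (default 0.98, the near-complete methylation typical of active RM
  systems), because a methyltransferase does not distinguish planted
  from background sites. `background_only` motifs model weakly
  methylated patterns (e.g. `p_site = 0.05`).
- **Pileup**: constant per-strand depth (default 100×, matching a
  coverage-normalized study design; per-position Poisson depth is the
  obvious extension but constant depth keeps the binomial oracles
  exact). Per read: fail the confidence filter with `p_fail` (0.05),
  carry a non-canonical base with `p_diff` (0.05) — drawn jointly as a
  multinomial so counts always conserve depth — and, at methylated
  sites, be called modified with `p_read` (default 0.9). These defaults
  put Percent Modified at fully methylated sites near
  0.9 × 0.9 = 0.81, inside the 0.7–0.9 band typical of real 6mA motifs;
  `p_read = 0.6` reproduces the weak-support regime (mean PM ≈ 0.54).
  `n_delete`/`n_nocall` are emitted as zero — the statistics never use
  them. Off-motif positions receive the methylated treatment with
  probability `background_call_rate` (default 0).
- **Strand counts**: error-free except at planted G-before-6mA contexts,
  where the methylated strand's G reads are miscalled A with
  `ambiguity_error_rate`; an optional uniform error floor is available.
- **Annotation**: non-overlapping genes at one per ~1.1 kb with lengths
  ~N(1000, 100²), random strands, COG letters from a configurable
  alphabet, ~2% rRNA and ~3% tRNA features, and one ori feature placed
  in an intergenic gap. Intergenic gaps are near-uniform (slack shared
  with ±20% jitter) rather than exponential: at this density uniform
  gaps stay wider than the 40-base promoter flank, and the
  promoter/start/end union then covers ~10.5–11% of the genome, the
  regime the regulatory-region analysis operates in; exponential gaps
  would push ~1/3 of promoters into their neighbours and drop the
  union below 10%.
- **Reproducibility**: every generator stage derives its RNG stream from
  `seed` plus a fixed stage offset, so identical config + seed gives
  byte-identical FASTA/GFF3/bedMethyl/TSV outputs; the caller's RNG
  state is left untouched.

What the simulation does *not* emulate — and what passing tests
therefore do not show about real data: basecaller-specific error
correlation along reads, coverage heterogeneity, repeat-induced mapping
artefacts, motif-context-dependent modification-call quality, and the
empirical observation that particular bases flank real ambiguous sites.
The tests demonstrate that the *estimators* are correct and the
pipeline's accounting is exact, not that nanopore data behaves like the
generator.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study at 30–200 kb
genome sizes with 100× coverage — large enough that binomial intervals
are tight (a 200 kb genome carries ~2,500 GATC adenines, giving a 99%
interval of about ±0.7% around a 98% per-site rate) and small enough to
re-run freely. Windowed means use value-wise averaging as described;
histogram bin edges are compared with an absolute 1e-9 tolerance where
floating-point bin arithmetic is involved; `flag_top` and all report
tables have deterministic orderings so that byte-identity of outputs is
a meaningful pipeline invariant (and is asserted as one). Degenerate
inputs — empty gene sets, empty call sets, motifs absent from the
genome, zero-length windows, sites at contig edges — return empty or
NA-marked results rather than errors, except where the input is
malformed (negative counts, non-18-column bedMethyl, incompatible mask
codes), which fail loudly with the offending line or position named.
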