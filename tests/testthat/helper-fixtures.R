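# Shared fixtures and independent oracles, built in code.

# canonical palindromic Dam-like motif, methylated on both strands
gatc_motif <- function() {
  motif("GATC", offsets = c(1, 2), mod_types = c("6mA", "6mA"),
        on_reverse = c(FALSE, TRUE))
}

# bipartite Type I-like motif: 6mA on the pattern strand, 4mC opposite
bipartite_motif <- function() {
  motif("GAAANNNNNNGGG", offsets = c(3, 10),
        mod_types = c("6mA", "4mC"), on_reverse = c(FALSE, TRUE))
}

# all distinct motif patterns of the restriction-modification systems the
# pipeline is exercised on (palindromes, bipartite Type I, Type III)
rm_system_patterns <- function() {
  c("GATC", "CCWGG", "GACNNNNNNGTC", "AGCNNNNNCTTC", "GAAANNNNNNGGG",
    "GAAGAC", "TGGCCA", "GAAYNNNNNGTC", "TCGA", "CAGDAC",
    "CYAANNNNNNGRTY", "GWAGNNNNNGAT", "CGANNNNNNNTCC", "GAAGNNNNNTAC",
    "CCAYNNNNNNRTC", "CCAYNNNNNNTTYG", "CCAYNNNNNNTGT", "AGGNNNNNGAT")
}

# a minimal pileup record data.frame
pileup_row <- function(n_mod, n_canonical, n_fail = 0, n_diff = 0,
                       n_other_mod = 0, n_delete = 0, n_nocall = 0,
                       contig = "c1", start = 0L, strand = "+",
                       mod_code = "a") {
  data.frame(contig = contig, start = start, end = start + 1L,
             mod_code = mod_code, score = 0L, strand = strand,
             thick_start = start, thick_end = start + 1L,
             color = "255,0,0",
             n_valid_cov = n_mod + n_canonical + n_other_mod,
             frac_col = 0, n_mod = n_mod, n_canonical = n_canonical,
             n_other_mod = n_other_mod, n_delete = n_delete,
             n_fail = n_fail, n_diff = n_diff, n_nocall = n_nocall,
             mod_type = unname(c(a = "6mA", m = "5mC",
                                 `21839` = "4mC")[mod_code]),
             stringsAsFactors = FALSE)
}

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""), "c1")
}

# character-by-character brute-force IUPAC scanner: the slow independent
# oracle. Returns 0-based starts of `pattern` (plus orientation only).
brute_force_starts <- function(seq, pattern) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(pat)
  n <- length(chars)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      base <- chars[s + j]
      exp <- methylscope::IUPAC_CODES[[pat[j]]]
      if (base %in% c("A", "C", "G", "T")) {
        if (!base %in% exp) { ok <- FALSE; break }
      } else if (pat[j] != "N") { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Biostrings-based independent oracle for clean A/C/G/T subjects
biostrings_starts <- function(seq, pattern) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(seq),
                                fixed = FALSE)
  BiocGenerics::start(m) - 1L
}

# occurrence set (start/strand) via an oracle scanner
oracle_occurrences <- function(seq, pattern, starts_fun = biostrings_starts) {
  rc <- methylscope::revcomp(pattern)
  fwd <- starts_fun(seq, pattern)
  rev <- starts_fun(seq, rc)
  data.frame(start = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))),
             stringsAsFactors = FALSE)
}
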