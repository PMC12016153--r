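# Strand-discordance detection, R/Y classification, association geometry,
# masking and context matrices.

count_row <- function(position, strand, A = 0, C = 0, G = 0, T = 0,
                      contig = "c1") {
  data.frame(contig = contig, position = position, strand = strand,
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

test_that("detect_ambiguous classifies R and Y mixtures by definition", {
  g <- c(c1 = strrep("G", 10))
  counts <- rbind(
    count_row(2, "+", A = 40, G = 60),     # R, minor fraction 0.4
    count_row(5, "+", G = 100),            # unanimous
    count_row(7, "+", A = 10, G = 90))     # below min_minor_frac 0.2
  sites <- detect_ambiguous(counts, g, min_cov = 10, min_minor_frac = 0.2)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$position, 2)
  expect_equal(sites$code, "R")
  expect_equal(sites$minor_fraction, 0.4)
  expect_equal(sites$discordant_strand, "+")

  # minus-strand C/T mixture (a read-space A/G on the minus strand)
  g2 <- c(c1 = strrep("C", 10))
  s2 <- detect_ambiguous(count_row(4, "-", C = 55, T = 45), g2)
  expect_equal(s2$code, "Y")
  expect_equal(s2$discordant_strand, "-")

  # non-R/Y mixtures go to diagnostics, not sites
  s3 <- detect_ambiguous(count_row(3, "+", A = 50, C = 50), g)
  expect_equal(nrow(s3), 0)
  expect_equal(nrow(attr(s3, "diagnostics")), 1)

  # depth below min_cov never yields a site
  s4 <- detect_ambiguous(count_row(2, "+", A = 4, G = 5), g)
  expect_equal(nrow(s4), 0)
})

test_that("detection is monotone in its thresholds", {
  set.seed(61)
  counts <- do.call(rbind, lapply(0:199, function(p) {
    a <- rbinom(1, 100, 0.25)
    count_row(p, "+", A = a, G = 100 - a)
  }))
  g <- c(c1 = strrep("G", 200))
  n_at <- function(mf, mc) nrow(detect_ambiguous(counts, g, min_cov = mc,
                                                 min_minor_frac = mf))
  expect_gte(n_at(0.1, 10), n_at(0.2, 10))
  expect_gte(n_at(0.2, 10), n_at(0.3, 10))
  expect_gte(n_at(0.2, 10), n_at(0.2, 120))
})

test_that("association follows the immediate-adjacency geometry", {
  calls <- data.frame(
    contig = "c1", position = c(108, 54), strand = c("+", "-"),
    mod_type = "6mA", fraction_modified = 1, percent_modified = 0.9,
    is_methylated = TRUE, n_valid_cov = 90, low_coverage = FALSE,
    stringsAsFactors = FALSE)
  sites <- data.frame(
    contig = "c1", position = c(107, 55, 300), code = c("R", "Y", "R"),
    minor_fraction = 0.4, discordant_strand = c("+", "-", "+"),
    ref_base = c("G", "C", "G"), stringsAsFactors = FALSE)
  out <- associate_ambiguous(sites, calls)
  expect_equal(out$association_kind,
               c("R_before_plus_6mA", "Y_opposite_minus_6mA", "none"))
  expect_equal(out$associated_position, c(108, 54, NA))
  # exactly one position is searched: a 6mA two bases away does not link
  far <- associate_ambiguous(
    data.frame(contig = "c1", position = 106, code = "R",
               minor_fraction = 0.4, discordant_strand = "+",
               ref_base = "G", stringsAsFactors = FALSE), calls)
  expect_equal(far$association_kind, "none")
})

test_that("planted discordant sites are recovered and associated", {
  cfg <- simulation_config(genome_length = 30000, seed = 71,
                           motifs = list(motif_spec(gatc_motif(),
                                                    planted_count = 60,
                                                    p_site = 0.98)),
                           ambiguity_error_rate = 0.5, coverage = 100)
  gen <- generate_genome(cfg)
  counts <- simulate_strand_counts(gen$genome, gen$truth, cfg)
  sites <- detect_ambiguous(counts, gen$genome)
  truth <- gen$truth$ambiguous_truth
  # every planted discordant context is detected with the right code
  tkey <- paste(truth$contig, truth$position, truth$code)
  skey <- paste(sites$contig, sites$position, sites$code)
  expect_true(all(tkey %in% skey))
  expect_setequal(unique(sites$code), c("R", "Y"))
  # >= 95% associate to the correct adjacent methylated adenine
  pu <- simulate_pileup(gen$genome, gen$truth, cfg)
  calls <- call_methylation(pu)
  assoc <- associate_ambiguous(sites, calls)
  expect_gte(mean(assoc$association_kind != "none"), 0.95)
  linked <- assoc[assoc$association_kind != "none", ]
  mkey <- paste(truth$position, truth$meth_position)
  expect_true(all(paste(linked$position, linked$associated_position) %in%
                    mkey))
  # error-free run: no sites at all (no false positives)
  cfg0 <- simulation_config(genome_length = 30000, seed = 71,
                            motifs = list(motif_spec(gatc_motif(),
                                                     planted_count = 60,
                                                     p_site = 0.98)),
                            ambiguity_error_rate = 0, coverage = 100)
  gen0 <- generate_genome(cfg0)
  counts0 <- simulate_strand_counts(gen0$genome, gen0$truth, cfg0)
  expect_equal(nrow(detect_ambiguous(counts0, gen0$genome)), 0)
})

test_that("strand symmetry: reverse-complementing the data mirrors R to Y", {
  cfg <- simulation_config(genome_length = 8000, seed = 81,
                           motifs = list(motif_spec(gatc_motif(),
                                                    planted_count = 20)),
                           ambiguity_error_rate = 0.5)
  gen <- generate_genome(cfg)
  counts <- simulate_strand_counts(gen$genome, gen$truth, cfg)
  sites <- detect_ambiguous(counts, gen$genome)
  L <- nchar(gen$genome[[1]])
  rc_genome <- stats::setNames(revcomp(gen$genome[[1]]),
                               names(gen$genome))
  rc_counts <- counts
  rc_counts$position <- L - 1L - counts$position
  rc_counts$strand <- ifelse(counts$strand == "+", "-", "+")
  rc_counts$A <- counts$T; rc_counts$T <- counts$A
  rc_counts$C <- counts$G; rc_counts$G <- counts$C
  rc_sites <- detect_ambiguous(rc_counts, rc_genome)
  expect_equal(nrow(rc_sites), nrow(sites))
  expect_setequal(
    paste(L - 1L - rc_sites$position,
          ifelse(rc_sites$code == "R", "Y", "R")),
    paste(sites$position, sites$code))
})

test_that("count_discordant finds planted strand disagreement and nothing else", {
  cfg <- simulation_config(genome_length = 20000, seed = 91,
                           motifs = list(motif_spec(gatc_motif(),
                                                    planted_count = 20,
                                                    p_site = 1)),
                           ambiguity_error_rate = 0.5, coverage = 100)
  gen <- generate_genome(cfg)
  counts <- simulate_strand_counts(gen$genome, gen$truth, cfg)
  res <- count_discordant(counts, gen$genome, min_frac = 0.2)
  truth_pos <- gen$truth$ambiguous_truth$position
  expect_setequal(res$sites$position, truth_pos)
  expect_equal(res$n, length(unique(truth_pos)))
  # clean simulation: zero
  cfg0 <- simulation_config(genome_length = 20000, seed = 91,
                            ambiguity_error_rate = 0)
  gen0 <- generate_genome(cfg0)
  counts0 <- simulate_strand_counts(gen0$genome, gen0$truth, cfg0)
  expect_equal(count_discordant(counts0, gen0$genome)$n, 0)
  # lower error rate -> fewer or equal detected sites in expectation
  cfg_lo <- simulation_config(genome_length = 20000, seed = 91,
                              motifs = list(motif_spec(gatc_motif(),
                                                       planted_count = 20,
                                                       p_site = 1)),
                              ambiguity_error_rate = 0.05, coverage = 100)
  gen_lo <- generate_genome(cfg_lo)
  counts_lo <- simulate_strand_counts(gen_lo$genome, gen_lo$truth, cfg_lo)
  expect_lte(count_discordant(counts_lo, gen_lo$genome, min_frac = 0.2)$n,
             res$n)
})

test_that("mask_genome substitutes codes and validates compatibility", {
  g <- c(c1 = "ACGTACGT")
  sites <- data.frame(contig = "c1", position = 2, code = "R",
                      minor_fraction = 0.3, discordant_strand = "+",
                      ref_base = "G", stringsAsFactors = FALSE)
  masked <- mask_genome(g, sites)
  expect_equal(masked[[1]], "ACRTACGT")
  expect_equal(nchar(masked[[1]]), 8)
  # identity with no sites
  expect_equal(mask_genome(g, sites[0, ]), g)
  # incompatible code/reference pair errors
  bad <- sites; bad$position <- 1   # reference C cannot be R
  expect_error(mask_genome(g, bad), "incompatible")
  # masked positions match only N in patterns
  expect_equal(unique(scan_motif(masked, motif("ACGT"))$start), 4)
  expect_equal(sum(scan_motif(masked, motif("ACNT"))$strand == "+"), 2)
})

test_that("context_pfm is normalized and oriented 5'->3' on the erroneous strand", {
  # all sites share context: CGAT with the R at the G
  g <- c(c1 = "TTCGATTTTCGATTTTCGATTT")
  sites <- data.frame(contig = "c1", position = c(3, 10, 17), code = "R",
                      minor_fraction = 0.4, discordant_strand = "+",
                      ref_base = "G", stringsAsFactors = FALSE)
  pfm <- context_pfm(sites, g, k = 2)
  expect_equal(rowSums(pfm), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(pfm["0", "G"], 1)
  expect_equal(pfm["-1", "C"], 1)
  expect_equal(pfm["1", "A"], 1)
  # a minus-strand site reads reverse-complemented
  g2 <- c(c1 = "TTATCGTT")   # minus strand 5'->3' around pos 4: ..CGAT..
  s2 <- data.frame(contig = "c1", position = 4, code = "Y",
                   minor_fraction = 0.4, discordant_strand = "-",
                   ref_base = "C", stringsAsFactors = FALSE)
  pfm2 <- context_pfm(s2, g2, k = 1)
  expect_equal(pfm2["0", "G"], 1)   # complement of the reference C
  # empty input: zero matrix with a warning
  expect_warning(p0 <- context_pfm(sites[0, ], g, k = 2), "no ambiguous")
  expect_true(all(p0 == 0))
})

test_that("context consensus around planted errors reproduces the motif", {
  cfg <- simulation_config(genome_length = 30000, seed = 95,
                           motifs = list(motif_spec(
                             motif("GAAGAC", 4, "6mA", FALSE),
                             planted_count = 60, p_site = 1)),
                           ambiguity_error_rate = 0.5)
  gen <- generate_genome(cfg)
  counts <- simulate_strand_counts(gen$genome, gen$truth, cfg)
  sites <- detect_ambiguous(counts, gen$genome)
  expect_gt(nrow(sites), 30)
  pfm <- context_pfm(sites, gen$genome, k = 4)
  # center is the G preceding the 6mA; the next base is the adenine
  expect_gt(pfm["0", "G"], 0.95)
  expect_gt(pfm["1", "A"], 0.95)
  # upstream context carries the GAAG of the motif
  expect_gt(pfm["-1", "A"], 0.9)
})
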