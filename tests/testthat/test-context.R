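# Gene/window density, PM histograms, and regulatory-region geometry.

make_calls <- function(contig, positions, strand = "+", mod_type = "6mA",
                       pm = 0.9) {
  n <- length(positions)
  data.frame(contig = contig, position = positions,
             strand = rep_len(strand, n), mod_type = rep_len(mod_type, n),
             fraction_modified = rep_len(pm, n),
             percent_modified = rep_len(pm, n),
             is_methylated = rep_len(pm > 0.5, n),
             n_valid_cov = 90, low_coverage = FALSE,
             stringsAsFactors = FALSE)
}

simple_genes <- function(starts, ends, strand = "+", class = "CDS") {
  n <- length(starts)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             contig = rep_len("c1", n),
             start = starts, end = ends, strand = rep_len(strand, n),
             feature_class = rep_len(class, n), cog = rep_len("S", n),
             stringsAsFactors = FALSE)
}

test_that("gene_density counts methylated bases over gene length", {
  genes <- simple_genes(0, 1000)
  calls <- make_calls("c1", c(10, 20, 30, 40, 50, 2000))
  d <- gene_density(calls, genes, "6mA")
  expect_equal(d$n_methylated, 5)
  expect_equal(d$density, 0.005)
  # no methylated bases -> 0
  d0 <- gene_density(make_calls("c1", 10, pm = 0.2), genes, "6mA")
  expect_equal(d0$density, 0)
  # both strands counted once per (position, strand)
  both <- rbind(make_calls("c1", c(10, 10), strand = c("+", "-")))
  expect_equal(gene_density(both, genes, "6mA")$n_methylated, 2)
  expect_error(gene_density(calls, simple_genes(5, 5), "6mA"), "length")
})

test_that("gene_density equals a brute-force membership count on simulations", {
  set.seed(31)
  for (rep in 1:10) {
    n_genes <- sample(3:8, 1)
    starts <- sort(sample(0:9000, n_genes)) ; ends <- starts + sample(200:900, n_genes, replace = TRUE)
    genes <- simple_genes(starts, pmin(ends, 10000))
    pos <- sample(0:9999, 300)
    pm <- runif(300)
    calls <- make_calls("c1", pos, strand = sample(c("+", "-"), 300, TRUE),
                        pm = pm)
    d <- gene_density(calls, genes, "6mA")
    for (i in seq_len(nrow(genes))) {
      manual <- sum(pm > 0.5 & pos >= genes$start[i] & pos < genes$end[i])
      expect_equal(d$n_methylated[i], manual)
    }
  }
})

test_that("flag_top flags exactly ceiling(fraction * N) with deterministic ties", {
  d <- data.frame(gene_id = sprintf("g%03d", 1:100),
                  density = seq(0.001, 0.1, length.out = 100))
  f <- flag_top(d, 0.05)
  expect_equal(sum(f$is_top), 5)
  expect_true(all(f$is_top[96:100]))
  # ceiling rule at N = 10
  expect_equal(sum(flag_top(d[1:10, ], 0.05)$is_top), 1)
  # all ties: lexicographically first gene_ids win
  tied <- data.frame(gene_id = sprintf("g%03d", sample(1:20)), density = 1)
  ft <- flag_top(tied, 0.1)
  expect_setequal(ft$gene_id[ft$is_top], c("g001", "g002"))
})

test_that("window_density averages raw PM per tiling window", {
  calls <- make_calls("c1", c(100, 200), pm = c(0.2, 0.4))
  w <- window_density(calls, c(c1 = 2500), window = 1000)
  expect_equal(nrow(w), 3)          # final partial window included
  expect_equal(w$mean_raw_pm[1], 0.3)
  expect_true(is.na(w$mean_raw_pm[2]))
  expect_equal(w$n_positions, c(2, 0, 0))
  # oracle: brute-force re-mean on a simulated call set
  set.seed(41)
  pos <- sample(0:4999, 800)
  pm <- runif(800)
  calls2 <- make_calls("c1", pos, pm = pm)
  w2 <- window_density(calls2, c(c1 = 5000), window = 1000)
  for (k in 0:4) {
    inwin <- pm[pos >= k * 1000 & pos < (k + 1) * 1000]
    expect_equal(w2$mean_raw_pm[k + 1], mean(inwin))
  }
  # window means lie in the convex hull of member values
  expect_true(all(w2$mean_raw_pm >= 0 & w2$mean_raw_pm <= 1, na.rm = TRUE))
})

test_that("densities are scale-invariant in read depth", {
  cfg <- simulation_config(genome_length = 10000, seed = 17,
                           motifs = list(motif_spec(gatc_motif(),
                                                    planted_count = 30)),
                           p_fail = 0, p_diff = 0, p_read = 1)
  gen <- generate_genome(cfg)
  pu <- simulate_pileup(gen$genome, gen$truth, cfg)
  pu2 <- pu
  for (cc in c("n_valid_cov", "n_mod", "n_canonical", "n_fail", "n_diff"))
    pu2[[cc]] <- 2L * pu2[[cc]]
  genes <- simple_genes(c(0, 5000), c(4000, 9000))
  d1 <- gene_density(call_methylation(pu), genes, "6mA")
  d2 <- gene_density(call_methylation(pu2), genes, "6mA")
  expect_equal(d1$density, d2$density)
})

test_that("pm_histogram bins per feature class over the 0.1-1 range", {
  genes <- rbind(simple_genes(0, 1000, class = "CDS"),
                 simple_genes(2000, 3000, class = "rRNA"))
  genes$gene_id <- c("cds1", "rrna1")
  calls <- rbind(
    make_calls("c1", 0:49 + 100, pm = 0.95),          # CDS, top bin
    make_calls("c1", 0:49 + 2100, pm = 0.3),          # rRNA, low-mid
    make_calls("c1", 0:9 + 200, pm = 0.05))           # below range
  h <- pm_histogram(calls, genes)
  cds <- h[h$feature_class == "CDS", ]
  expect_equal(sum(cds$count), 50)                    # 0.05 values excluded
  expect_equal(cds$proportion[abs(cds$bin_lo - 0.9) < 1e-9], 1)
  rr <- h[h$feature_class == "rRNA", ]
  expect_equal(rr$proportion[abs(rr$bin_lo - 0.3) < 1e-9], 1)
  # planted low-PM signal inside rRNA exceeds CDS mass in the same range
  lowband <- function(cl) sum(h$proportion[h$feature_class == cl &
                                             h$bin_lo >= 0.2 &
                                             h$bin_hi <= 0.4])
  expect_gt(lowband("rRNA"), lowband("CDS"))
})

test_that("define_regions reproduces the worked strand-aware intervals", {
  lens <- c(c1 = 1000)
  plus <- define_regions(simple_genes(100, 400, "+"), lens, flank = 40)
  expect_equal(plus$promoter[, c("start", "end")],
               data.frame(start = 60L, end = 100L))
  expect_equal(plus$start[, c("start", "end")],
               data.frame(start = 100L, end = 140L))
  expect_equal(plus$end[, c("start", "end")],
               data.frame(start = 360L, end = 400L))
  minus <- define_regions(simple_genes(100, 400, "-"), lens, flank = 40)
  expect_equal(minus$promoter[, c("start", "end")],
               data.frame(start = 400L, end = 440L))
  expect_equal(minus$start[, c("start", "end")],
               data.frame(start = 360L, end = 400L))
  expect_equal(minus$end[, c("start", "end")],
               data.frame(start = 100L, end = 140L))
  # clipping at the contig edge
  edge <- define_regions(simple_genes(10, 200, "+"), lens, flank = 40)
  expect_equal(edge$promoter[, c("start", "end")],
               data.frame(start = 0L, end = 10L))
  # short genes: start/end regions truncated to the gene, may overlap
  short <- define_regions(simple_genes(500, 560, "+"), lens, flank = 40)
  expect_equal(short$start$end - short$start$start, 40L)
  expect_equal(short$end[, c("start", "end")],
               data.frame(start = 520L, end = 560L))
  # single + gene on 1 kb contig: union fraction 120/1000
  expect_equal(genome_region_fraction(plus, lens), 0.12)
  # no genes -> 0
  empty <- define_regions(simple_genes(integer(0), integer(0)), lens)
  expect_equal(genome_region_fraction(empty, lens), 0)
})

test_that("synthetic annotation density lands near the expected region fraction", {
  cfg <- simulation_config(genome_length = 200000, seed = 23)
  gen <- generate_genome(cfg)
  genes <- generate_annotation(cfg, gen$genome)
  lens <- stats::setNames(nchar(gen$genome), names(gen$genome))
  regions <- define_regions(genes, lens, flank = 40)
  frac <- genome_region_fraction(regions, lens)
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.12)
  # region intervals never exceed contig bounds
  all_r <- rbind(regions$promoter, regions$start, regions$end)
  expect_true(all(all_r$start >= 0 & all_r$end <= lens))
  # monotone in the gene set
  frac_half <- genome_region_fraction(
    define_regions(genes[seq_len(nrow(genes) %/% 2), ], lens, flank = 40),
    lens)
  expect_lte(frac_half, frac)
})

test_that("motif_region_proportions matches planted placement and the uniform null", {
  lens <- c(c1 = 1000)
  regions <- define_regions(simple_genes(100, 400, "+"), lens, flank = 40)
  inside_prom <- data.frame(motif = "GAT*C", site_index = 1,
                            mod_type = "6mA", contig = "c1",
                            position = c(61, 70, 99),
                            stringsAsFactors = FALSE)
  p <- motif_region_proportions(inside_prom, regions)
  expect_equal(p$frac_promoter, 1)
  expect_equal(p$frac_start, 0)
  expect_equal(p$frac_end, 0)
  # empty annotation -> all zero
  empty <- define_regions(simple_genes(integer(0), integer(0)), lens)
  p0 <- motif_region_proportions(inside_prom, empty)
  expect_equal(unlist(p0[, c("frac_promoter", "frac_start", "frac_end")],
                      use.names = FALSE), c(0, 0, 0))
  # uniform placement converges to each category's genome fraction
  set.seed(53)
  cfg <- simulation_config(genome_length = 100000, seed = 53)
  gen <- generate_genome(cfg)
  genes <- generate_annotation(cfg, gen$genome)
  lens2 <- stats::setNames(nchar(gen$genome), names(gen$genome))
  regions2 <- define_regions(genes, lens2, flank = 40)
  unif <- data.frame(motif = "X", site_index = 1, mod_type = "6mA",
                     contig = "c1",
                     position = sample(0:(lens2[[1]] - 1), 20000,
                                       replace = TRUE),
                     stringsAsFactors = FALSE)
  pu <- motif_region_proportions(unif, regions2)
  cat_frac <- function(cat) {
    d <- regions2[[cat]]
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(d$start + 1L, d$end)))) / lens2[[1]]
  }
  expect_equal(pu$frac_promoter, cat_frac("promoter"), tolerance = 0.05)
  expect_equal(pu$frac_start, cat_frac("start"), tolerance = 0.05)
  expect_equal(pu$frac_end, cat_frac("end"), tolerance = 0.05)
})
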