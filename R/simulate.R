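# Synthetic methylome generator.
#
# Emits the inputs the analysis consumes — genome FASTA, GFF3 annotation,
# bedMethyl pileup, strand-split base counts — with the statistical
# structure the pipeline assumes, plus ground-truth manifests, so every
# downstream stage is testable without sequencing data.

# run `expr` under `seed` without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(nm, " must be a probability in [0, 1]")
  x
}

#' Declare a motif to simulate
#'
#' @param m a \code{\link{motif}}.
#' @param planted_count number of occurrences to plant at non-overlapping
#'   uniform-random positions (0 with \code{background_only = TRUE} means
#'   only accidental background matches of the pattern are methylated).
#' @param p_site per-occurrence methylation probability: every occurrence
#'   of the pattern in the emitted genome (planted or accidental) has each
#'   of its methylatable bases methylated independently with this
#'   probability.
#' @param p_read per-read modified-call probability at a methylated site;
#'   \code{NULL} uses the config-level default.
#' @param background_only plant nothing, only methylate background matches.
#' @return A \code{motif_spec} list.
#' @export
motif_spec <- function(m, planted_count = 0, p_site = 0.98, p_read = NULL,
                       background_only = planted_count == 0) {
  stopifnot(inherits(m, "motif"), planted_count >= 0)
  .check_prob(p_site, "p_site")
  if (!is.null(p_read)) .check_prob(p_read, "p_read")
  structure(list(motif = m, planted_count = as.integer(planted_count),
                 p_site = p_site, p_read = p_read,
                 background_only = isTRUE(background_only)),
            class = "motif_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: constant 100x
#' per-strand read depth, per-read modified-call probability 0.9 with 5%
#' confidence-filter failures and 5% base-mismatch reads (giving typical
#' Percent Modified values in the 0.75-0.85 range at fully methylated
#' sites), no off-motif background signal, and one gene per ~1.1 kb with
#' mean gene length 1 kb.
#'
#' @param genome_length genome size in bases (> 0).
#' @param gc_content GC fraction of the background sequence, in [0, 1].
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param motifs list of \code{\link{motif_spec}} objects.
#' @param coverage reads per strand per position (> 0).
#' @param p_read default per-read modified-call probability at methylated
#'   sites.
#' @param p_fail per-read probability of failing the confidence filter.
#' @param p_diff per-read probability of carrying a non-canonical base.
#' @param background_call_rate per-base probability that an off-motif
#'   position carries a spurious methylation signal.
#' @param ambiguity_error_rate probability that a read on the methylated
#'   strand miscalls the G immediately 5' of a 6mA as A.
#' @param strand_error_floor small uniform miscall rate applied to all
#'   other positions of the strand-count table (default 0 = error-free).
#' @param gene_count number of genes to annotate; \code{NULL} = one per
#'   ~1.1 kb.
#' @param gene_length_mean mean annotated gene length in bases.
#' @param cog_alphabet COG category letters to draw from.
#' @param include_ori annotate one origin-of-replication feature.
#' @param contig_name name of the (single) emitted contig.
#' @return A validated \code{sim_config} list.
#' @export
simulation_config <- function(genome_length = 100000, gc_content = 0.5,
                              seed = 1, motifs = list(), coverage = 100,
                              p_read = 0.9, p_fail = 0.05, p_diff = 0.05,
                              background_call_rate = 0,
                              ambiguity_error_rate = 0,
                              strand_error_floor = 0,
                              gene_count = NULL, gene_length_mean = 1000,
                              cog_alphabet = c("C", "E", "F", "G", "H", "I",
                                               "J", "K", "L", "M", "O", "P",
                                               "Q", "S", "T", "U", "V"),
                              include_ori = TRUE,
                              contig_name = "contig_1") {
  if (genome_length <= 0) stop("genome_length must be > 0")
  if (coverage <= 0) stop("coverage must be > 0")
  .check_prob(gc_content, "gc_content")
  for (nm in c("p_read", "p_fail", "p_diff", "background_call_rate",
               "ambiguity_error_rate", "strand_error_floor"))
    .check_prob(get(nm), nm)
  if (!all(vapply(motifs, inherits, logical(1), "motif_spec")))
    stop("motifs must be a list of motif_spec objects")
  if (is.null(gene_count)) gene_count <- floor(genome_length / 1100)
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    seed = as.integer(seed), motifs = motifs,
    coverage = as.integer(coverage), p_read = p_read, p_fail = p_fail,
    p_diff = p_diff, background_call_rate = background_call_rate,
    ambiguity_error_rate = ambiguity_error_rate,
    strand_error_floor = strand_error_floor,
    gene_count = as.integer(gene_count),
    gene_length_mean = gene_length_mean, cog_alphabet = cog_alphabet,
    include_ori = isTRUE(include_ori), contig_name = contig_name),
    class = "sim_config")
}

# sample one concrete instantiation of an IUPAC pattern
.instantiate_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (length(exp) == 1) exp else sample(exp, 1)
  }, character(1)), collapse = "")
}

#' Generate a genome with planted methylation motifs and its ground truth
#'
#' Background bases are i.i.d. at the configured GC content; planted
#' occurrences are placed uniformly at random without overlap (each a
#' concrete instantiation of the IUPAC pattern, on a random strand). The
#' emitted genome is then scanned for every motif and each occurrence's
#' methylatable bases are drawn methylated independently with the motif's
#' \code{p_site} — accidental background matches are methylated too, as a
#' methyltransferase would; only planted occurrences are recorded in
#' \code{planted}. 6mA sites whose 5'-adjacent base on the methylated
#' strand is G are recorded as strand-discordance truth for the ambiguity
#' module.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{genome} (named character vector) and
#'   \code{truth}: \code{planted} (motif, contig, start, strand),
#'   \code{methylated_sites} (contig, position, strand, mod_type, p_read,
#'   motif), \code{ambiguous_truth} (contig, position, code, strand,
#'   meth_position, meth_strand).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  planted_bases <- sum(vapply(config$motifs, function(ms)
    ms$planted_count * nchar(ms$motif$pattern), numeric(1)))
  if (planted_bases > L / 2)
    stop("infeasible planting density: planted motif bases exceed half the genome")
  .with_seed(config$seed + 101L, {
    gc <- config$gc_content
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    occupied <- rep(FALSE, L)
    planted <- list()
    for (ms in config$motifs) {
      if (ms$planted_count == 0) next
      len <- nchar(ms$motif$pattern)
      placed <- 0L
      tries <- 0L
      max_tries <- ms$planted_count * 200L
      while (placed < ms$planted_count) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("infeasible planting density: could not place ",
               motif_label(ms$motif), " without overlap")
        s <- sample.int(L - len + 1L, 1L) - 1L       # 0-based start
        if (any(occupied[(s + 1L):(s + len)])) next
        strand <- sample(c("+", "-"), 1L)
        inst <- .instantiate_pattern(ms$motif$pattern)
        if (strand == "-") inst <- revcomp(inst)
        seq_chars[(s + 1L):(s + len)] <- strsplit(inst, "", fixed = TRUE)[[1]]
        occupied[(s + 1L):(s + len)] <- TRUE
        placed <- placed + 1L
        planted[[length(planted) + 1L]] <- data.frame(
          motif = motif_label(ms$motif), contig = config$contig_name,
          start = s, strand = strand, stringsAsFactors = FALSE)
      }
    }
    genome <- stats::setNames(paste(seq_chars, collapse = ""),
                              config$contig_name)

    # methylation truth: every occurrence of every motif, p_site per site
    meth <- list()
    for (ms in config$motifs) {
      occ <- scan_motif(genome, ms$motif)
      sites <- occurrence_sites(occ, ms$motif)
      if (nrow(sites) == 0) next
      # one draw per physical methylatable base: palindromes report the
      # same adenine from both strand orientations
      sites <- sites[!duplicated(sites[c("contig", "position",
                                         "site_strand", "mod_type")]), ,
                     drop = FALSE]
      keep <- stats::runif(nrow(sites)) < ms$p_site
      sites <- sites[keep, , drop = FALSE]
      if (nrow(sites) == 0) next
      meth[[length(meth) + 1L]] <- data.frame(
        contig = sites$contig, position = sites$position,
        strand = sites$site_strand, mod_type = sites$mod_type,
        p_read = if (is.null(ms$p_read)) config$p_read else ms$p_read,
        motif = motif_label(ms$motif), stringsAsFactors = FALSE)
    }
    meth <- if (length(meth)) do.call(rbind, meth) else
      data.frame(contig = character(), position = integer(),
                 strand = character(), mod_type = character(),
                 p_read = numeric(), motif = character(),
                 stringsAsFactors = FALSE)
    meth <- meth[!duplicated(meth[c("contig", "position", "strand",
                                    "mod_type")]), , drop = FALSE]
    meth <- meth[order(meth$contig, meth$position, meth$strand), ,
                 drop = FALSE]
    rownames(meth) <- NULL

    truth <- list(planted = if (length(planted)) do.call(rbind, planted)
                  else data.frame(motif = character(), contig = character(),
                                  start = integer(), strand = character(),
                                  stringsAsFactors = FALSE),
                  methylated_sites = meth,
                  ambiguous_truth = .ambiguous_truth(genome, meth))
    list(genome = genome, truth = truth)
  })
}

# strand-discordance truth: methylated 6mA with a G immediately 5' on the
# methylated strand. Plus-strand 6mA at t with G at t-1 -> R at t-1 (+);
# minus-strand 6mA at t with C at t+1 (a G on the minus strand) -> Y at
# t+1 (-).
.ambiguous_truth <- function(genome, meth) {
  out <- list()
  for (ctg in names(genome)) {
    chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
    m <- meth[meth$contig == ctg & meth$mod_type == "6mA", , drop = FALSE]
    plus <- m[m$strand == "+" & m$position >= 1, , drop = FALSE]
    plus <- plus[chars[plus$position] == "G", , drop = FALSE]  # base at pos-1
    minus <- m[m$strand == "-" & m$position <= length(chars) - 2L, ,
               drop = FALSE]
    minus <- minus[chars[minus$position + 2L] == "C", , drop = FALSE]
    if (nrow(plus))
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, position = plus$position - 1L, code = "R",
        strand = "+", meth_position = plus$position, meth_strand = "+",
        stringsAsFactors = FALSE)
    if (nrow(minus))
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, position = minus$position + 1L, code = "Y",
        strand = "-", meth_position = minus$position, meth_strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(), position = integer(),
                      code = character(), strand = character(),
                      meth_position = integer(), meth_strand = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$position), , drop = FALSE]
}

#' Generate a Bakta-style annotation for a simulated genome
#'
#' Non-overlapping genes with random strands, lengths drawn around
#' \code{gene_length_mean} (sd = 10%), COG categories drawn from the
#' configured alphabet; ~2% of features are rRNA and ~3% tRNA; one
#' optional ori feature is placed in a gap when \code{include_ori}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param genome named character vector (from
#'   \code{\link{generate_genome}}).
#' @return data.frame of gene features: \code{gene_id}, \code{contig},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{feature_class}, \code{cog}.
#' @export
generate_annotation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  genome <- .as_genome(genome)
  L <- nchar(genome[[1]])
  ctg <- names(genome)[1]
  n <- config$gene_count
  if (n < 0) stop("gene_count must be >= 0")
  empty <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), feature_class = character(),
                      cog = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  .with_seed(config$seed + 202L, {
    lens <- pmax(100L, as.integer(round(stats::rnorm(
      n, config$gene_length_mean, 0.1 * config$gene_length_mean))))
    slack <- L - sum(lens)
    if (slack < n)   # need at least 1-base gaps
      stop("genes cannot fit in genome: total gene length ", sum(lens),
           " exceeds genome length ", L)
    # near-uniform intergenic spacing: at the default density (~1 gene
    # per 1.1 kb) gaps stay comfortably wider than the 40-base promoter
    # flank, so regulatory regions of neighbouring genes rarely collide
    w <- stats::runif(n + 1L, 0.8, 1.2)
    gaps <- floor(slack * w / sum(w))
    starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n]))
    feature_class <- sample(c("CDS", "rRNA", "tRNA"), n, replace = TRUE,
                            prob = c(0.95, 0.02, 0.03))
    genes <- data.frame(
      gene_id = sprintf("gene_%05d", seq_len(n)), contig = ctg,
      start = as.integer(starts), end = as.integer(starts + lens),
      strand = sample(c("+", "-"), n, replace = TRUE),
      feature_class = feature_class,
      cog = ifelse(feature_class == "CDS",
                   sample(config$cog_alphabet, n, replace = TRUE),
                   NA_character_),
      stringsAsFactors = FALSE)
    if (config$include_ori) {
      gap_starts <- c(0L, genes$end)
      gap_ends <- c(genes$start, L)
      big <- which(gap_ends - gap_starts >= 250L)
      if (length(big)) {
        g <- big[sample.int(length(big), 1L)]
        genes <- rbind(genes, data.frame(
          gene_id = "ori_1", contig = ctg, start = gap_starts[g],
          end = gap_starts[g] + 250L, strand = "+",
          feature_class = "ori", cog = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    if (any(genes$end > L) ||
        any(utils::head(genes$end, -1) > utils::tail(genes$start, -1)))
      stop("genes cannot fit in genome without overlap")
    genes
  })
}

#' Simulate a bedMethyl pileup from a genome and its methylation truth
#'
#' Every methylatable base gets one strand-specific record: A on either
#' strand a 6mA (code \code{a}) record, C on either strand a cytosine
#' record (code \code{m}, or the truth site's own code, \code{21839} for
#' 4mC). Read counts: (n_fail, n_diff, n_valid) are drawn jointly as a
#' multinomial over the per-read outcome probabilities (p_fail, p_diff,
#' remainder), then at methylated sites n_mod ~ Binomial(n_valid,
#' p_read); off-truth positions receive the same methylated treatment
#' with probability \code{background_call_rate} and are canonical
#' otherwise. Counts always sum to total depth.
#'
#' @param genome named character vector.
#' @param truth truth list from \code{\link{generate_genome}}.
#' @param config a \code{\link{simulation_config}}.
#' @return Pileup data.frame in bedMethyl column layout (plus
#'   \code{mod_type}).
#' @export
simulate_pileup <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- .as_genome(genome)
  meth <- truth$methylated_sites
  .with_seed(config$seed + 303L, {
    recs <- lapply(names(genome), function(ctg) {
      chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
      pos0 <- seq_along(chars) - 1L
      # methylatable: A(+), T(+)->A(-), C(+), G(+)->C(-)
      plus_a <- pos0[chars == "A"]; minus_a <- pos0[chars == "T"]
      plus_c <- pos0[chars == "C"]; minus_c <- pos0[chars == "G"]
      df <- data.frame(
        contig = ctg,
        start = c(plus_a, minus_a, plus_c, minus_c),
        strand = rep(c("+", "-", "+", "-"),
                     c(length(plus_a), length(minus_a),
                       length(plus_c), length(minus_c))),
        base_kind = rep(c("A", "A", "C", "C"),
                        c(length(plus_a), length(minus_a),
                          length(plus_c), length(minus_c))),
        stringsAsFactors = FALSE)
      df
    })
    df <- do.call(rbind, recs)
    df$mod_type <- ifelse(df$base_kind == "A", "6mA", "5mC")
    df$p_read <- config$p_read
    df$methylated <- FALSE
    if (nrow(meth)) {
      key <- paste(df$contig, df$start, df$strand, sep = "\r")
      mkey <- paste(meth$contig, meth$position, meth$strand, sep = "\r")
      idx <- match(key, mkey)
      hit <- !is.na(idx)
      df$methylated[hit] <- TRUE
      df$mod_type[hit] <- meth$mod_type[idx[hit]]
      df$p_read[hit] <- meth$p_read[idx[hit]]
    }
    if (config$background_call_rate > 0) {
      bg <- !df$methylated &
        stats::runif(nrow(df)) < config$background_call_rate
      df$methylated[bg] <- TRUE
    }
    n <- nrow(df)
    N <- config$coverage
    n_fail <- stats::rbinom(n, N, config$p_fail)
    p_diff_c <- if (config$p_fail < 1)
      config$p_diff / (1 - config$p_fail) else 0
    n_diff <- stats::rbinom(n, N - n_fail, min(1, p_diff_c))
    n_valid <- N - n_fail - n_diff
    n_mod <- integer(n)
    mi <- which(df$methylated)
    n_mod[mi] <- stats::rbinom(length(mi), n_valid[mi], df$p_read[mi])
    out <- data.frame(
      contig = df$contig, start = df$start, end = df$start + 1L,
      mod_code = unname(.MOD_TYPE_CODE[df$mod_type]), score = n_valid,
      strand = df$strand, thick_start = df$start, thick_end = df$start + 1L,
      color = "255,0,0", n_valid_cov = n_valid, frac_col = 0,
      n_mod = n_mod, n_canonical = n_valid - n_mod, n_other_mod = 0L,
      n_delete = 0L, n_fail = n_fail, n_diff = n_diff, n_nocall = 0L,
      mod_type = df$mod_type, stringsAsFactors = FALSE)
    out$frac_col <- round(100 * fraction_modified(out), 2)
    out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate strand-split base counts with methylation-induced miscalls
#'
#' Counts are reported in reference (plus-strand) orientation per strand
#' of origin, the standard pileup convention. At each planted
#' G-before-6mA context the G's reads on the methylated strand are
#' miscalled A with probability \code{ambiguity_error_rate} (for a
#' minus-strand 6mA this surfaces as a C-vs-T mixture on the minus-strand
#' row, i.e. an IUPAC Y in plus space). All other positions are
#' error-free, or carry the uniform \code{strand_error_floor}.
#'
#' @param genome named character vector.
#' @param truth truth list from \code{\link{generate_genome}}.
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame: \code{contig}, \code{position} (0-based),
#'   \code{strand}, \code{A}, \code{C}, \code{G}, \code{T}.
#' @export
simulate_strand_counts <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- .as_genome(genome)
  amb <- truth$ambiguous_truth
  N <- config$coverage
  .with_seed(config$seed + 404L, {
    res <- lapply(names(genome), function(ctg) {
      chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
      n <- length(chars)
      df <- data.frame(
        contig = ctg, position = rep(seq_len(n) - 1L, 2L),
        strand = rep(c("+", "-"), each = n),
        A = 0L, C = 0L, G = 0L, T = 0L, stringsAsFactors = FALSE)
      ref_idx <- match(rep(chars, 2L), c("A", "C", "G", "T"))
      cnt <- matrix(0L, nrow = 2L * n, ncol = 4L,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
      if (config$strand_error_floor > 0) {
        e <- config$strand_error_floor
        n_err <- stats::rbinom(2L * n, N, e)
        cnt[cbind(seq_len(2L * n), ref_idx)] <- N - n_err
        # errors spread uniformly over the three other bases
        for (r in which(n_err > 0)) {
          alt <- setdiff(1:4, ref_idx[r])
          spread <- stats::rmultinom(1, n_err[r], rep(1 / 3, 3))[, 1]
          cnt[r, alt] <- cnt[r, alt] + spread
        }
      } else {
        cnt[cbind(seq_len(2L * n), ref_idx)] <- N
      }
      a <- amb[amb$contig == ctg, , drop = FALSE]
      if (nrow(a) && config$ambiguity_error_rate > 0) {
        row <- ifelse(a$strand == "+", a$position + 1L, n + a$position + 1L)
        miscalls <- stats::rbinom(nrow(a), N, config$ambiguity_error_rate)
        for (i in seq_len(nrow(a))) {
          r <- row[i]
          cnt[r, ] <- 0L
          if (a$code[i] == "R") {            # ref G, miscalled A
            cnt[r, "G"] <- N - miscalls[i]
            cnt[r, "A"] <- miscalls[i]
          } else {                           # ref C, miscalled T (minus G->A)
            cnt[r, "C"] <- N - miscalls[i]
            cnt[r, "T"] <- miscalls[i]
          }
        }
      }
      df$A <- cnt[, "A"]; df$C <- cnt[, "C"]
      df$G <- cnt[, "G"]; df$T <- cnt[, "T"]
      df
    })
    out <- do.call(rbind, res)
    out[order(out$contig, out$position, out$strand), , drop = FALSE]
  })
}

#' Write a complete simulated bundle to a directory
#'
#' Emits genome.fasta, annotation.gff3, pileup.bedmethyl,
#' strand_counts.tsv, truth_methylated.tsv, truth_planted.tsv and
#' truth_ambiguous.tsv. Deterministic: identical config + seed gives
#' byte-identical files.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  genes <- generate_annotation(config, gen$genome)
  pileup <- simulate_pileup(gen$genome, gen$truth, config)
  counts <- simulate_strand_counts(gen$genome, gen$truth, config)
  paths <- list(
    fasta = file.path(outdir, "genome.fasta"),
    gff3 = file.path(outdir, "annotation.gff3"),
    bedmethyl = file.path(outdir, "pileup.bedmethyl"),
    strand_counts = file.path(outdir, "strand_counts.tsv"),
    truth_methylated = file.path(outdir, "truth_methylated.tsv"),
    truth_planted = file.path(outdir, "truth_planted.tsv"),
    truth_ambiguous = file.path(outdir, "truth_ambiguous.tsv"))
  write_fasta(gen$genome, paths$fasta)
  write_gff3(genes, paths$gff3, contig_lengths = nchar(gen$genome))
  write_bedmethyl(pileup, paths$bedmethyl)
  data.table::fwrite(counts, paths$strand_counts, sep = "\t", quote = FALSE)
  data.table::fwrite(gen$truth$methylated_sites, paths$truth_methylated,
                     sep = "\t", quote = FALSE)
  data.table::fwrite(gen$truth$planted, paths$truth_planted,
                     sep = "\t", quote = FALSE)
  data.table::fwrite(gen$truth$ambiguous_truth, paths$truth_ambiguous,
                     sep = "\t", quote = FALSE)
  invisible(list(genome = gen$genome, truth = gen$truth, genes = genes,
                 pileup = pileup, strand_counts = counts, paths = paths))
}
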