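# End-to-end orchestration: call -> motifs -> genomic context ->
# ambiguity, with all thresholds surfaced in a single config and every
# report number recomputable from the stage TSVs.

#' Build a pipeline run configuration
#'
#' @param fasta,gff3,bedmethyl,strand_counts input paths
#'   (\code{strand_counts} optional: NULL skips the ambiguity stage).
#' @param motifs named list of \code{\link{motif}} objects to evaluate;
#'   NULL triggers de novo discovery per modification type.
#' @param outdir output directory.
#' @param threshold Percent Modified call threshold.
#' @param min_total_reads minimum depth for a methylation call.
#' @param region_flank promoter/start/end region width (bases).
#' @param window_size window size for windowed density (bases).
#' @param top_fraction top fraction of genes to flag.
#' @param min_cov,min_minor_frac ambiguity-detection thresholds.
#' @param seed integer seed recorded in the run log.
#' @return A \code{run_config} list.
#' @export
run_config <- function(fasta, gff3, bedmethyl, strand_counts = NULL,
                       motifs = NULL, outdir = "methylscope_out",
                       threshold = 0.5, min_total_reads = 5,
                       region_flank = 40, window_size = 1000,
                       top_fraction = 0.05, min_cov = 10,
                       min_minor_frac = 0.2, seed = 1) {
  stopifnot(threshold > 0, threshold < 1, top_fraction > 0,
            top_fraction < 1, region_flank > 0, window_size > 0)
  structure(list(fasta = fasta, gff3 = gff3, bedmethyl = bedmethyl,
                 strand_counts = strand_counts, motifs = motifs,
                 outdir = outdir, threshold = threshold,
                 min_total_reads = min_total_reads,
                 region_flank = region_flank, window_size = window_size,
                 top_fraction = top_fraction, min_cov = min_cov,
                 min_minor_frac = min_minor_frac, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Motifs may be given inline as a list of \code{pattern} /
#' \code{offsets} / \code{mod_types} / \code{on_reverse} entries, or via
#' \code{motif_file} pointing to a motif-spec TSV.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  motifs <- NULL
  if (!is.null(y$motif_file)) {
    motifs <- read_motif_specs(y$motif_file)
  } else if (!is.null(y$motifs)) {
    motifs <- lapply(y$motifs, function(m)
      motif(m$pattern, offsets = unlist(m$offsets),
            mod_types = unlist(m$mod_types),
            on_reverse = as.logical(unlist(m$on_reverse))))
    names(motifs) <- vapply(motifs, motif_label, character(1))
  }
  args <- y[setdiff(names(y), c("motifs", "motif_file"))]
  do.call(run_config, c(args, list(motifs = motifs)))
}

.check_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("pipeline input missing: %s file not found at '%s'",
                 what, if (is.null(path)) "<unset>" else path),
         call. = FALSE)
  path
}

#' Run the full methylome analysis pipeline
#'
#' Stages, in order: methylation calling from the bedMethyl pileup;
#' motif scanning/summarizing (or de novo discovery when no motif list
#' is given); gene/window/region methylation density; ambiguity
#' detection from strand counts (when provided). Writes per-stage TSVs,
#' a motif table in asterisk notation, a motif-by-site
#' fraction-methylated matrix, and a run log with thresholds and seed.
#' Deterministic: identical inputs + config give byte-identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list of all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_input(config$fasta, "genome FASTA")
  .check_input(config$gff3, "GFF3 annotation")
  .check_input(config$bedmethyl, "bedMethyl pileup")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$outdir, f)
  log_lines <- c(
    "methylscope run log",
    paste0("package_version: ", as.character(utils::packageVersion("methylscope"))),
    paste0("threshold_percent_modified: ", config$threshold),
    paste0("min_total_reads: ", config$min_total_reads),
    paste0("region_flank: ", config$region_flank),
    paste0("window_size: ", config$window_size),
    paste0("top_fraction: ", config$top_fraction),
    paste0("ambiguity_min_cov: ", config$min_cov),
    paste0("ambiguity_min_minor_frac: ", config$min_minor_frac),
    paste0("seed: ", config$seed))

  stage <- "load inputs"
  res <- tryCatch({
    genome <- read_fasta(config$fasta)
    genes <- read_gff3(config$gff3)
    pileup <- read_bedmethyl(config$bedmethyl)
    contig_lengths <- stats::setNames(nchar(genome), names(genome))

    stage <- "methylation calling"
    calls <- call_methylation(pileup, threshold = config$threshold,
                              min_total_reads = config$min_total_reads)
    write_calls(calls, out_path("calls.tsv"))

    stage <- "motif analysis"
    motifs <- config$motifs
    if (is.null(motifs)) {
      motifs <- list()
      for (mt in c("6mA", "5mC", "4mC")) {
        found <- suppressWarnings(
          find_motifs_denovo(genome, calls, mt,
                             threshold = config$threshold))
        motifs <- c(motifs, found)
      }
      names(motifs) <- vapply(motifs, motif_label, character(1))
    }
    summaries <- do.call(rbind, lapply(motifs, function(m)
      evaluate_motif(genome, calls, m, threshold = config$threshold)))
    if (!is.null(summaries)) rownames(summaries) <- NULL
    motif_table <- if (length(motifs)) do.call(rbind, lapply(motifs,
      function(m) data.frame(
        motif = motif_label(m), pattern = m$pattern,
        palindromic = motif_is_palindromic(m),
        mod_types = paste(m$meth_sites$mod_type, collapse = ","),
        stringsAsFactors = FALSE)))
      else data.frame(motif = character(), pattern = character(),
                      palindromic = logical(), mod_types = character())
    rownames(motif_table) <- NULL
    data.table::fwrite(motif_table, out_path("motif_table.tsv"), sep = "\t")
    if (!is.null(summaries))
      data.table::fwrite(summaries, out_path("motif_summary.tsv"),
                         sep = "\t")
    explained <- do.call(rbind, lapply(c("6mA", "5mC", "4mC"), function(mt)
      data.frame(mod_type = mt,
                 fraction_explained = fraction_explained(
                   calls, genome, motifs, mt,
                   threshold = config$threshold),
                 stringsAsFactors = FALSE)))
    data.table::fwrite(explained, out_path("fraction_explained.tsv"),
                       sep = "\t")

    stage <- "genomic context"
    densities <- do.call(rbind, lapply(
      intersect(c("6mA", "5mC", "4mC"), unique(calls$mod_type)),
      function(mt) flag_top(gene_density(calls, genes, mt,
                                         threshold = config$threshold),
                            fraction = config$top_fraction)))
    data.table::fwrite(densities, out_path("gene_density.tsv"), sep = "\t")
    windows <- window_density(calls, contig_lengths,
                              window = config$window_size)
    data.table::fwrite(windows, out_path("window_density.tsv"), sep = "\t")
    histo <- pm_histogram(calls, genes)
    data.table::fwrite(histo, out_path("pm_histogram.tsv"), sep = "\t")
    regions <- define_regions(genes, contig_lengths,
                              flank = config$region_flank)
    region_frac <- genome_region_fraction(regions, contig_lengths)
    site_calls <- do.call(rbind, lapply(motifs, function(m) {
      s <- occurrence_sites(scan_motif(genome, m), m)
      if (!nrow(s)) return(NULL)
      ckey <- .call_key(calls$contig, calls$position, calls$strand,
                        calls$mod_type)
      pm <- calls$percent_modified[match(
        .call_key(s$contig, s$position, s$site_strand, s$mod_type), ckey)]
      s <- s[!is.na(pm) & pm > config$threshold, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      data.frame(motif = motif_label(m), site_index = s$site_index,
                 mod_type = s$mod_type, contig = s$contig,
                 position = s$position, stringsAsFactors = FALSE)
    }))
    region_props <- if (is.null(site_calls))
      motif_region_proportions(
        data.frame(motif = character(), site_index = integer(),
                   mod_type = character(), contig = character(),
                   position = integer()), regions)
      else motif_region_proportions(site_calls, regions)
    data.table::fwrite(region_props, out_path("region_proportions.tsv"),
                       sep = "\t")
    log_lines <- c(log_lines,
                   sprintf("genome_region_fraction: %.6f", region_frac))

    stage <- "ambiguity detection"
    ambiguity <- NULL
    if (!is.null(config$strand_counts)) {
      .check_input(config$strand_counts, "strand-count table")
      counts <- data.table::fread(config$strand_counts, sep = "\t",
                                  data.table = FALSE)
      sites <- detect_ambiguous(counts, genome, min_cov = config$min_cov,
                                min_minor_frac = config$min_minor_frac)
      sites <- associate_ambiguous(sites, calls,
                                   threshold = config$threshold)
      data.table::fwrite(sites, out_path("ambiguous_sites.tsv"),
                         sep = "\t")
      masked <- mask_genome(genome, sites)
      write_fasta(masked, out_path("masked_genome.fasta"))
      if (nrow(sites)) {
        pfm <- context_pfm(sites, genome, k = 5)
        pfm_df <- data.frame(offset = rownames(pfm), pfm,
                             stringsAsFactors = FALSE)
        data.table::fwrite(pfm_df, out_path("context_pfm.tsv"), sep = "\t")
      }
      ambiguity <- list(sites = sites, masked = masked)
    }
    writeLines(log_lines, out_path("run_log.txt"))
    list(calls = calls, motifs = motifs, summaries = summaries,
         explained = explained, densities = densities, windows = windows,
         histogram = histo, regions = regions,
         region_fraction = region_frac, region_proportions = region_props,
         ambiguity = ambiguity, outdir = config$outdir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Agreement between replicate methylation call sets
#'
#' For every modification type, compares the sets of methylated
#' (contig, position, strand) coordinates between call sets on a shared
#' reference: pairwise intersection/union sizes, Jaccard index and
#' per-set exclusive counts, plus the overall (all-sets) intersection
#' and union.
#'
#' @param call_sets named list of >= 2 methylation-call data.frames on
#'   the same coordinate space.
#' @param threshold Percent Modified call threshold.
#' @return list with \code{pairwise} and \code{overall} data.frames.
#' @export
compare_replicates <- function(call_sets, threshold = 0.5) {
  stopifnot(length(call_sets) >= 2)
  if (is.null(names(call_sets)))
    names(call_sets) <- paste0("set", seq_along(call_sets))
  contigs <- lapply(call_sets, function(d) sort(unique(d$contig)))
  if (length(unique(vapply(contigs, paste, character(1), collapse = ","))) > 1)
    stop("call sets are on different contigs; a shared reference is required")
  mod_types <- sort(unique(unlist(lapply(call_sets, function(d)
    unique(d$mod_type)))))
  meth_keys <- function(d, mt) {
    m <- d[!is.na(d$percent_modified) & d$percent_modified > threshold &
             d$mod_type == mt, , drop = FALSE]
    unique(paste(m$contig, m$position, m$strand, sep = "\r"))
  }
  pairwise <- list(); overall <- list()
  for (mt in mod_types) {
    keys <- lapply(call_sets, meth_keys, mt = mt)
    nm <- names(call_sets)
    for (i in seq_along(keys)) for (j in seq_along(keys)) if (i < j) {
      inter <- length(intersect(keys[[i]], keys[[j]]))
      uni <- length(union(keys[[i]], keys[[j]]))
      pairwise[[length(pairwise) + 1L]] <- data.frame(
        mod_type = mt, set_a = nm[i], set_b = nm[j],
        n_a = length(keys[[i]]), n_b = length(keys[[j]]),
        intersection = inter, union = uni,
        jaccard = if (uni > 0) inter / uni else NA_real_,
        exclusive_a = length(setdiff(keys[[i]], keys[[j]])),
        exclusive_b = length(setdiff(keys[[j]], keys[[i]])),
        stringsAsFactors = FALSE)
    }
    overall[[length(overall) + 1L]] <- data.frame(
      mod_type = mt,
      intersection_all = length(Reduce(intersect, keys)),
      union_all = length(Reduce(union, keys)),
      stringsAsFactors = FALSE)
  }
  list(pairwise = do.call(rbind, pairwise),
       overall = do.call(rbind, overall))
}
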