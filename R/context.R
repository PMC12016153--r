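# Methylation density over genes, windows and regulatory regions.
# Coordinates are 0-based half-open throughout; IRanges (1-based
# inclusive) is used internally for overlap and union arithmetic.

.to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

#' Per-gene methylation density
#'
#' Number of methylated bases (Percent Modified > \code{threshold}, both
#' strands, each (position, strand) counted once) overlapping the gene
#' interval, divided by the gene length.
#'
#' @param calls methylation-call data.frame.
#' @param genes gene-feature data.frame (0-based half-open
#'   \code{start}/\code{end}).
#' @param mod_type modification type to count.
#' @param threshold Percent Modified call threshold.
#' @return data.frame: \code{gene_id}, \code{contig}, \code{cog},
#'   \code{feature_class}, \code{mod_type}, \code{n_methylated},
#'   \code{gene_length}, \code{density}.
#' @export
gene_density <- function(calls, genes, mod_type, threshold = 0.5) {
  if (any(genes$end <= genes$start))
    stop("zero- or negative-length gene in annotation")
  meth <- calls[!is.na(calls$percent_modified) &
                  calls$percent_modified > threshold &
                  calls$mod_type == mod_type, , drop = FALSE]
  meth <- meth[!duplicated(meth[c("contig", "position", "strand")]), ,
               drop = FALSE]
  n_meth <- integer(nrow(genes))
  for (ctg in unique(genes$contig)) {
    gi <- which(genes$contig == ctg)
    m <- meth[meth$contig == ctg, , drop = FALSE]
    if (!nrow(m)) next
    hits <- IRanges::countOverlaps(
      .to_iranges(genes$start[gi], genes$end[gi]),
      IRanges::IRanges(start = m$position + 1L, width = 1L))
    n_meth[gi] <- hits
  }
  data.frame(
    gene_id = genes$gene_id, contig = genes$contig,
    cog = genes$cog, feature_class = genes$feature_class,
    mod_type = mod_type, n_methylated = n_meth,
    gene_length = genes$end - genes$start,
    density = n_meth / (genes$end - genes$start),
    stringsAsFactors = FALSE)
}

#' Flag the top fraction of genes by methylation density
#'
#' Exactly \code{ceiling(fraction * N)} records are flagged, chosen by
#' density descending; ties at the cutoff are broken by \code{gene_id}
#' lexicographic order so the flagging is deterministic.
#'
#' @param records output of \code{\link{gene_density}}.
#' @param fraction top fraction to flag, in (0, 1).
#' @return \code{records} with a logical \code{is_top} column.
#' @export
flag_top <- function(records, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(records)
  if (n == 0) {
    records$is_top <- logical(0)
    return(records)
  }
  k <- ceiling(fraction * n)
  ord <- order(-records$density, records$gene_id)
  records$is_top <- FALSE
  records$is_top[ord[seq_len(k)]] <- TRUE
  records
}

#' Windowed mean of raw Percent Modified values
#'
#' Tiles each contig into windows of \code{window} bases (final partial
#' window included) and averages the raw Percent Modified values of the
#' positions falling in each window (both strands pooled; positions
#' without a defined value do not contribute). Windows with no values
#' are emitted with \code{mean_raw_pm = NA} and \code{n_positions = 0}.
#'
#' @param calls methylation-call data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param mod_type modification type; \code{NULL} pools all types.
#' @param window window size in bases (> 0).
#' @return data.frame: \code{contig}, \code{window_start},
#'   \code{mod_type}, \code{mean_raw_pm}, \code{n_positions}.
#' @export
window_density <- function(calls, contig_lengths, mod_type = NULL,
                           window = 1000) {
  stopifnot(window > 0)
  vals <- calls[!is.na(calls$percent_modified), , drop = FALSE]
  if (!is.null(mod_type))
    vals <- vals[vals$mod_type == mod_type, , drop = FALSE]
  out <- lapply(names(contig_lengths), function(ctg) {
    n_win <- ceiling(contig_lengths[[ctg]] / window)
    v <- vals[vals$contig == ctg, , drop = FALSE]
    win <- floor(v$position / window)
    sums <- tapply(v$percent_modified, factor(win, levels = 0:(n_win - 1)),
                   sum)
    cnts <- tapply(v$percent_modified, factor(win, levels = 0:(n_win - 1)),
                   length)
    cnts[is.na(cnts)] <- 0L
    data.frame(
      contig = ctg,
      window_start = as.integer((0:(n_win - 1)) * window),
      mod_type = if (is.null(mod_type)) "all" else mod_type,
      mean_raw_pm = as.numeric(ifelse(cnts > 0, sums / cnts, NA_real_)),
      n_positions = as.integer(cnts),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent Modified distribution per feature class
#'
#' Histogram of raw Percent Modified values over positions inside
#' features of each class, normalized to proportions per class. Values
#' below the first bin edge (default 0.1) are excluded, matching the
#' displayed range 0.1-1.
#'
#' @param calls methylation-call data.frame.
#' @param genes gene-feature data.frame.
#' @param breaks monotone bin edges covering [0.1, 1].
#' @param mod_type modification type; \code{NULL} pools all types.
#' @return data.frame: \code{feature_class}, \code{bin_lo}, \code{bin_hi},
#'   \code{count}, \code{proportion}.
#' @export
pm_histogram <- function(calls, genes, breaks = seq(0.1, 1, by = 0.1),
                         mod_type = NULL) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  vals <- calls[!is.na(calls$percent_modified) &
                  calls$percent_modified >= breaks[1], , drop = FALSE]
  if (!is.null(mod_type))
    vals <- vals[vals$mod_type == mod_type, , drop = FALSE]
  classes <- unique(genes$feature_class)
  out <- lapply(classes, function(cl) {
    g <- genes[genes$feature_class == cl, , drop = FALSE]
    inside <- logical(nrow(vals))
    for (ctg in unique(g$contig)) {
      sel <- vals$contig == ctg
      if (!any(sel)) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(start = vals$position[sel] + 1L, width = 1L),
        .to_iranges(g$start[g$contig == ctg], g$end[g$contig == ctg]))
      inside[sel] <- inside[sel] | ov > 0
    }
    v <- pmin(vals$percent_modified[inside], breaks[length(breaks)])
    h <- hist(v, breaks = breaks, plot = FALSE, right = FALSE,
              include.lowest = TRUE)
    data.frame(feature_class = cl,
               bin_lo = utils::head(breaks, -1),
               bin_hi = utils::tail(breaks, -1),
               count = h$counts,
               proportion = if (sum(h$counts) > 0)
                 h$counts / sum(h$counts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Define promoter / gene-start / gene-end regions
#'
#' Strand-aware 40-base regions per gene: the promoter is the 40 bases
#' upstream of the gene (capturing the bacterial core promoter with its
#' -10 and -35 elements), the start region the first 40 bases of the
#' gene, the end region its last 40 bases. For minus-strand genes the
#' layout mirrors. Intervals are clipped to contig bounds; genes shorter
#' than \code{2 * flank} have start/end regions truncated to the gene
#' (they may overlap each other). Strandless features (e.g. ori) are
#' treated as plus-strand.
#'
#' @param genes gene-feature data.frame.
#' @param contig_lengths named integer vector.
#' @param flank region width in bases (default 40).
#' @return Object of class \code{region_set}: list of three data.frames
#'   (\code{promoter}, \code{start}, \code{end}), each with
#'   \code{gene_id}, \code{contig}, \code{start}, \code{end} (0-based
#'   half-open; empty intervals dropped).
#' @export
define_regions <- function(genes, contig_lengths, flank = 40) {
  stopifnot(flank > 0)
  strand <- ifelse(is.na(genes$strand), "+", genes$strand)
  plus <- strand == "+"
  glen <- genes$end - genes$start
  f_inner <- pmin(flank, glen)
  prom_s <- ifelse(plus, genes$start - flank, genes$end)
  prom_e <- ifelse(plus, genes$start, genes$end + flank)
  start_s <- ifelse(plus, genes$start, genes$end - f_inner)
  start_e <- ifelse(plus, genes$start + f_inner, genes$end)
  end_s <- ifelse(plus, genes$end - f_inner, genes$start)
  end_e <- ifelse(plus, genes$end, genes$start + f_inner)
  clip <- function(s, e) {
    lim <- contig_lengths[genes$contig]
    s2 <- pmax(0L, pmin(s, lim))
    e2 <- pmax(0L, pmin(e, lim))
    keep <- e2 > s2
    data.frame(gene_id = genes$gene_id[keep], contig = genes$contig[keep],
               start = as.integer(s2[keep]), end = as.integer(e2[keep]),
               stringsAsFactors = FALSE)
  }
  structure(list(promoter = clip(prom_s, prom_e),
                 start = clip(start_s, start_e),
                 end = clip(end_s, end_e),
                 flank = flank),
            class = "region_set")
}

.region_union <- function(regions) {
  all <- rbind(regions$promoter, regions$start, regions$end)
  split(all, all$contig)
}

#' Fraction of the genome inside promoter / start / end regions
#'
#' Width of the union of all three region categories (overlapping
#' intervals counted once) over the total genome length.
#'
#' @param regions a \code{\link{define_regions}} result.
#' @param contig_lengths named integer vector.
#' @return Fraction in [0, 1].
#' @export
genome_region_fraction <- function(regions, contig_lengths) {
  per_ctg <- .region_union(regions)
  covered <- sum(vapply(per_ctg, function(d)
    sum(IRanges::width(IRanges::reduce(.to_iranges(d$start, d$end)))),
    numeric(1)))
  covered / sum(contig_lengths)
}

#' Proportion of a motif's methylated bases inside each region category
#'
#' For each methylated site of each motif: the fraction of its methylated
#' bases whose genomic position falls in promoter / start / end regions.
#' A base inside several categories counts once per category; the three
#' categories are reported separately (they need not sum to 1).
#'
#' @param site_calls data.frame of methylated motif-base positions, with
#'   columns \code{motif}, \code{site_index}, \code{mod_type},
#'   \code{contig}, \code{position} (e.g. built from
#'   \code{\link{occurrence_sites}} joined to calls).
#' @param regions a \code{\link{define_regions}} result.
#' @return data.frame: \code{motif}, \code{site_index}, \code{mod_type},
#'   \code{n_bases}, \code{frac_promoter}, \code{frac_start},
#'   \code{frac_end}.
#' @export
motif_region_proportions <- function(site_calls, regions) {
  in_cat <- function(cat) {
    d <- regions[[cat]]
    res <- logical(nrow(site_calls))
    for (ctg in unique(site_calls$contig)) {
      sel <- site_calls$contig == ctg
      dd <- d[d$contig == ctg, , drop = FALSE]
      if (!nrow(dd)) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(start = site_calls$position[sel] + 1L, width = 1L),
        .to_iranges(dd$start, dd$end))
      res[sel] <- ov > 0
    }
    res
  }
  if (nrow(site_calls) == 0)
    return(data.frame(motif = character(), site_index = integer(),
                      mod_type = character(), n_bases = integer(),
                      frac_promoter = numeric(), frac_start = numeric(),
                      frac_end = numeric(), stringsAsFactors = FALSE))
  site_calls$.prom <- in_cat("promoter")
  site_calls$.start <- in_cat("start")
  site_calls$.end <- in_cat("end")
  grp <- split(site_calls,
               list(site_calls$motif, site_calls$site_index), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(d) data.frame(
    motif = d$motif[1], site_index = d$site_index[1],
    mod_type = d$mod_type[1], n_bases = nrow(d),
    frac_promoter = mean(d$.prom), frac_start = mean(d$.start),
    frac_end = mean(d$.end), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$motif, out$site_index), , drop = FALSE]
}
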