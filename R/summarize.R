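# Motif-level summaries of per-position methylation calls, and de novo
# motif discovery from methylated-base sequence contexts.

.call_key <- function(contig, position, strand, mod_type) {
  paste(contig, position, strand, mod_type, sep = "\r")
}

#' Summarize methylation over a motif's occurrences
#'
#' One summary row per methylated site of the motif (bipartite motifs
#' with 6mA on one strand and 4mC on the other yield two rows). An
#' occurrence's methylatable base counts as methylated when its call's
#' Percent Modified exceeds \code{threshold}; occurrences whose base has
#' no call (or no defined Percent Modified) count as unmethylated and are
#' tallied separately in \code{n_no_data}.
#'
#' @param m the \code{\link{motif}}.
#' @param occurrences output of \code{\link{scan_motif}} for \code{m}.
#' @param calls methylation-call data.frame
#'   (\code{\link{call_methylation}}).
#' @param threshold Percent Modified call threshold (strict \code{>}).
#' @return data.frame, one row per meth site: \code{motif},
#'   \code{site_index}, \code{offset}, \code{mod_type},
#'   \code{n_occurrences}, \code{n_methylated}, \code{n_no_data},
#'   \code{frac_methylated} (denominator: all occurrences),
#'   \code{frac_methylated_with_data} (denominator: occurrences with a
#'   call), \code{mean_percent_modified} (over occurrences with data).
#' @export
summarize_motif <- function(m, occurrences, calls, threshold = 0.5) {
  stopifnot(inherits(m, "motif"))
  sites <- occurrence_sites(occurrences, m)
  site_meta <- m$meth_sites
  ckey <- .call_key(calls$contig, calls$position, calls$strand,
                    calls$mod_type)
  out <- lapply(seq_len(nrow(site_meta)), function(i) {
    s <- sites[sites$site_index == i, , drop = FALSE]
    n_occ <- nrow(s)
    idx <- match(.call_key(s$contig, s$position, s$site_strand,
                           s$mod_type), ckey)
    pm <- calls$percent_modified[idx]
    has_data <- !is.na(idx) & !is.na(pm)
    meth <- has_data & pm > threshold
    data.frame(
      motif = motif_label(m), site_index = i,
      offset = site_meta$offset[i], mod_type = site_meta$mod_type[i],
      n_occurrences = n_occ,
      n_methylated = sum(meth),
      n_no_data = n_occ - sum(has_data),
      frac_methylated = if (n_occ > 0) sum(meth) / n_occ else NA_real_,
      frac_methylated_with_data =
        if (sum(has_data) > 0) sum(meth) / sum(has_data) else NA_real_,
      mean_percent_modified =
        if (sum(has_data) > 0) mean(pm[has_data]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a candidate motif against a genome and call set
#'
#' Scan-and-summarize in one verb, for assessing specific candidate
#' motifs (e.g. weakly methylated ones like TGGCCA or TCGA).
#'
#' @inheritParams summarize_motif
#' @param genome named character vector of contig sequences.
#' @return As \code{\link{summarize_motif}}.
#' @export
evaluate_motif <- function(genome, calls, m, threshold = 0.5) {
  summarize_motif(m, scan_motif(genome, m), calls, threshold = threshold)
}

#' Fraction of methylated bases explained by a set of motifs
#'
#' Of all positions called methylated for \code{mod_type}, the fraction
#' that coincide with some motif's methylatable base (matched on contig,
#' position, strand and modification type).
#'
#' @param calls methylation-call data.frame.
#' @param genome named character vector of contig sequences.
#' @param motifs list of \code{\link{motif}} objects.
#' @param mod_type one of \code{"6mA"}, \code{"5mC"}, \code{"4mC"}.
#' @param threshold Percent Modified call threshold.
#' @return Fraction in [0, 1]; NA when there are no methylated positions.
#' @export
fraction_explained <- function(calls, genome, motifs, mod_type,
                               threshold = 0.5) {
  meth <- calls[!is.na(calls$percent_modified) &
                  calls$percent_modified > threshold &
                  calls$mod_type == mod_type, , drop = FALSE]
  if (nrow(meth) == 0) return(NA_real_)
  if (length(motifs) == 0) return(0)
  in_motif <- character(0)
  for (m in motifs) {
    sites <- occurrence_sites(scan_motif(genome, m), m)
    sites <- sites[sites$mod_type == mod_type, , drop = FALSE]
    if (nrow(sites))
      in_motif <- c(in_motif, .call_key(sites$contig, sites$position,
                                        sites$site_strand, sites$mod_type))
  }
  keys <- .call_key(meth$contig, meth$position, meth$strand, meth$mod_type)
  mean(keys %in% unique(in_motif))
}

# extract centered, canonically oriented contexts around methylated bases:
# the modified base sits at index k+1 and reads A (6mA) or C (mC) on its
# own strand; minus-strand contexts are reverse-complemented.
.meth_contexts <- function(genome, calls, mod_type, k, threshold = 0.5) {
  meth <- calls[!is.na(calls$percent_modified) &
                  calls$percent_modified > threshold &
                  calls$mod_type == mod_type &
                  calls$strand %in% c("+", "-"), , drop = FALSE]
  out <- character(0)
  for (ctg in unique(meth$contig)) {
    seq <- genome[[ctg]]
    n <- nchar(seq)
    m <- meth[meth$contig == ctg, , drop = FALSE]
    m <- m[m$position - k >= 0 & m$position + k <= n - 1L, , drop = FALSE]
    if (!nrow(m)) next
    ctx <- substring(seq, m$position - k + 1L, m$position + k + 1L)
    neg <- m$strand == "-"
    ctx[neg] <- vapply(ctx[neg], revcomp, character(1))
    out <- c(out, unname(ctx))
  }
  out
}

# minimal IUPAC set covering >= cover of the column's base frequencies
.column_consensus <- function(freqs, cover = 0.9) {
  ord <- order(freqs, decreasing = TRUE)
  cum <- cumsum(freqs[ord])
  take <- seq_len(which(cum >= cover)[1])
  sort(names(freqs)[ord[take]])
}

.set_to_iupac <- function(bases) {
  for (code in names(IUPAC_CODES))
    if (setequal(IUPAC_CODES[[code]], bases)) return(code)
  stop("no IUPAC code for base set: ", paste(bases, collapse = ""))
}

# column-wise consensus of a context matrix: minimal IUPAC set per
# column covering `cover` of rows; columns with a set of <= 3 bases are
# "specific", the center is pinned to the modified base
.context_consensus <- function(mat, center_col, center_base, cover) {
  width <- ncol(mat)
  cons <- vector("list", width)
  for (j in seq_len(width)) {
    freqs <- prop.table(table(factor(mat[, j],
                                     levels = c("A", "C", "G", "T"))))
    cons[[j]] <- .column_consensus(
      stats::setNames(as.numeric(freqs), c("A", "C", "G", "T")), cover)
  }
  cons[[center_col]] <- center_base
  specific <- vapply(cons, length, integer(1)) <= 3
  specific[center_col] <- TRUE
  list(cons = cons, specific = specific)
}

# rows of `mat` matching the consensus at its specific columns
.consensus_support <- function(mat, cons, specific) {
  supp <- rep(TRUE, nrow(mat))
  for (j in which(specific))
    supp <- supp & mat[, j] %in% cons[[j]]
  supp
}

# merge motifs that share length and methylated offset and differ in
# exactly one column, widening that column's IUPAC code; repeat to
# fixpoint (rebuilds e.g. CAGDAC from CAGAAC/CAGGAC/CAGTAC)
.merge_variant_motifs <- function(found) {
  repeat {
    merged <- FALSE
    for (i in seq_along(found)) {
      for (j in seq_along(found)) {
        if (j <= i || merged) next
        a <- found[[i]]; b <- found[[j]]
        if (nchar(a$pattern) != nchar(b$pattern)) next
        if (!identical(a$meth_sites, b$meth_sites)) next
        ca <- strsplit(a$pattern, "")[[1]]
        cb <- strsplit(b$pattern, "")[[1]]
        diff <- which(ca != cb)
        if (length(diff) != 1) next
        un <- sort(unique(c(IUPAC_CODES[[ca[diff]]],
                            IUPAC_CODES[[cb[diff]]])))
        ca[diff] <- .set_to_iupac(un)
        found[[i]] <- motif(paste(ca, collapse = ""),
                            offsets = a$meth_sites$offset,
                            mod_types = a$meth_sites$mod_type,
                            on_reverse = a$meth_sites$on_reverse)
        found[[j]] <- NULL
        merged <- TRUE
      }
      if (merged) break
    }
    if (!merged) return(found)
  }
}

#' De novo motif discovery from methylated-base contexts
#'
#' A seeded greedy consensus procedure. Contexts of \code{context_k}
#' bases either side of each methylated base (canonically oriented, the
#' modified base centered) are stacked. Each round seeds on the most
#' frequent 4-mer anchored at the modified base (over the four windows
#' touching the center), then refines: the seeded subset is reduced
#' column-wise to the smallest IUPAC set covering at least \code{cover}
#' of sites per column (sets of more than 3 bases become N), and the
#' support set is re-matched against all remaining contexts until it
#' stabilizes. The motif spans the outermost specific columns; it is
#' emitted when it has at least two fully determined flanking bases,
#' \code{min_sites} supporting contexts, and fold enrichment (support
#' rate over the genome-background probability of the pattern) of at
#' least \code{min_fold}; its supporters are removed and the next round
#' starts. Finally, motifs differing in a single column are merged into
#' IUPAC degenerate codes, so a column where only A, G and T variants
#' have support becomes D, not N.
#'
#' @param genome named character vector of contig sequences.
#' @param calls methylation-call data.frame.
#' @param mod_type modification type to discover motifs for.
#' @param context_k half-width of the extracted context.
#' @param min_sites minimum number of supporting methylated sites.
#' @param min_fold minimum fold enrichment over genome background.
#' @param threshold Percent Modified call threshold.
#' @param cover per-column coverage fraction for the consensus set.
#' @return List of \code{\link{motif}} objects (empty, with a warning,
#'   when fewer than \code{min_sites} methylated positions exist or no
#'   motif passes the filters).
#' @export
find_motifs_denovo <- function(genome, calls, mod_type, context_k = 10,
                               min_sites = 50, min_fold = 4,
                               threshold = 0.5, cover = 0.9) {
  genome <- .as_genome(genome)
  contexts <- .meth_contexts(genome, calls, mod_type, context_k, threshold)
  if (length(contexts) < min_sites) {
    warning(sprintf(
      "too few methylated %s positions (%d < %d); no motifs reported",
      mod_type, length(contexts), min_sites))
    return(list())
  }
  # genome background base frequencies, strand-symmetrized
  all_chars <- strsplit(paste(unlist(genome), collapse = ""), "")[[1]]
  tab <- table(factor(all_chars, levels = c("A", "C", "G", "T")))
  bg <- (tab + rev(tab)) / (2 * sum(tab))
  bg <- stats::setNames(as.numeric(bg), c("A", "C", "G", "T"))

  center_base <- if (mod_type == "6mA") "A" else "C"
  cc <- context_k + 1L
  mat_all <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  remaining <- mat_all
  motifs_found <- list()
  for (round in 1:8) {
    if (nrow(remaining) < min_sites) break
    # seed: most frequent center-anchored 4-mer over the windows
    # [-3..0], [-2..1], [-1..2], [0..3]
    best <- NULL
    for (off in -3:0) {
      cols <- (cc + off):(cc + off + 3L)
      words <- apply(remaining[, cols, drop = FALSE], 1, paste,
                     collapse = "")
      tw <- sort(table(words), decreasing = TRUE)
      if (is.null(best) || tw[1] > best$count)
        best <- list(count = as.integer(tw[1]), cols = cols,
                     rows = words == names(tw)[1])
    }
    subset <- if (best$count >= min_sites) remaining[best$rows, ,
                                                     drop = FALSE]
              else remaining   # fall back to a whole-set consensus
    # refine: consensus over subset, re-match over everything remaining
    for (iter in 1:5) {
      cs <- .context_consensus(subset, cc, center_base, cover)
      supp <- .consensus_support(remaining, cs$cons, cs$specific)
      new_subset <- remaining[supp, , drop = FALSE]
      if (nrow(new_subset) == nrow(subset)) break
      subset <- new_subset
    }
    specific <- cs$specific
    flank_single <- vapply(cs$cons, length, integer(1)) == 1
    flank_single[cc] <- FALSE
    if (sum(flank_single) < 2) break
    lo <- min(which(specific)); hi <- max(which(specific))
    codes <- vapply(cs$cons[lo:hi], .set_to_iupac, character(1))
    codes[!specific[lo:hi]] <- "N"
    pattern <- paste(codes, collapse = "")
    n_supp <- sum(supp)
    p_bg <- prod(vapply(cs$cons[lo:hi][specific[lo:hi]],
                        function(s) sum(bg[s]), numeric(1)))
    fold <- (n_supp / nrow(remaining)) / p_bg
    if (n_supp >= min_sites && fold >= min_fold) {
      motifs_found[[length(motifs_found) + 1L]] <-
        motif(pattern, offsets = cc - lo, mod_types = mod_type,
              on_reverse = FALSE)
      remaining <- remaining[!supp, , drop = FALSE]
    } else break
  }
  motifs_found <- .merge_variant_motifs(motifs_found)
  if (!length(motifs_found))
    warning("no motif passed the support/enrichment filters")
  motifs_found
}
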