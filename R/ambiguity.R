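# Detection of strand-specific, methylation-induced basecalling
# ambiguities from strand-split base counts. The error pattern: the
# strand carrying a 6mA tends to miscall the G immediately 5' of the
# methylated adenine as A, producing an IUPAC R (G/A mixture) on that
# strand; the mirrored minus-strand case surfaces as Y (C/T) in
# plus-strand base space.

.BASES <- c("A", "C", "G", "T")

#' Detect ambiguous (R/Y) positions from strand-split base counts
#'
#' A position is ambiguous when, on at least one strand with depth >=
#' \code{min_cov}, the two most frequent basecalls are {A, G} (code R) or
#' {C, T} (code Y) and the minor base's fraction of that strand's depth
#' is >= \code{min_minor_frac}. Counts are in reference orientation, so
#' codes are already in plus-strand base space; a minus-strand read-space
#' A/G mixture arrives here as C/T and is reported as Y. Other mixtures
#' (e.g. A/C) are returned in the \code{diagnostics} attribute, not as
#' sites.
#'
#' @param counts strand-count data.frame (\code{contig}, \code{position},
#'   \code{strand}, \code{A}, \code{C}, \code{G}, \code{T}), reference
#'   orientation.
#' @param genome named character vector (reference sequences).
#' @param min_cov minimum per-strand depth (>= 1).
#' @param min_minor_frac minimum minor-base fraction, in (0, 0.5].
#' @return data.frame of sites: \code{contig}, \code{position},
#'   \code{code} (R/Y), \code{minor_fraction}, \code{discordant_strand},
#'   \code{ref_base}; attribute \code{"diagnostics"} holds non-R/Y
#'   mixtures.
#' @export
detect_ambiguous <- function(counts, genome, min_cov = 10,
                             min_minor_frac = 0.2) {
  stopifnot(min_cov >= 1, min_minor_frac > 0, min_minor_frac <= 0.5)
  genome <- .as_genome(genome)
  mat <- as.matrix(counts[, .BASES])
  depth <- rowSums(mat)
  ord_top <- max.col(mat, ties.method = "first")
  mat2 <- mat
  mat2[cbind(seq_len(nrow(mat)), ord_top)] <- -1L
  ord_2nd <- max.col(mat2, ties.method = "last")
  minor_n <- mat[cbind(seq_len(nrow(mat)), ord_2nd)]
  minor_frac <- ifelse(depth > 0, minor_n / depth, 0)
  pair <- paste(pmin(ord_top, ord_2nd), pmax(ord_top, ord_2nd))
  code <- ifelse(pair == "1 3", "R", ifelse(pair == "2 4", "Y", NA))
  is_mixed <- depth >= min_cov & minor_frac >= min_minor_frac
  hit <- is_mixed & !is.na(code)
  sites <- data.frame(
    contig = counts$contig[hit], position = counts$position[hit],
    code = code[hit], minor_fraction = minor_frac[hit],
    discordant_strand = counts$strand[hit],
    stringsAsFactors = FALSE)
  sites$ref_base <- substring(genome[sites$contig],
                              sites$position + 1L, sites$position + 1L)
  # collapse duplicate (contig, position, code) from the two strands,
  # keeping the strand with the larger minor fraction
  sites <- sites[order(sites$contig, sites$position,
                       -sites$minor_fraction), , drop = FALSE]
  sites <- sites[!duplicated(sites[c("contig", "position", "code")]), ,
                 drop = FALSE]
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  diag <- data.frame(
    contig = counts$contig[is_mixed & is.na(code)],
    position = counts$position[is_mixed & is.na(code)],
    strand = counts$strand[is_mixed & is.na(code)],
    stringsAsFactors = FALSE)
  attr(sites, "diagnostics") <- diag
  sites
}

#' Associate ambiguous positions with adjacent methylated adenines
#'
#' The geometry of the methylation-induced error: an R at plus position p
#' links to a methylated 6mA on the plus strand at p + 1 (the error
#' immediately precedes the adenine 5' to 3'); a Y at plus position q is
#' the mirrored case and links to a methylated 6mA on the minus strand at
#' plus coordinate q - 1. Exactly one position is searched (immediate
#' adjacency). Sites with no adjacent call get
#' \code{association_kind = "none"}.
#'
#' @param sites output of \code{\link{detect_ambiguous}}.
#' @param calls methylation-call data.frame with 6mA calls.
#' @param threshold Percent Modified call threshold.
#' @return \code{sites} with \code{associated_position} and
#'   \code{association_kind} (\code{R_before_plus_6mA},
#'   \code{Y_opposite_minus_6mA} or \code{none}).
#' @export
associate_ambiguous <- function(sites, calls, threshold = 0.5) {
  meth <- calls[!is.na(calls$percent_modified) &
                  calls$percent_modified > threshold &
                  calls$mod_type == "6mA", , drop = FALSE]
  key <- paste(meth$contig, meth$position, meth$strand, sep = "\r")
  want_pos <- ifelse(sites$code == "R", sites$position + 1L,
                     sites$position - 1L)
  want_strand <- ifelse(sites$code == "R", "+", "-")
  found <- paste(sites$contig, want_pos, want_strand, sep = "\r") %in% key
  sites$associated_position <- ifelse(found, want_pos, NA_integer_)
  sites$association_kind <- ifelse(
    !found, "none",
    ifelse(sites$code == "R", "R_before_plus_6mA", "Y_opposite_minus_6mA"))
  sites
}

#' Count strand-discordant positions
#'
#' The call-free analogue of \code{\link{detect_ambiguous}}: a position
#' is discordant when the fraction of reads on one strand not supporting
#' the other strand's consensus base is >= \code{min_frac} (both strands
#' must reach \code{min_cov}). Robust at high error rates, where the
#' erroneous strand's majority base is a coin flip; zero on error-free
#' data; monotone in \code{min_frac}.
#'
#' @param counts strand-count data.frame (reference orientation).
#' @param genome named character vector.
#' @param min_frac minimum disagreement fraction, in (0, 0.5].
#' @param min_cov minimum per-strand depth.
#' @return list with \code{n} (count) and \code{sites} (data.frame:
#'   \code{contig}, \code{position}, \code{disagreement}).
#' @export
count_discordant <- function(counts, genome, min_frac = 0.2, min_cov = 10) {
  stopifnot(min_frac > 0, min_frac <= 0.5)
  plus <- counts[counts$strand == "+", , drop = FALSE]
  minus <- counts[counts$strand == "-", , drop = FALSE]
  key_p <- paste(plus$contig, plus$position)
  key_m <- paste(minus$contig, minus$position)
  idx <- match(key_p, key_m)
  ok <- !is.na(idx)
  plus <- plus[ok, , drop = FALSE]
  minus <- minus[idx[ok], , drop = FALSE]
  mp <- as.matrix(plus[, .BASES]); mm <- as.matrix(minus[, .BASES])
  dp <- rowSums(mp); dm <- rowSums(mm)
  deep <- dp >= min_cov & dm >= min_cov
  cons_p <- max.col(mp, ties.method = "first")
  cons_m <- max.col(mm, ties.method = "first")
  # counts are both in reference orientation: compare directly
  dis_p <- 1 - mp[cbind(seq_len(nrow(mp)), cons_m)] / pmax(dp, 1)
  dis_m <- 1 - mm[cbind(seq_len(nrow(mm)), cons_p)] / pmax(dm, 1)
  disagreement <- pmax(dis_p, dis_m)
  hit <- deep & disagreement >= min_frac
  sites <- data.frame(contig = plus$contig[hit],
                      position = plus$position[hit],
                      disagreement = disagreement[hit],
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  list(n = nrow(sites), sites = sites)
}

#' Mask ambiguous positions in a genome with their IUPAC codes
#'
#' Replaces the base at each ambiguous position with R or Y; everything
#' else, including sequence length, is unchanged. Masked letters match
#' only pattern N when the genome is subsequently scanned for motifs.
#'
#' @param genome named character vector.
#' @param sites output of \code{\link{detect_ambiguous}}.
#' @return Named character vector over the IUPAC alphabet.
#' @export
mask_genome <- function(genome, sites) {
  genome <- .as_genome(genome)
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
    if (any(s$position < 0 | s$position >= length(chars)))
      stop("ambiguous site outside genome: contig ", ctg)
    ref <- chars[s$position + 1L]
    bad <- (s$code == "R" & !ref %in% c("A", "G")) |
      (s$code == "Y" & !ref %in% c("C", "T"))
    if (any(bad))
      stop(sprintf(
        "mask validation error: code %s at %s:%d is incompatible with reference base %s",
        s$code[which(bad)[1]], ctg, s$position[which(bad)[1]],
        ref[which(bad)[1]]))
    chars[s$position + 1L] <- s$code
    genome[[ctg]] <- paste(chars, collapse = "")
  }
  genome
}

#' Position frequency matrix of the context around ambiguous sites
#'
#' For each site, the reference window of \code{k} bases either side is
#' extracted (reverse-complemented when the discordant strand is minus,
#' so the error context always reads 5' to 3' on the erroneous strand)
#' and per-position base frequencies are tallied. Suitable for DNA-logo
#' rendering: with planted motif-driven errors the consensus around the
#' center reproduces the motif.
#'
#' @param sites output of \code{\link{detect_ambiguous}}.
#' @param genome named character vector.
#' @param k half-width (>= 1).
#' @return Matrix (2k + 1) x 4 (columns A, C, G, T), rows summing to 1;
#'   rownames give offsets -k..k. Zero-row matrix with a warning if no
#'   site has a full window.
#' @export
context_pfm <- function(sites, genome, k = 5) {
  stopifnot(k >= 1)
  genome <- .as_genome(genome)
  width <- 2L * k + 1L
  mat <- matrix(0, nrow = width, ncol = 4,
                dimnames = list(as.character(-k:k), .BASES))
  n_used <- 0L
  for (ctg in unique(sites$contig)) {
    seqc <- genome[[ctg]]
    n <- nchar(seqc)
    s <- sites[sites$contig == ctg, , drop = FALSE]
    s <- s[s$position - k >= 0 & s$position + k <= n - 1L, , drop = FALSE]
    if (!nrow(s)) next
    ctx <- substring(seqc, s$position - k + 1L, s$position + k + 1L)
    neg <- s$discordant_strand == "-"
    ctx[neg] <- vapply(ctx[neg], revcomp, character(1))
    cm <- do.call(rbind, strsplit(ctx, "", fixed = TRUE))
    for (j in seq_len(width)) {
      tb <- table(factor(cm[, j], levels = .BASES))
      mat[j, ] <- mat[j, ] + as.numeric(tb)
    }
    n_used <- n_used + nrow(s)
  }
  if (n_used == 0) {
    warning("no ambiguous site has a complete context window")
    return(mat)
  }
  mat / rowSums(mat)
}
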