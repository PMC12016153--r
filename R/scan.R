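# IUPAC motif scanning.
#
# The scanner is a bit-mask matcher: each genome base maps to one bit
# (A=1, C=2, G=4, T=8; any non-ACGT letter, e.g. an R/Y-masked base, maps
# to a separate bit matched only by pattern N). A pattern character's mask
# is the union of its expansion bits, so a position matches iff
# bitwAnd(mask, base_bit) != 0 at every pattern offset. This gives the
# conservative semantics needed on masked assemblies: masked letters never
# satisfy a specific pattern character, only N.

# 0-based start positions of IUPAC `pattern` in encoded sequence `enc`
.match_starts <- function(enc, pattern) {
  L <- nchar(pattern)
  n <- length(enc)
  if (n < L) return(integer(0))
  masks <- .iupac_mask(strsplit(pattern, "", fixed = TRUE)[[1]])
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    # skip N columns: they match everything
    if (masks[j] == 31L) next
    ok <- ok & bitwAnd(enc[j:(n - L + j)], masks[j]) > 0L
  }
  which(ok) - 1L
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    genome <- out
  }
  if (!is.character(genome)) stop("genome must be a named character vector")
  if (is.null(names(genome))) {
    if (length(genome) != 1)
      stop("multi-contig genome must be named")
    names(genome) <- "contig_1"
  }
  genome
}

#' Scan a genome for all occurrences of a motif on both strands
#'
#' Reports every plus-strand match of the pattern (strand \code{"+"}) and
#' every plus-strand match of its reverse complement (strand \code{"-"});
#' for palindromic motifs the + and - occurrences at the same start are
#' both reported, since they carry distinct methylated-base coordinates.
#' Overlapping occurrences are all reported.
#'
#' @param genome named character vector of contig sequences (uppercase
#'   A/C/G/T; other letters match only pattern N), or a
#'   \code{Biostrings::DNAStringSet}.
#' @param m a \code{\link{motif}}.
#' @return data.frame with columns \code{contig}, \code{start} (0-based
#'   plus-strand coordinate of the leftmost matched base), \code{strand}.
#' @export
scan_motif <- function(genome, m) {
  stopifnot(inherits(m, "motif"))
  genome <- .as_genome(genome)
  rc <- revcomp(m$pattern)
  res <- lapply(names(genome), function(ctg) {
    enc <- .encode_seq(genome[[ctg]])
    fwd <- .match_starts(enc, m$pattern)
    rev <- .match_starts(enc, rc)
    data.frame(
      contig = rep(ctg, length(fwd) + length(rev)),
      start = c(fwd, rev),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

#' Genomic coordinates of a motif's methylatable bases per occurrence
#'
#' Expands each occurrence into one row per methylated site of the motif,
#' giving the plus-strand coordinate and the strand of the methylatable
#' base. For a minus-strand occurrence at start s, pattern offset o maps
#' to plus coordinate s + L - 1 - o and the site strand is flipped.
#'
#' @param occurrences output of \code{\link{scan_motif}}.
#' @param m the \code{\link{motif}} that was scanned.
#' @return data.frame: \code{contig}, \code{start}, \code{strand}
#'   (occurrence), \code{site_index}, \code{offset}, \code{mod_type},
#'   \code{position} (0-based plus coordinate of the methylatable base),
#'   \code{site_strand}.
#' @export
occurrence_sites <- function(occurrences, m) {
  stopifnot(inherits(m, "motif"))
  sites <- m$meth_sites
  if (nrow(sites) == 0 || nrow(occurrences) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), site_index = integer(),
                      offset = integer(), mod_type = character(),
                      position = integer(), site_strand = character(),
                      stringsAsFactors = FALSE))
  }
  L <- nchar(m$pattern)
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    o <- sites$offset[i]
    plus <- occurrences$strand == "+"
    pos <- ifelse(plus, occurrences$start + o,
                  occurrences$start + L - 1L - o)
    pattern_strand_is_plus <- plus
    meth_on_pattern_strand <- !sites$on_reverse[i]
    site_strand <- ifelse(pattern_strand_is_plus == meth_on_pattern_strand,
                          "+", "-")
    data.frame(occurrences,
               site_index = i, offset = o, mod_type = sites$mod_type[i],
               position = as.integer(pos), site_strand = site_strand,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
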