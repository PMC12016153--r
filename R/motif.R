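#' Construct a methylation motif
#'
#' A motif is an IUPAC pattern together with the positions, modification
#' types and strands of its methylated bases. Bipartite Type I motifs
#' carry one methylated base per strand (e.g. GAAANNNNNNGGG with 6mA at
#' offset 3 on the pattern strand and 4mC on the complementary strand at
#' offset 10); palindromic Type II motifs such as GATC are methylated
#' symmetrically on both strands.
#'
#' @param pattern IUPAC pattern string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @param offsets integer vector, 0-based indices into \code{pattern} of
#'   the methylated bases.
#' @param mod_types character vector, one of \code{"6mA"}, \code{"5mC"},
#'   \code{"4mC"} per offset.
#' @param on_reverse logical vector; \code{TRUE} when the methylated base
#'   lies on the strand opposite the pattern's orientation (rendered with
#'   a trailing asterisk, e.g. \code{GAT*C}).
#' @return An object of class \code{"motif"}: a list with elements
#'   \code{pattern} and \code{meth_sites} (data.frame with columns
#'   \code{offset}, \code{mod_type}, \code{on_reverse}).
#' @examples
#' gatc <- motif("GATC", offsets = c(1, 2), mod_types = c("6mA", "6mA"),
#'               on_reverse = c(FALSE, TRUE))
#' motif_label(gatc)  # "GAT*C"
#' @export
motif <- function(pattern, offsets = integer(), mod_types = character(),
                  on_reverse = logical(length(offsets))) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(IUPAC_CODES)))
    stop("pattern contains non-IUPAC characters: ", pattern)
  n <- length(offsets)
  if (length(mod_types) != n || length(on_reverse) != n)
    stop("offsets, mod_types and on_reverse must have equal length")
  if (n > 0) {
    if (any(offsets < 0 | offsets >= nchar(pattern)))
      stop("meth site offset outside pattern")
    if (!all(mod_types %in% c("6mA", "5mC", "4mC")))
      stop("mod_type must be 6mA, 5mC or 4mC")
    for (i in seq_len(n)) {
      ch <- chars[offsets[i] + 1L]
      eff <- if (on_reverse[i]) .IUPAC_COMPLEMENT[ch] else ch
      need <- if (mod_types[i] == "6mA") "A" else "C"
      if (!need %in% IUPAC_CODES[[eff]])
        stop(sprintf(
          "pattern base '%s' at offset %d is not %s-compatible for %s%s",
          ch, offsets[i], need, mod_types[i],
          if (on_reverse[i]) " (on reverse strand)" else ""))
    }
  }
  structure(
    list(pattern = pattern,
         meth_sites = data.frame(offset = as.integer(offsets),
                                 mod_type = as.character(mod_types),
                                 on_reverse = as.logical(on_reverse),
                                 stringsAsFactors = FALSE)),
    class = "motif")
}

#' Render a motif in asterisk notation
#'
#' Bases methylated on the complementary strand get a trailing \code{"*"}
#' (the convention used for restriction-modification motif tables, e.g.
#' \code{GAT*C}, \code{CCW*GG}, \code{GAAANNNNNNG*GG}).
#'
#' @param m a \code{motif}.
#' @return Character string.
#' @export
motif_label <- function(m) {
  stopifnot(inherits(m, "motif"))
  chars <- strsplit(m$pattern, "", fixed = TRUE)[[1]]
  rev_off <- m$meth_sites$offset[m$meth_sites$on_reverse]
  chars[rev_off + 1L] <- paste0(chars[rev_off + 1L], "*")
  paste(chars, collapse = "")
}

#' @export
format.motif <- function(x, ...) {
  sites <- x$meth_sites
  site_str <- if (nrow(sites) == 0) "no methylated sites" else
    paste(sprintf("%s@%d%s", sites$mod_type, sites$offset,
                  ifelse(sites$on_reverse, "(-)", "(+)")), collapse = ", ")
  sprintf("<motif %s | %s>", motif_label(x), site_str)
}

#' @export
print.motif <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Reverse-complement a motif
#'
#' The pattern is reverse-complemented under IUPAC complement rules and
#' each methylated site is remapped to offset \code{L - 1 - offset} with
#' its strand flag toggled. An involution: applying it twice returns the
#' original motif.
#'
#' @param m a \code{motif}.
#' @return The reverse-complement \code{motif}.
#' @export
reverse_complement_motif <- function(m) {
  stopifnot(inherits(m, "motif"))
  L <- nchar(m$pattern)
  motif(revcomp(m$pattern),
        offsets = L - 1L - m$meth_sites$offset,
        mod_types = m$meth_sites$mod_type,
        on_reverse = !m$meth_sites$on_reverse)
}

#' Is a motif palindromic?
#'
#' True when the pattern equals its own reverse complement (e.g. GATC,
#' CCWGG), the hallmark of Type II restriction-modification targets.
#'
#' @param m a \code{motif}.
#' @return Logical.
#' @export
motif_is_palindromic <- function(m) {
  stopifnot(inherits(m, "motif"))
  identical(m$pattern, revcomp(m$pattern))
}

#' Read / write motif specification tables
#'
#' The on-disk motif format is a TSV with columns \code{pattern},
#' \code{offset}, \code{mod_type}, \code{on_reverse}; one row per
#' methylated site, rows sharing a pattern form one motif.
#'
#' @param path file path.
#' @return \code{read_motif_specs}: named list of \code{motif} objects
#'   (names are asterisk-notation labels).
#' @export
read_motif_specs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "offset", "mod_type", "on_reverse")
  if (!all(need %in% names(df)))
    stop("motif spec file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$pattern), function(d)
    motif(d$pattern[1], d$offset, d$mod_type, as.logical(d$on_reverse)))
  out <- out[order(names(out))]
  names(out) <- vapply(out, motif_label, character(1))
  out
}

#' @rdname read_motif_specs
#' @param motifs list of \code{motif} objects.
#' @export
write_motif_specs <- function(motifs, path) {
  rows <- do.call(rbind, lapply(motifs, function(m)
    data.frame(pattern = m$pattern, m$meth_sites, stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
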