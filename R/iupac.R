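#' IUPAC nucleotide code expansions
#'
#' Named list mapping each IUPAC degenerate nucleotide code to the set of
#' concrete bases it stands for (e.g. \code{R} = A or G, \code{Y} = C or T,
#' \code{D} = A, G or T, \code{N} = any base).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# bit encoding: A=1, C=2, G=4, T=8; bit 16 marks a non-ACGT genome letter
# (masked/ambiguous base) which is matched only by pattern N.
.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.iupac_mask <- function(chars) {
  m <- vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (is.null(exp)) stop("unknown IUPAC code: '", ch, "'", call. = FALSE)
    sum(.BASE_BITS[exp])
  }, integer(1))
  # N additionally matches masked (non-ACGT) genome letters
  m[chars == "N"] <- m[chars == "N"] + 16L
  unname(m)
}

# encode a genome string as match bits: ACGT -> its bit, anything else -> 16
.encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  enc <- .BASE_BITS[chars]
  enc[is.na(enc)] <- 16L
  unname(enc)
}

#' Match a single IUPAC pattern character against a concrete base
#'
#' Returns \code{TRUE} iff \code{base} belongs to the expansion of
#' \code{pattern_char} (so \code{iupac_match("D", "C")} is \code{FALSE}:
#' D excludes C). Both arguments are vectorized and recycled.
#'
#' @param pattern_char IUPAC code character(s).
#' @param base concrete base character(s) (A/C/G/T).
#' @return Logical vector.
#' @export
iupac_match <- function(pattern_char, base) {
  pattern_char <- toupper(pattern_char)
  base <- toupper(base)
  if (!all(base %in% names(.BASE_BITS)))
    stop("base must be one of A, C, G, T")
  mask <- .iupac_mask(pattern_char)
  bitwAnd(mask, .BASE_BITS[base]) > 0L
}

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse-complement a (possibly IUPAC-degenerate) sequence string
#'
#' @param seq character string over the IUPAC alphabet.
#' @return Reverse-complemented string (R<->Y, K<->M, B<->V, D<->H;
#'   W/S/N are self-complementary).
#' @export
revcomp <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- .IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) stop("non-IUPAC character in sequence")
  paste(rev(unname(comp)), collapse = "")
}
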