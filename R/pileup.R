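# bedMethyl pileup records and per-position methylation statistics.
#
# The 18-column bedMethyl dialect (tab-separated, 0-based half-open):
#   chrom start end mod_code score strand thickStart thickEnd color
#   n_valid_cov percent_modified(0-100) n_mod n_canonical n_other_mod
#   n_delete n_fail n_diff n_nocall
# mod codes: a = 6mA, m = 5mC, 21839 = 4mC (ChEBI). Other codes are kept
# but flagged. Strand "." is accepted and recorded as NA (excluded from
# strand-specific analyses).

.BEDMETHYL_COLS <- c(
  "contig", "start", "end", "mod_code", "score", "strand",
  "thick_start", "thick_end", "color",
  "n_valid_cov", "frac_col", "n_mod", "n_canonical", "n_other_mod",
  "n_delete", "n_fail", "n_diff", "n_nocall")

.MOD_CODE_TYPE <- c(a = "6mA", m = "5mC", `21839` = "4mC")
.MOD_TYPE_CODE <- c(`6mA` = "a", `5mC` = "m", `4mC` = "21839")

#' Read a bedMethyl file (18-column dialect)
#'
#' @param path path to a tab-separated bedMethyl file.
#' @return data.frame of pileup records with the canonical column names
#'   (\code{contig}, \code{start}, \code{end}, \code{mod_code},
#'   \code{strand}, count columns) plus \code{mod_type} (NA and a warning
#'   for codes outside a/m/21839) and \code{known_code}.
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  first <- readLines(path, n = 1)
  n_fields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (n_fields != 18)
    stop(sprintf("bedMethyl parse error: expected 18 columns, found %d (line 1)",
                 n_fields))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 4, 6, 9)),
                          data.table = FALSE)
  if (ncol(dt) != 18)
    stop(sprintf("bedMethyl parse error: expected 18 columns, found %d",
                 ncol(dt)))
  names(dt) <- .BEDMETHYL_COLS
  count_cols <- c("n_valid_cov", "n_mod", "n_canonical", "n_other_mod",
                  "n_delete", "n_fail", "n_diff", "n_nocall")
  for (cc in count_cols) {
    bad <- which(dt[[cc]] < 0)
    if (length(bad))
      stop(sprintf("bedMethyl validation error: negative %s at line %d",
                   cc, bad[1]))
  }
  bad_end <- which(dt$end != dt$start + 1L)
  if (length(bad_end))
    stop(sprintf("bedMethyl validation error: end != start + 1 at line %d",
                 bad_end[1]))
  dt$strand[!dt$strand %in% c("+", "-")] <- NA_character_
  dt$mod_type <- unname(.MOD_CODE_TYPE[dt$mod_code])
  dt$known_code <- !is.na(dt$mod_type)
  if (any(!dt$known_code))
    warning(sprintf("%d records carry mod codes outside {a, m, 21839}; kept but flagged",
                    sum(!dt$known_code)))
  dt
}

#' Write pileup records as bedMethyl
#'
#' @param records pileup data.frame (as from \code{\link{read_bedmethyl}}
#'   or \code{\link{simulate_pileup}}).
#' @param path output path.
#' @export
write_bedmethyl <- function(records, path) {
  out <- records
  out$end <- out$start + 1L
  out$score <- out$n_valid_cov
  out$thick_start <- out$start
  out$thick_end <- out$end
  out$color <- "255,0,0"
  out$frac_col <- round(100 * fraction_modified(out), 2)
  out$frac_col[!is.finite(out$frac_col)] <- 0
  out$strand[is.na(out$strand)] <- "."
  data.table::fwrite(out[, .BEDMETHYL_COLS], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fraction Modified: n_mod / n_valid_cov
#'
#' The upstream pileup statistic: modified reads over reads confidently
#' classified as modified or canonical. Undefined (NA) when
#' \code{n_valid_cov} is 0.
#'
#' @param records pileup data.frame.
#' @return Numeric vector in [0, 1] (NA where undefined).
#' @export
fraction_modified <- function(records) {
  denom <- records$n_valid_cov
  ifelse(denom > 0, records$n_mod / denom, NA_real_)
}

#' Percent Modified: n_mod / (n_valid_cov + n_fail + n_diff)
#'
#' A stricter per-position agreement statistic: the denominator also
#' counts reads failing the confidence filter and reads whose base
#' differs from the canonical base, so positions with low valid coverage
#' cannot reach high values on a handful of confident reads. Always
#' less than or equal to Fraction Modified. Undefined (NA) when the
#' denominator is 0. Deletion reads are not counted.
#'
#' @param records pileup data.frame.
#' @return Numeric vector in [0, 1] (NA where undefined).
#' @export
percent_modified <- function(records) {
  denom <- records$n_valid_cov + records$n_fail + records$n_diff
  ifelse(denom > 0, records$n_mod / denom, NA_real_)
}

#' Call per-position methylation status
#'
#' A position is methylated when its Percent Modified value is strictly
#' greater than \code{threshold} (default 0.5; 0.3 recovers motifs whose
#' per-read support is weaker). Records with total read depth below
#' \code{min_total_reads} are emitted with \code{is_methylated = NA} and
#' flagged \code{low_coverage}; records with an undefined Percent
#' Modified are likewise not called.
#'
#' @param records pileup data.frame.
#' @param threshold call threshold on Percent Modified, in (0, 1).
#' @param min_total_reads minimum total read depth to attempt a call.
#' @return data.frame of methylation calls: \code{contig},
#'   \code{position} (0-based), \code{strand}, \code{mod_type},
#'   \code{fraction_modified}, \code{percent_modified},
#'   \code{is_methylated}, \code{n_valid_cov}, \code{low_coverage}.
#' @export
call_methylation <- function(records, threshold = 0.5, min_total_reads = 5) {
  stopifnot(threshold > 0, threshold < 1)
  fm <- fraction_modified(records)
  pm <- percent_modified(records)
  total <- records$n_mod + records$n_canonical + records$n_other_mod +
    records$n_delete + records$n_fail + records$n_diff + records$n_nocall
  low <- total < min_total_reads
  is_meth <- ifelse(low | is.na(pm), NA, pm > threshold)
  data.frame(
    contig = records$contig,
    position = records$start,
    strand = records$strand,
    mod_type = if ("mod_type" %in% names(records)) records$mod_type
               else unname(.MOD_CODE_TYPE[records$mod_code]),
    fraction_modified = fm,
    percent_modified = pm,
    is_methylated = is_meth,
    n_valid_cov = records$n_valid_cov,
    low_coverage = low,
    stringsAsFactors = FALSE)
}

#' Read / write methylation-call tables
#'
#' Plain TSV with the columns produced by \code{\link{call_methylation}}.
#'
#' @param calls calls data.frame.
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = c("contig", "strand",
                                                    "mod_type")))
}
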