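# Genome and annotation IO. FASTA goes through Biostrings; GFF3 reading
# goes through rtracklayer's parser, writing is a plain 9-column emitter
# (1-based inclusive coordinates, attributes ID=, product=,
# feature_class=, cog=).

#' Read / write genome FASTA
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of uppercase contig
#'   sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param genome named character vector of contig sequences.
#' @export
write_fasta <- function(genome, path) {
  genome <- .as_genome(genome)
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

.GFF_TYPE <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", ori = "region",
               other = "region")

#' Write gene features as GFF3
#'
#' 0-based half-open internal coordinates are converted to GFF3's
#' 1-based inclusive convention.
#'
#' @param genes gene-feature data.frame (see
#'   \code{\link{generate_annotation}}).
#' @param path output path.
#' @param contig_lengths optional named integer vector for
#'   \code{##sequence-region} headers.
#' @export
write_gff3 <- function(genes, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       names(contig_lengths), contig_lengths), con)
  if (nrow(genes)) {
    attrs <- sprintf("ID=%s;product=%s;feature_class=%s%s",
                     genes$gene_id,
                     ifelse(genes$feature_class == "CDS",
                            "hypothetical protein", genes$feature_class),
                     genes$feature_class,
                     ifelse(is.na(genes$cog), "",
                            paste0(";cog=", genes$cog)))
    lines <- sprintf("%s\tmethylscope\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     genes$contig,
                     unname(.GFF_TYPE[genes$feature_class]),
                     genes$start + 1L, genes$end,
                     genes$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 annotation into a gene-feature table
#'
#' Accepts Bakta-style GFF3. The feature class is taken from a
#' \code{feature_class} attribute when present, otherwise inferred from
#' the GFF type column (CDS/rRNA/tRNA; anything else becomes
#' \code{"other"}). COG categories are read from a \code{cog} (or
#' \code{COG}) attribute; when several letters are annotated the first
#' is kept.
#'
#' @param path GFF3 file.
#' @return data.frame with \code{gene_id}, \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{feature_class},
#'   \code{cog}.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(NA_character_, length(gr))
  }
  fclass <- get_attr("feature_class")
  type <- as.character(mc$type)
  infer <- ifelse(type %in% c("CDS", "rRNA", "tRNA"), type,
                  ifelse(grepl("ori", tolower(type)), "ori", "other"))
  fclass[is.na(fclass)] <- infer[is.na(fclass)]
  cog <- get_attr("cog")
  cog2 <- get_attr("COG")
  cog[is.na(cog)] <- cog2[is.na(cog)]
  cog <- ifelse(is.na(cog) | cog == "", NA_character_,
                substr(cog, 1, 1))
  id <- get_attr("ID")
  id[is.na(id)] <- sprintf("feature_%05d", which(is.na(id)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- NA_character_
  out <- data.frame(
    gene_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    feature_class = fclass,
    cog = cog,
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("invalid feature interval in ", path)
  rownames(out) <- NULL
  out
}
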