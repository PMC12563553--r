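#' Read gene models (TSS table)
#'
#' Reads gene records from either a GFF3 file (records with
#' \code{type == "gene"}) or a 6-column tab-delimited table with header
#' \code{gene_id chrom strand tss gene_length ortholog_id} (TSS 0-based;
#' \code{ortholog_id} "." when absent).  Returns a width-1
#' \link[GenomicRanges]{GRanges} positioned at each gene's TSS with
#' metadata columns \code{gene_id}, \code{gene_length} and
#' \code{ortholog_id}.
#'
#' GFF3 1-based coordinates are converted to the TSS convention
#' \code{tss = start - 1} (0-based) on the plus strand and
#' \code{tss = end - 1} on the minus strand; the returned GRanges stores
#' the TSS 1-based as all intervals in this package.
#'
#' @param path path to a GFF3 (\code{.gff}, \code{.gff3}) or TSV file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or
#'   \code{"tsv"}.
#' @return A width-1 \code{GRanges} of TSS positions.
#' @section Errors:
#' Duplicated \code{gene_id}s and strands other than \code{+}/\code{-}
#' are rejected.
#' @seealso \code{\link{writeGeneModels}}, \code{\link{nearestTSS}}
#' @export
readGeneModels <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
      else "tsv"
  if (format == "gff3") {
    gff <- rtracklayer::import(path, format = "gff3")
    gff <- gff[!is.na(gff$type) & as.character(gff$type) == "gene"]
    geneId <- if (!is.null(gff$ID)) as.character(gff$ID)
      else as.character(gff$gene_id)
    strand <- as.character(GenomicRanges::strand(gff))
    if (any(!strand %in% c("+", "-")))
      .stopf("gene '%s' has unknown strand '%s'",
        geneId[!strand %in% c("+", "-")][1L],
        strand[!strand %in% c("+", "-")][1L])
    tss1 <- ifelse(strand == "+", GenomicRanges::start(gff),
      GenomicRanges::end(gff))
    ortho <- if (!is.null(gff$ortholog_id)) as.character(gff$ortholog_id)
      else NA_character_
    gm <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(gff)),
      IRanges::IRanges(tss1, width = 1L), strand = strand,
      gene_id = geneId,
      gene_length = GenomicRanges::width(gff),
      ortholog_id = ortho)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
      colClasses = c("character", "character", "character", "integer",
        "integer", "character"))
    need <- c("gene_id", "chrom", "strand", "tss", "gene_length",
      "ortholog_id")
    if (!identical(colnames(tab), need))
      .stopf("gene table '%s' must have columns: %s", path,
        paste(need, collapse = ", "))
    if (any(!tab$strand %in% c("+", "-")))
      .stopf("gene '%s' has unknown strand '%s'",
        tab$gene_id[!tab$strand %in% c("+", "-")][1L],
        tab$strand[!tab$strand %in% c("+", "-")][1L])
    ortho <- tab$ortholog_id
    ortho[ortho == "."] <- NA_character_
    gm <- GenomicRanges::GRanges(tab$chrom,
      IRanges::IRanges(tab$tss + 1L, width = 1L), strand = tab$strand,
      gene_id = tab$gene_id, gene_length = tab$gene_length,
      ortholog_id = ortho)
  }
  if (anyDuplicated(gm$gene_id))
    .stopf("duplicate gene_id '%s' in '%s'",
      gm$gene_id[duplicated(gm$gene_id)][1L], path)
  if (any(gm$gene_length <= 0))
    .stopf("gene '%s' has non-positive gene_length",
      gm$gene_id[gm$gene_length <= 0][1L])
  gm
}

#' Write gene models as a 6-column TSV
#'
#' Inverse of \code{\link{readGeneModels}} for the TSV representation
#' (TSS written 0-based, absent orthologs as "."); round trips are
#' byte-identical.
#'
#' @param genes a gene-model \code{GRanges} as returned by
#'   \code{\link{readGeneModels}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  ortho <- genes$ortholog_id
  ortho[is.na(ortho)] <- "."
  lines <- c(
    "gene_id\tchrom\tstrand\ttss\tgene_length\tortholog_id",
    paste(genes$gene_id, as.character(GenomicRanges::seqnames(genes)),
      as.character(GenomicRanges::strand(genes)),
      GenomicRanges::start(genes) - 1L, genes$gene_length, ortho,
      sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
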