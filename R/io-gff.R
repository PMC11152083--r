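#' Read gene models from a GFF3 file
#'
#' Extracts features of type \code{"gene"} and derives each gene's
#' strand-aware 5' end (the start-codon proxy used by the proximity rule).
#' On-disk GFF3 coordinates are 1-based inclusive; in-memory coordinates are
#' 0-based half-open, as everywhere in this package.
#'
#' @param path Path to a GFF3 file.
#' @return A \code{data.frame} with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}
#'   (\code{"+"}/\code{"-"}) and \code{start_codon_pos} (0-based position of
#'   the 5' end: \code{start} on \code{+}, \code{end - 1} on \code{-}).
#' @details Transcript/CDS children are ignored: the gene interval and its 5'
#'   end stand in for the annotated start codon. A gene without a strand is an
#'   error, since the proximity rule is strand-aware.
#' @export
read_gff_genes <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), start_codon_pos = numeric()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    bad <- which(strand == "*")[1L]
    stop("gene without strand in '", path, "' (e.g. ",
         as.character(GenomicRanges::seqnames(gr))[bad],
         ":", BiocGenerics::start(gr)[bad], "); strand is required",
         call. = FALSE)
  }
  id <- gr$ID
  if (is.null(id)) id <- gr$gene_id
  if (is.null(id)) id <- gr$Name
  if (is.null(id) || anyNA(id)) {
    fallback <- paste0("gene_", seq_along(gr))
    id <- if (is.null(id)) fallback else ifelse(is.na(id), fallback, id)
  }
  start0 <- BiocGenerics::start(gr) - 1L   # to 0-based half-open
  end0 <- BiocGenerics::end(gr)
  data.frame(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(start0),
    end = as.numeric(end0),
    strand = strand,
    start_codon_pos = as.numeric(ifelse(strand == "+", start0, end0 - 1)),
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#'
#' Inverse of \code{\link{read_gff_genes}} for fixture generation: writes one
#' \code{gene} feature per row, converting back to 1-based inclusive
#' coordinates.
#'
#' @param genes A gene \code{data.frame} as returned by
#'   \code{\link{read_gff_genes}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    lines <- c(lines, sprintf(
      "%s\tdeltasnp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, as.integer(genes$start) + 1L, as.integer(genes$end),
      genes$strand, genes$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
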