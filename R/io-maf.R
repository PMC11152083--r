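#' Read multiple-alignment blocks (MAF)
#'
#' Parses a MAF file into a list of alignment blocks. Each block holds one
#' row per sequence; the \code{src} field is split at the first \code{"."}
#' into species and chromosome (a dot-free \code{src} is used for both).
#' Minus-strand rows additionally carry forward-strand coordinates
#' (\code{fstart}) computed from \code{src_size}, so downstream windowing
#' never needs strand arithmetic.
#'
#' @param path Path to a MAF file.
#' @return A list of blocks; each block is a \code{data.frame} with columns
#'   \code{species}, \code{chrom}, \code{start} (strand coordinates as in the
#'   file), \code{size}, \code{strand}, \code{src_size}, \code{fstart}
#'   (0-based forward-strand start of the aligned segment) and \code{text}
#'   (gapped alignment row).
#' @details Rows whose ungapped text length disagrees with the stated size,
#'   or whose gapped length differs from the rest of the block, are errors.
#'   Non-\code{a}/\code{s} line types (\code{i}, \code{e}, \code{q}, comments)
#'   are skipped.
#' @export
read_maf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur) == 0L) return(NULL)
    blk <- do.call(rbind, cur)
    widths <- nchar(blk$text)
    if (length(unique(widths)) != 1L) {
      stop("MAF block rows have unequal aligned widths near '",
           blk$species[1L], "'", call. = FALSE)
    }
    ungapped <- nchar(gsub("-", "", blk$text, fixed = TRUE))
    if (any(ungapped != blk$size)) {
      stop("MAF row size mismatch for '", blk$species[which(ungapped != blk$size)[1L]],
           "': stated size differs from ungapped text length", call. = FALSE)
    }
    blk
  }
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    type <- substr(ln, 1L, 1L)
    if (type == "a") {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (type == "s") {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 7L) stop("malformed MAF s-line: ", ln, call. = FALSE)
      src <- f[2L]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0L) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0L) substr(src, dot + 1L, nchar(src)) else src
      start <- as.numeric(f[3L]); size <- as.numeric(f[4L])
      strand <- f[5L]; src_size <- as.numeric(f[6L])
      fstart <- if (strand == "+") start else src_size - (start + size)
      cur[[length(cur) + 1L]] <- data.frame(
        species = species, chrom = chrom, start = start, size = size,
        strand = strand, src_size = src_size, fstart = fstart,
        text = f[7L], stringsAsFactors = FALSE)
    }
    # i/e/q and other auxiliary lines carry no alignment text; skipped
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write multiple-alignment blocks as MAF
#'
#' @param blocks A list of block \code{data.frame}s as returned by
#'   \code{\link{read_maf}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (blk in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s.%s %s %s %s %s %s",
                       blk$species, blk$chrom, fmt(blk$start), fmt(blk$size),
                       blk$strand, fmt(blk$src_size), blk$text), con)
    writeLines("", con)
  }
  invisible(path)
}
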