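#' Read pairwise alignment records (PAF)
#'
#' Parses the 12 mandatory tab-separated PAF columns (minimap2 dialect);
#' optional SAM-style tags beyond column 12 are ignored. Coordinates are
#' 0-based half-open as in the format itself.
#'
#' @param path Path to a PAF file.
#' @return A \code{data.frame} with columns \code{qname}, \code{qlen},
#'   \code{qstart}, \code{qend}, \code{strand}, \code{tname}, \code{tlen},
#'   \code{tstart}, \code{tend}, \code{n_match}, \code{block_len},
#'   \code{mapq}, in file order.
#' @details Lines with fewer than 12 columns, invalid strand symbols, empty
#'   intervals (\code{qend <= qstart} or \code{tend <= tstart}) or
#'   \code{n_match > block_len} raise an error naming the offending line.
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(
    qname = character(), qlen = numeric(), qstart = numeric(),
    qend = numeric(), strand = character(), tname = character(),
    tlen = numeric(), tstart = numeric(), tend = numeric(),
    n_match = numeric(), block_len = numeric(), mapq = numeric())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("PAF line ", which(nf < 12L)[1L], " of '", path,
         "' has fewer than 12 columns", call. = FALSE)
  }
  m <- vapply(fields, function(f) f[1:12], character(12L))
  num <- function(i) suppressWarnings(as.numeric(m[i, ]))
  paf <- data.frame(
    qname = m[1L, ], qlen = num(2L), qstart = num(3L), qend = num(4L),
    strand = m[5L, ], tname = m[6L, ], tlen = num(7L), tstart = num(8L),
    tend = num(9L), n_match = num(10L), block_len = num(11L),
    mapq = num(12L), stringsAsFactors = FALSE)
  bad_line <- function(cond) {
    i <- which(cond)
    if (length(i)) stop("invalid PAF record at line ", i[1L], " of '", path,
                        "'", call. = FALSE)
  }
  bad_line(!(paf$strand %in% c("+", "-")))
  bad_line(is.na(paf$qlen) | is.na(paf$qstart) | is.na(paf$qend) |
           is.na(paf$tlen) | is.na(paf$tstart) | is.na(paf$tend) |
           is.na(paf$n_match) | is.na(paf$block_len) | is.na(paf$mapq))
  bad_line(paf$qstart < 0 | paf$qend <= paf$qstart | paf$qend > paf$qlen)
  bad_line(paf$tstart < 0 | paf$tend <= paf$tstart | paf$tend > paf$tlen)
  bad_line(paf$n_match > paf$block_len)
  paf
}

#' Write pairwise alignment records as PAF
#'
#' @param paf A PAF \code{data.frame} as returned by \code{\link{read_paf}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_paf <- function(paf, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- if (nrow(paf)) sprintf(
    "%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
    paf$qname, fmt(paf$qlen), fmt(paf$qstart), fmt(paf$qend), paf$strand,
    paf$tname, fmt(paf$tlen), fmt(paf$tstart), fmt(paf$tend),
    fmt(paf$n_match), fmt(paf$block_len), fmt(paf$mapq)) else character()
  writeLines(lines, path)
  invisible(path)
}
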