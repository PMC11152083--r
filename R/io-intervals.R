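#' Write genomic intervals as BED or TSV
#'
#' BED output is the three mandatory 0-based half-open columns (plus a name
#' column when \code{intervals} has a \code{name} column); TSV output carries
#' every column of \code{intervals} with a header line.
#'
#' @param intervals A \code{data.frame} with at least \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param path Output path.
#' @param format \code{"BED"} or \code{"TSV"}.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("BED", "TSV")) {
  format <- match.arg(format)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start < 0 | intervals$end <= intervals$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (format == "BED") {
    fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
    cols <- sprintf("%s\t%s\t%s", intervals$chrom,
                    fmt(intervals$start), fmt(intervals$end))
    if ("name" %in% names(intervals)) {
      cols <- paste(cols, intervals$name, sep = "\t")
    }
    writeLines(cols, path)
  } else {
    utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read genomic intervals from BED or TSV
#'
#' @param path Input path.
#' @param format \code{"BED"} (headerless, 0-based half-open) or \code{"TSV"}
#'   (header required, must contain \code{chrom}/\code{start}/\code{end}).
#' @return A \code{data.frame} of intervals.
#' @export
read_intervals <- function(path, format = c("BED", "TSV")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "BED") {
    if (length(readLines(path, n = 1L)) == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    names(x)[1:3] <- c("chrom", "start", "end")
    if (ncol(x) >= 4L) names(x)[4L] <- "name"
  } else {
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  }
  x
}

#' Read a chromosome-class map
#'
#' Two-column TSV (header optional: \code{chrom}, \code{class}) assigning
#' each scaffold to \code{autosome}, \code{Z}, \code{W} or \code{exclude}.
#' The divergence scan analyzes autosomes and Z separately and drops
#' W/excluded scaffolds.
#'
#' @param path Input path.
#' @return Named character vector: scaffold id -> class.
#' @export
read_class_map <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (identical(tolower(as.character(x[1L, 1L])), "chrom")) x <- x[-1L, ]
  cls <- as.character(x[[2L]])
  ok <- c("autosome", "Z", "W", "exclude")
  if (!all(cls %in% ok)) {
    stop("unknown chromosome class(es): ",
         paste(setdiff(unique(cls), ok), collapse = ", "),
         " (expected ", paste(ok, collapse = "/"), ")")
  }
  stats::setNames(cls, as.character(x[[1L]]))
}

#' Write a chromosome-class map
#'
#' @param class_map Named character vector (scaffold id -> class).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_class_map <- function(class_map, path) {
  writeLines(sprintf("%s\t%s", names(class_map), class_map), path)
  invisible(path)
}

# Intervals data.frame -> GRanges (0-based half-open -> 1-based inclusive).
as_granges0 <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1,
                              end = intervals$end))
}
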