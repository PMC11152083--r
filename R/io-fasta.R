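#' Read a FASTA assembly
#'
#' Parses a (possibly multi-record) nucleotide FASTA file into an assembly
#' object. Case is preserved so that soft-masked (lowercase) regions remain
#' distinguishable; record order follows the file.
#'
#' @param path Path to a FASTA file.
#' @param name Label for the assembly; defaults to the file name.
#' @return An object of class \code{"assembly"}: a list with elements
#'   \code{seqs} (a named \code{\link[Biostrings]{DNAStringSet}}, IUPAC
#'   alphabet) and \code{name}. Scaffold ids are the first whitespace-delimited
#'   token of each header and must be unique.
#' @details An empty file yields an empty assembly with a warning. Duplicate
#'   scaffold ids and symbols outside the IUPAC nucleotide alphabet are
#'   errors.
#' @export
read_fasta <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  # BStringSet keeps case (soft-masking) intact; DNAStringSet would not
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
  }
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  valid <- sum(Biostrings::letterFrequency(
    seqs, letters = c(iupac, tolower(iupac))))
  if (valid < sum(Biostrings::width(seqs))) {
    lines <- readLines(path)
    bad <- which(!startsWith(lines, ">") &
                 grepl(sprintf("[^%s]", paste0(
                   c(iupac, tolower(iupac)), collapse = "")), lines))[1L]
    stop("non-nucleotide symbol in '", path, "' at line ", bad, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(ids) == 0L)) stop("empty scaffold id in '", path, "'")
  names(seqs) <- ids
  structure(list(seqs = seqs, name = name), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly '", x$name, "': ", length(x$seqs), " scaffold(s), ",
      format(sum(Biostrings::width(x$seqs)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Scaffold lengths of an assembly
#'
#' @param assembly An \code{"assembly"} object from \code{\link{read_fasta}}.
#' @return Named integer vector of scaffold lengths, in record order.
#' @export
scaffold_lengths <- function(assembly) {
  stats::setNames(Biostrings::width(assembly$seqs), names(assembly$seqs))
}

#' Assembly summary statistics
#'
#' Computes standard assembly metrics (total length, scaffold counts, largest
#' scaffold, N50, GC and N percentages) over scaffolds longer than
#' \code{min_len}, in the style of conventional assembly QC reports.
#'
#' N50 is the largest length L such that scaffolds of length >= L jointly
#' cover at least half of the (filtered) total assembly length. GC% is
#' computed over unambiguous bases only (A/C/G/T, case-insensitive, so
#' soft-masked bases count); N% is the fraction of N among all filtered bases.
#'
#' @param assembly An \code{"assembly"}, or a numeric vector of scaffold
#'   lengths (in which case the base-composition fields are \code{NA}).
#' @param min_len Scaffolds of length \code{> min_len} are retained
#'   (default 500 bp).
#' @return A one-row \code{data.frame} with columns \code{total_len},
#'   \code{n_scaffolds}, \code{n_ge_5kb}, \code{n_ge_50kb}, \code{largest},
#'   \code{n50}, \code{gc_pct}, \code{n_pct}, \code{min_len_filter}.
#' @examples
#' assembly_stats(c(10, 9, 8, 7, 6), min_len = 0)  # n50 = 8
#' @export
assembly_stats <- function(assembly, min_len = 500) {
  stopifnot(is.numeric(min_len), length(min_len) == 1L, min_len >= 0)
  if (inherits(assembly, "assembly")) {
    lens <- as.numeric(Biostrings::width(assembly$seqs))
    keep <- lens > min_len
    if (!any(keep)) stop("no scaffold longer than min_len = ", min_len)
    seqs <- assembly$seqs[keep]
    freq <- colSums(Biostrings::letterFrequency(
      seqs, letters = c("Aa", "Cc", "Gg", "Tt", "Nn"),
      OR = "|"))  # soft-masked lowercase folded into each base
    acgt <- sum(freq[c("A|a", "C|c", "G|g", "T|t")])
    gc_pct <- 100 * sum(freq[c("G|g", "C|c")]) / acgt
    n_pct <- 100 * freq[["N|n"]] / sum(lens[keep])
  } else {
    lens <- as.numeric(assembly)
    keep <- lens > min_len
    if (!any(keep)) stop("no scaffold longer than min_len = ", min_len)
    gc_pct <- NA_real_
    n_pct <- NA_real_
  }
  lens <- sort(lens[keep], decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1L]]
  data.frame(
    total_len = total,
    n_scaffolds = length(lens),
    n_ge_5kb = sum(lens >= 5000),
    n_ge_50kb = sum(lens >= 50000),
    largest = lens[1L],
    n50 = n50,
    gc_pct = gc_pct,
    n_pct = n_pct,
    min_len_filter = min_len
  )
}
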