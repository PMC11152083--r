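#' Inversion-detection parameters
#'
#' @param min_len Minimum reference span of a reported inversion (default
#'   50000 bp; calls must exceed this).
#' @param screen_len Screening-window length within which the locally
#'   dominant ("direct") alignment orientation is assessed (default 20 Mb).
#' @param min_block Minimum reference span of an alignment block entering
#'   the analysis (default 5000 bp; suppresses small repeat-driven blocks).
#' @param merge_gap Maximum reference gap between consecutive
#'   opposite-strand blocks merged into one call (default 100000 bp).
#' @param min_mapq Minimum mapping quality (default 30).
#' @return A list of class \code{"inversion_params"}.
#' @export
inversion_params <- function(min_len = 50000, screen_len = 20000000,
                             min_block = 5000, merge_gap = 100000,
                             min_mapq = 30) {
  stopifnot(min_block <= min_len, min_len > 0, screen_len > 0,
            min_block > 0, merge_gap > 0, min_mapq >= 0)
  structure(list(min_len = min_len, screen_len = screen_len,
                 min_block = min_block, merge_gap = merge_gap,
                 min_mapq = min_mapq), class = "inversion_params")
}

#' Detect chromosomal inversions from pairwise alignment records
#'
#' Formalizes dot-plot screening as strand-run analysis. Within each
#' (reference scaffold, query scaffold) pairing, alignment blocks passing the
#' size and mapping-quality filters are binned into screening windows of
#' \code{screen_len} bp on the reference; the majority strand of each
#' screening window (by aligned reference bp) defines the locally "direct"
#' orientation, so a wholesale reversed scaffold is not an inversion. Maximal
#' runs of consecutive opposite-strand blocks separated by reference gaps of
#' at most \code{merge_gap} are merged; merged runs spanning more than
#' \code{min_len} bp on the reference become calls.
#'
#' @param paf PAF \code{data.frame} (query genome mapped onto the reference,
#'   i.e. reference coordinates in the target columns).
#' @param params An \code{\link{inversion_params}} list.
#' @return A \code{data.frame} of calls sorted by reference coordinate:
#'   \code{chrom}, \code{start}, \code{end} (reference, 0-based half-open),
#'   \code{query_chrom}, \code{query_start}, \code{query_end},
#'   \code{n_blocks}, \code{screen_window_id}; parameters echoed in the
#'   \code{"params"} attribute.
#' @export
detect_inversions <- function(paf, params = inversion_params()) {
  stopifnot(inherits(params, "inversion_params"))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), query_chrom = character(),
                      query_start = numeric(), query_end = numeric(),
                      n_blocks = integer(), screen_window_id = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "params") <- unclass(params)
  if (nrow(paf) == 0L) return(empty)
  paf <- paf[paf$mapq >= params$min_mapq &
             (paf$tend - paf$tstart) >= params$min_block, , drop = FALSE]
  if (nrow(paf) == 0L) return(empty)
  calls <- list()
  for (key in unique(paste(paf$tname, paf$qname, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    p <- paf[paf$tname == parts[1L] & paf$qname == parts[2L], , drop = FALSE]
    p <- p[order(p$tstart), , drop = FALSE]
    # majority strand per screening window, weighted by aligned reference bp
    bin <- floor(p$tstart / params$screen_len)
    span <- p$tend - p$tstart
    maj <- vapply(split(seq_len(nrow(p)), bin), function(i) {
      plus <- sum(span[i][p$strand[i] == "+"])
      minus <- sum(span[i][p$strand[i] == "-"])
      if (minus > plus) "-" else "+"
    }, character(1))
    inverted <- p$strand != maj[as.character(bin)]
    if (!any(inverted)) next
    # maximal runs of inverted blocks with reference gaps <= merge_gap
    idx <- which(inverted)
    run_id <- cumsum(c(1, diff(idx) > 1 |
      (p$tstart[idx[-1]] - p$tend[idx[-length(idx)]]) > params$merge_gap))
    for (r in split(idx, run_id)) {
      ref_start <- min(p$tstart[r]); ref_end <- max(p$tend[r])
      if (ref_end - ref_start <= params$min_len) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = parts[1L], start = ref_start, end = ref_end,
        query_chrom = parts[2L],
        query_start = min(p$qstart[r]), query_end = max(p$qend[r]),
        n_blocks = length(r),
        screen_window_id = paste0(parts[1L], ":",
                                  floor(ref_start / params$screen_len)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- unclass(params)
  out
}

#' Genes overlapping inversion calls
#'
#' A gene is reported for a call when its interval intersects the call's
#' reference interval by at least 1 bp (half-open convention: a gene ending
#' exactly at a call's start does not overlap).
#'
#' @param calls Inversion calls from \code{\link{detect_inversions}}.
#' @param genes Gene \code{data.frame} from \code{\link{read_gff_genes}}.
#' @return A list with \code{per_call} (\code{data.frame}: call coordinates,
#'   gene_id) and \code{genes} (deduplicated character vector of gene ids).
#' @export
genes_in_inversions <- function(calls, genes) {
  rows <- list()
  if (nrow(calls) && nrow(genes)) {
    for (i in seq_len(nrow(calls))) {
      g <- genes[genes$chrom == calls$chrom[i] &
                 genes$start < calls$end[i] &
                 genes$end > calls$start[i], , drop = FALSE]
      if (nrow(g) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = calls$chrom[i], start = calls$start[i], end = calls$end[i],
        gene_id = g$gene_id, stringsAsFactors = FALSE)
    }
  }
  per_call <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               gene_id = character())
  list(per_call = per_call, genes = sort(unique(per_call$gene_id)))
}
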