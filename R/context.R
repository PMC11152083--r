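#' Total overlap length between two interval sets
#'
#' Both sets are reduced to their interval unions before measuring, so the
#' result is the number of base pairs lying in both unions — insensitive to
#' how either set is split into records.
#'
#' @param windows,genic Interval \code{data.frame}s (\code{chrom},
#'   \code{start}, \code{end}; 0-based half-open).
#' @return Overlap in bp (0 for empty inputs).
#' @export
overlap_length <- function(windows, genic) {
  if (nrow(windows) == 0L || nrow(genic) == 0L) return(0)
  a <- GenomicRanges::reduce(as_granges0(windows))
  b <- GenomicRanges::reduce(as_granges0(genic))
  sum(as.numeric(BiocGenerics::width(GenomicRanges::intersect(a, b))))
}

# Uniform random re-placement of windows on the genome: every valid start
# position (across scaffolds where the window fits) is equally likely.
shuffle_windows <- function(widths, chrom_sizes, scope, chroms = NULL) {
  sizes <- as.numeric(chrom_sizes)
  nm <- names(chrom_sizes)
  n <- length(widths)
  if (scope == "chromosome") {
    slots <- sizes[match(chroms, nm)] - widths + 1
    if (anyNA(slots) || any(slots < 1)) {
      stop("a window does not fit on its own scaffold")
    }
    out_chrom <- chroms
    out_start <- floor(stats::runif(n, 0, slots))
  } else {
    out_chrom <- character(n)
    out_start <- numeric(n)
    for (w in unique(widths)) {
      i <- which(widths == w)
      slots <- pmax(sizes - w + 1, 0)
      if (sum(slots) < 1) stop("window of ", w, " bp fits on no scaffold")
      cs <- cumsum(slots)
      r <- floor(stats::runif(length(i), 0, cs[length(cs)]))
      j <- findInterval(r, cs, left.open = FALSE) + 1L
      out_chrom[i] <- nm[j]
      out_start[i] <- r - c(0, cs)[j]
    }
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_start + widths,
             stringsAsFactors = FALSE)
}

# Prefix-sum representation of an interval union, for O(log n) coverage
# queries: cov(x) = bp of the union lying in [0, x).
coverage_index <- function(intervals, chroms) {
  gr <- GenomicRanges::reduce(as_granges0(intervals))
  idx <- list()
  for (ch in chroms) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    s <- BiocGenerics::start(g) - 1
    e <- BiocGenerics::end(g)
    o <- order(s)
    s <- s[o]; e <- e[o]
    idx[[ch]] <- list(s = s, e = e, cumw = c(0, cumsum(e - s)))
  }
  idx
}

# Overlap (bp) of the union of `windows` with the indexed union. Windows are
# merged per chromosome first so self-overlapping placements are not double
# counted.
coverage_overlap <- function(idx, chrom, start, end) {
  cov <- function(ix, x) {
    j <- findInterval(x, ix$s)
    ifelse(j == 0, 0,
           ix$cumw[pmax(j, 1L)] +
             pmin(pmax(x - ix$s[pmax(j, 1L)], 0),
                  ix$e[pmax(j, 1L)] - ix$s[pmax(j, 1L)]))
  }
  total <- 0
  for (ch in unique(chrom)) {
    ix <- idx[[ch]]
    if (is.null(ix) || length(ix$s) == 0L) next
    i <- which(chrom == ch)
    o <- i[order(start[i])]
    s <- start[o]; e <- end[o]
    m <- length(s)
    if (m > 1L) {
      emax <- cummax(e)
      new <- c(TRUE, s[-1L] > emax[-m])
      s <- s[new]
      e <- emax[c(which(new)[-1L] - 1L, m)]
    }
    total <- total + sum(cov(ix, e) - cov(ix, s))
  }
  total
}

#' Permutation test of window-genic overlap
#'
#' Tests whether a window set overlaps genic regions more (enrichment) or
#' less (depletion) than expected by chance. Each permutation re-places every
#' window, length preserved, uniformly at random on the genome (default) or
#' on its own scaffold; shuffled windows may overlap one another. Empirical
#' one-sided p-values use the add-one correction
#' \code{p = (1 + #(null >= obs)) / (1 + n_perm)} and its mirror.
#'
#' @param windows Interval \code{data.frame} of the observed windows.
#' @param genic Interval \code{data.frame} of genic regions.
#' @param chrom_sizes Named numeric vector of scaffold lengths.
#' @param n_perm Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed recorded in the result.
#' @param scope \code{"genome"} (windows move anywhere) or
#'   \code{"chromosome"} (windows stay on their own scaffold).
#' @return A list of class \code{"permutation_result"}: \code{observed_overlap},
#'   \code{null_mean}, \code{null_sd}, \code{z}, \code{p_greater},
#'   \code{p_less}, \code{n_perm}, \code{seed}, \code{scope},
#'   \code{null_overlaps} (the null distribution).
#' @export
permutation_enrichment <- function(windows, genic, chrom_sizes,
                                   n_perm = 10000, seed = 1,
                                   scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  stopifnot(n_perm >= 100)
  obs <- overlap_length(windows, genic)
  widths <- windows$end - windows$start
  idx <- coverage_index(genic, names(chrom_sizes))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    sh <- shuffle_windows(widths, chrom_sizes, scope, windows$chrom)
    coverage_overlap(idx, sh$chrom, sh$start, sh$end)
  }, numeric(1))
  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  structure(list(
    observed_overlap = obs,
    null_mean = mu,
    null_sd = sdv,
    z = z,
    p_greater = (1 + sum(null >= obs)) / (1 + n_perm),
    p_less = (1 + sum(null <= obs)) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed,
    scope = scope,
    null_overlaps = null
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "permutation overlap test (%s scope, %d permutations, seed %d)\n",
    "  observed %.0f bp, null %.1f +/- %.1f bp, z = %.3f\n",
    "  p_greater = %.4g, p_less = %.4g\n"),
    x$scope, x$n_perm, x$seed, x$observed_overlap, x$null_mean, x$null_sd,
    if (is.na(x$z)) NA else x$z, x$p_greater, x$p_less))
  invisible(x)
}

#' Genes with start codons near selected windows
#'
#' A gene is reported for a window when its strand-aware 5' end (start-codon
#' proxy) lies within \code{D} bp upstream or downstream of the window, i.e.
#' in \code{[start - D, end + D)} on the same scaffold. Distances are to the
#' nearest window edge, 0 when the start codon lies inside the window.
#'
#' @param selected Interval \code{data.frame} of selected windows (columns
#'   \code{chrom}, \code{start}, \code{end}; a \code{window_id} column is
#'   carried through when present).
#' @param genes Gene \code{data.frame} from \code{\link{read_gff_genes}}.
#' @param D Proximity range in bp (default 250000).
#' @return A list with \code{per_window} (\code{data.frame}: window, gene_id,
#'   distance) and \code{genes} (deduplicated \code{data.frame}: gene_id,
#'   min distance over windows).
#' @export
genes_near_windows <- function(selected, genes, D = 250000) {
  stopifnot(D >= 0)
  hits <- list()
  if (nrow(selected) && nrow(genes)) {
    wid <- if ("window_id" %in% names(selected)) selected$window_id else
      paste0(selected$chrom, ":", selected$start, "-", selected$end)
    for (i in seq_len(nrow(selected))) {
      g <- genes[genes$chrom == selected$chrom[i] &
                 genes$start_codon_pos >= selected$start[i] - D &
                 genes$start_codon_pos < selected$end[i] + D, , drop = FALSE]
      if (nrow(g) == 0L) next
      dist <- pmax(0,
                   selected$start[i] - g$start_codon_pos,
                   g$start_codon_pos - (selected$end[i] - 1))
      hits[[length(hits) + 1L]] <- data.frame(
        window = wid[i], gene_id = g$gene_id, distance = dist,
        stringsAsFactors = FALSE)
    }
  }
  per_window <- if (length(hits)) do.call(rbind, hits) else
    data.frame(window = character(), gene_id = character(),
               distance = numeric())
  if (nrow(per_window)) {
    agg <- stats::aggregate(distance ~ gene_id, per_window, min)
    agg <- agg[order(agg$gene_id), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(gene_id = character(), distance = numeric())
  }
  list(per_window = per_window, genes = agg)
}
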