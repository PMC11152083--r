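#' Partition a genome into fixed non-overlapping windows
#'
#' Tiles each scaffold with contiguous windows of width \code{L} starting at
#' 0; the trailing window of a scaffold may be shorter than \code{L}.
#'
#' @param chrom_sizes Named numeric vector of scaffold lengths (bp).
#' @param L Window width in bp (default 10000).
#' @return A \code{data.frame} with columns \code{window_id}
#'   (\code{"chrom:index"}, index 0-based), \code{chrom}, \code{start},
#'   \code{end}; attributes \code{chrom_sizes} and \code{L}.
#' @examples
#' make_windows(c(chr1 = 25000), L = 10000)  # 3 windows, last 5 kb
#' @export
make_windows <- function(chrom_sizes, L = 10000) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 1)
  stopifnot(length(chrom_sizes) > 0, all(chrom_sizes > 0),
            !is.null(names(chrom_sizes)))
  per <- lapply(names(chrom_sizes), function(chrom) {
    size <- chrom_sizes[[chrom]]
    n <- ceiling(size / L)
    start <- (seq_len(n) - 1) * L
    data.frame(window_id = paste0(chrom, ":", seq_len(n) - 1L),
               chrom = chrom, start = start,
               end = pmin(start + L, size), stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, per)
  rownames(grid) <- NULL
  attr(grid, "chrom_sizes") <- chrom_sizes
  attr(grid, "L") <- L
  grid
}

# Character classification tables used by the column scan: unambiguous
# nucleotides (case-insensitive); everything else (N, other ambiguity codes,
# gaps) is treated as not aligned.
.ACGT <- c("A", "C", "G", "T", "a", "c", "g", "t")

#' Accumulate per-window aligned-base and SNP counts for species pairs
#'
#' Walks MAF blocks column by column on the reference genome's coordinate
#' system and counts, per window and per species pair, the reference
#' positions at which both members of the pair contribute an unambiguous
#' nucleotide (aligned bases) and at which those nucleotides differ (SNPs).
#' Pairs need not include the reference species: for a pair of two query
#' species, a column is counted at the reference position it projects to,
#' provided the reference carries an unambiguous base there.
#'
#' Each reference position is counted at most once per pair: where blocks
#' overlap on the reference, the first-encountered block wins and duplicated
#' coverage is tallied in the \code{"duplicated_bp"} attribute.
#'
#' @param maf List of MAF blocks from \code{\link{read_maf}}.
#' @param grid Window grid from \code{\link{make_windows}} on the reference
#'   genome.
#' @param ref_species Name of the reference species (must match the species
#'   component of MAF \code{src} fields).
#' @param pairs Either a character vector of query species (each paired with
#'   the reference) or a two-column \code{data.frame}/matrix of species pairs.
#' @return A long \code{data.frame}: one row per window x pair with columns
#'   \code{window_id}, \code{chrom}, \code{start}, \code{end}, \code{pair}
#'   (\code{"a_vs_b"}), \code{a}, \code{b}, \code{aligned_bases},
#'   \code{snp_count}.
#' @export
accumulate_pair_counts <- function(maf, grid, ref_species, pairs) {
  if (is.character(pairs)) {
    pairs <- data.frame(a = ref_species, b = pairs, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(a = as.character(pairs[[1L]]),
                        b = as.character(pairs[[2L]]),
                        stringsAsFactors = FALSE)
  }
  L <- attr(grid, "L")
  stopifnot(!is.null(L))
  chroms <- unique(grid$chrom)
  n_pairs <- nrow(pairs)
  pair_lab <- paste0(pairs$a, "_vs_", pairs$b)

  # per (pair, chrom): IRanges of reference spans already counted
  seen <- lapply(seq_len(n_pairs), function(i) {
    stats::setNames(rep(list(IRanges::IRanges()), length(chroms)), chroms)
  })
  dup_bp <- 0

  # accumulators; window row index = chrom offset + floor(pos / L)
  aligned <- matrix(0, nrow = nrow(grid), ncol = n_pairs,
                    dimnames = list(grid$window_id, pair_lab))
  snp <- aligned
  n_per_chrom <- table(factor(grid$chrom, levels = unique(grid$chrom)))
  chrom_off <- stats::setNames(
    cumsum(c(0, as.numeric(n_per_chrom)[-length(n_per_chrom)])),
    names(n_per_chrom))

  # base coding over raw bytes: A/a..T/t -> 1..4, '-' -> -1, anything
  # else (N, other ambiguity codes) -> 0
  code_tab <- integer(256)
  code_tab[as.integer(charToRaw("-"))] <- -1L
  for (i in 1:4) {
    code_tab[as.integer(charToRaw(c("A", "C", "G", "T")[i]))] <- i
    code_tab[as.integer(charToRaw(c("a", "c", "g", "t")[i]))] <- i
  }

  for (blk in maf) {
    ref_i <- which(blk$species == ref_species)
    if (length(ref_i) == 0L) next
    ref_i <- ref_i[1L]
    chrom <- blk$chrom[ref_i]
    if (!(chrom %in% chroms)) next
    codes <- lapply(blk$text, function(s) code_tab[as.integer(charToRaw(s))])
    names(codes) <- blk$species
    refc <- codes[[ref_i]]
    nongap <- refc != -1L
    if (!any(nongap)) {
      message("MAF block with gap-only reference row skipped on ", chrom)
      next
    }
    # forward-strand reference position of each alignment column
    pos <- rep(NA_real_, length(refc))
    if (blk$strand[ref_i] == "+") {
      pos[nongap] <- blk$fstart[ref_i] + seq_len(sum(nongap)) - 1
    } else {
      pos[nongap] <- blk$fstart[ref_i] + blk$size[ref_i] - seq_len(sum(nongap))
    }
    ref_ok <- refc >= 1L
    span <- IRanges::IRanges(start = blk$fstart[ref_i] + 1,
                             width = blk$size[ref_i])
    for (k in seq_len(n_pairs)) {
      a <- pairs$a[k]; b <- pairs$b[k]
      if (!(a %in% blk$species) || !(b %in% blk$species)) next
      ac <- codes[[a]]; bc <- codes[[b]]
      ok <- ref_ok & ac >= 1L & bc >= 1L
      # first block wins on overlapping reference coverage
      old <- seen[[k]][[chrom]]
      if (length(old) && IRanges::overlapsAny(span, old)) {
        dup <- IRanges::overlapsAny(IRanges::IRanges(pos[ok] + 1, width = 1), old)
        if (any(dup)) {
          dup_bp <- dup_bp + sum(dup)
          ok[which(ok)[dup]] <- FALSE
        }
      }
      seen[[k]][[chrom]] <- IRanges::reduce(c(old, span))
      if (!any(ok)) next
      is_snp <- ok & ac != bc
      idx <- chrom_off[[chrom]] + floor(pos[ok] / L) + 1
      aligned[, k] <- aligned[, k] + tabulate(idx, nbins = nrow(grid))
      if (any(is_snp)) {
        snp[, k] <- snp[, k] +
          tabulate(chrom_off[[chrom]] + floor(pos[is_snp] / L) + 1,
                   nbins = nrow(grid))
      }
    }
  }
  if (dup_bp > 0) {
    message("dropped ", dup_bp,
            " duplicated reference positions (depth > 1; first block wins)")
  }
  out <- data.frame(
    window_id = rep(grid$window_id, times = n_pairs),
    chrom = rep(grid$chrom, times = n_pairs),
    start = rep(grid$start, times = n_pairs),
    end = rep(grid$end, times = n_pairs),
    pair = rep(pair_lab, each = nrow(grid)),
    a = rep(pairs$a, each = nrow(grid)),
    b = rep(pairs$b, each = nrow(grid)),
    aligned_bases = as.vector(aligned),
    snp_count = as.vector(snp),
    stringsAsFactors = FALSE)
  attr(out, "duplicated_bp") <- dup_bp
  out
}

#' Per-window SNP proportions with aligned-base filtering
#'
#' Converts pair counts to SNP proportions (SNPs per aligned base) and flags
#' the windows that enter the divergence scan: a window passes when every
#' pair reaches \code{A_min} aligned bases and its chromosome class is
#' analyzed (autosome or Z; W and excluded scaffolds are dropped from the
#' scan).
#'
#' @param counts Long counts \code{data.frame} from
#'   \code{\link{accumulate_pair_counts}}.
#' @param class_map Named character vector (scaffold -> class), see
#'   \code{\link{read_class_map}}.
#' @param A_min Minimum aligned bases per window per pair (default 3000 bp,
#'   i.e. the lowest 1\% of a 10-kb window grid).
#' @return \code{counts} with added columns \code{class}, \code{proportion}
#'   (\code{NA} where no base aligned) and \code{pass_filter} (identical for
#'   all pairs of a window).
#' @export
compute_proportions <- function(counts, class_map, A_min = 3000) {
  stopifnot(A_min >= 0)
  missing_cls <- setdiff(unique(counts$chrom), names(class_map))
  if (length(missing_cls)) {
    stop("scaffold(s) missing from chromosome-class map: ",
         paste(missing_cls, collapse = ", "))
  }
  counts$class <- unname(class_map[counts$chrom])
  counts$proportion <- ifelse(counts$aligned_bases > 0,
                              counts$snp_count / counts$aligned_bases,
                              NA_real_)
  min_aligned <- stats::ave(counts$aligned_bases, counts$window_id,
                            FUN = min)
  counts$pass_filter <- min_aligned >= A_min & counts$class %in% c("autosome", "Z")
  attr(counts, "A_min") <- A_min
  counts
}
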