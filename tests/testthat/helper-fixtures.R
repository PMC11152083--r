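# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; nothing is read from disk except what the tests
# themselves write to tempdirs.

.BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = .BASES4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One MAF block data.frame in the in-memory layout of read_maf().
maf_block <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    size <- nchar(gsub("-", "", r$text, fixed = TRUE))
    start <- if (is.null(r$start)) 0 else r$start
    src_size <- if (is.null(r$src_size)) max(start + size, 1000) else r$src_size
    strand <- if (is.null(r$strand)) "+" else r$strand
    fstart <- if (strand == "+") start else src_size - (start + size)
    data.frame(species = r$species, chrom = r$chrom, start = start,
               size = size, strand = strand, src_size = src_size,
               fstart = fstart, text = r$text, stringsAsFactors = FALSE)
  }))
}

# Random small MAF fixture on one reference chromosome: gapped, N-ridden,
# possibly overlapping blocks over several species.
random_maf <- function(n_blocks = 5, species = c("ref", "q1", "q2"),
                       chrom_len = 2000, max_cols = 120) {
  blocks <- list()
  for (i in seq_len(n_blocks)) {
    ncol <- sample(20:max_cols, 1)
    start <- sample(0:(chrom_len - ncol), 1)
    make_text <- function(gap_p, n_p) {
      ch <- sample(c(.BASES4, "N", "-"), ncol, replace = TRUE,
                   prob = c(rep((1 - gap_p - n_p) / 4, 4), n_p, gap_p))
      ch
    }
    ref <- make_text(gap_p = 0.08, n_p = 0.05)
    rows <- list(list(species = species[1], chrom = "chr1",
                      start = start, src_size = chrom_len,
                      text = paste(ref, collapse = "")))
    present <- species[-1][stats::runif(length(species) - 1) < 0.85]
    for (sp in present) {
      q <- make_text(gap_p = 0.1, n_p = 0.05)
      rows[[length(rows) + 1]] <- list(species = sp, chrom = "q_chr",
                                       start = sample(0:500, 1),
                                       src_size = 5000,
                                       text = paste(q, collapse = ""))
    }
    blocks[[i]] <- maf_block(rows)
  }
  blocks
}

# Independent per-column oracle for pair counts: explicit loops, per-position
# bookkeeping, first-encountered block wins on duplicated reference coverage.
naive_pair_counts <- function(maf, grid, ref_species, a, b) {
  L <- attr(grid, "L")
  aligned <- stats::setNames(numeric(nrow(grid)), grid$window_id)
  snp <- aligned
  seen <- character(0)
  for (blk in maf) {
    if (!all(c(ref_species, a, b) %in% blk$species)) next
    ri <- which(blk$species == ref_species)[1]
    refch <- strsplit(blk$text[ri], "")[[1]]
    ach <- strsplit(blk$text[which(blk$species == a)[1]], "")[[1]]
    bch <- strsplit(blk$text[which(blk$species == b)[1]], "")[[1]]
    chrom <- blk$chrom[ri]
    pos <- blk$fstart[ri]
    block_positions <- seq(blk$fstart[ri], length.out = blk$size[ri])
    for (j in seq_along(refch)) {
      if (refch[j] == "-") next
      p <- pos
      pos <- pos + 1
      key <- paste0(chrom, ":", p)
      already <- key %in% seen
      if (already) next
      if (!(toupper(refch[j]) %in% .BASES4)) next
      if (!(toupper(ach[j]) %in% .BASES4)) next
      if (!(toupper(bch[j]) %in% .BASES4)) next
      wid <- paste0(chrom, ":", floor(p / L))
      aligned[wid] <- aligned[wid] + 1
      if (toupper(ach[j]) != toupper(bch[j])) snp[wid] <- snp[wid] + 1
    }
    seen <- union(seen, paste0(chrom, ":", block_positions))
  }
  list(aligned = aligned, snp = snp)
}

# Small simulated alignment shared by scan/pipeline tests (memoized).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 42,
        chrom_sizes = c(chr1 = 1e6, chr2 = 1e6, chrZ = 5e5, chrW = 2e5),
        n_planted = 4, n_genes = 60,
        planted_inversions = data.frame(
          species = "barn_swallow", chrom = c("chr1", "chr2"),
          start = c(3e5, 5e5), end = c(3.6e5, 5.4e5)))
      cache <<- list(cfg = cfg, sim = simulate_alignment(cfg))
    }
    cache
  }
})

swallow_design <- function(q = 0.99) {
  comparison_design("martin",
                    c("barn_swallow", "bank_swallow", "tree_swallow"), q = q)
}

planted_ids <- function(cfg) {
  paste0(cfg$planted_windows$chrom, ":",
         cfg$planted_windows$start / cfg$window_size)
}

# Default-scale simulation (the generator's out-of-the-box study conditions),
# memoized because two acceptance properties consume it.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      cache <<- list(cfg = cfg, sim = simulate_alignment(cfg))
    }
    cache
  }
})
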