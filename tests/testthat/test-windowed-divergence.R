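test_that("make_windows tiles scaffolds with a short trailing window", {
  g <- make_windows(c(chr1 = 25000), L = 10000)
  expect_equal(g$start, c(0, 10000, 20000))
  expect_equal(g$end, c(10000, 20000, 25000))
  expect_identical(g$window_id, c("chr1:0", "chr1:1", "chr1:2"))

  exact <- make_windows(c(c = 10000), L = 10000)
  expect_equal(nrow(exact), 1)
  expect_equal(exact$end, 10000)

  multi <- make_windows(c(a = 5000, b = 15000), L = 10000)
  expect_equal(nrow(multi), 3)
  expect_error(make_windows(c(a = 100), L = 0))
})

test_that("pair counts handle mismatches, N and gap columns", {
  grid <- make_windows(c(chr1 = 10000), L = 10000)
  blk <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 0, src_size = 10000,
         text = "ACGT"),
    list(species = "qry", chrom = "c", text = "ACGA")))
  cnt <- accumulate_pair_counts(list(blk), grid, "ref", "qry")
  expect_equal(cnt$aligned_bases, 4)
  expect_equal(cnt$snp_count, 1)

  blk2 <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 0, src_size = 10000,
         text = "ACGT"),
    list(species = "qry", chrom = "c", text = "ANGT")))
  cnt2 <- accumulate_pair_counts(list(blk2), grid, "ref", "qry")
  expect_equal(cnt2$aligned_bases, 3)
  expect_equal(cnt2$snp_count, 0)

  # gap in the reference consumes no reference position
  blk3 <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 0, src_size = 10000,
         text = "AC-T"),
    list(species = "qry", chrom = "c", text = "ACGT")))
  cnt3 <- accumulate_pair_counts(list(blk3), grid, "ref", "qry")
  expect_equal(cnt3$aligned_bases, 3)
})

test_that("soft-masked bases count as their base; ambiguity codes do not", {
  grid <- make_windows(c(chr1 = 10000), L = 10000)
  blk <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 0, src_size = 10000,
         text = "acgR"),
    list(species = "qry", chrom = "c", text = "ATGT")))
  cnt <- accumulate_pair_counts(list(blk), grid, "ref", "qry")
  expect_equal(cnt$aligned_bases, 3)  # R excluded
  expect_equal(cnt$snp_count, 1)      # a/A identical, c/T differs
})

test_that("minus-strand reference rows are counted at forward positions", {
  grid <- make_windows(c(chr1 = 10), L = 5)
  blk <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 2, src_size = 10,
         strand = "-", text = "ACGT"),
    list(species = "qry", chrom = "c", text = "ACGA")))
  cnt <- accumulate_pair_counts(list(blk), grid, "ref", "qry")
  # forward interval [4, 8): one aligned base in window [0,5), three in [5,10)
  expect_equal(cnt$aligned_bases, c(1, 3))
  expect_equal(sum(cnt$snp_count), 1)
})

test_that("windowed counts equal the naive per-column oracle on random MAFs", {
  set.seed(202)
  grid <- make_windows(c(chr1 = 2000), L = 500)
  for (i in 1:100) {
    maf <- random_maf(n_blocks = sample(2:6, 1))
    fast <- accumulate_pair_counts(maf, grid, "ref",
                                   data.frame(a = c("ref", "q1"),
                                              b = c("q1", "q2")))
    for (pr in list(c("ref", "q1"), c("q1", "q2"))) {
      oracle <- naive_pair_counts(maf, grid, "ref", pr[1], pr[2])
      got <- fast[fast$pair == paste0(pr[1], "_vs_", pr[2]), ]
      expect_equal(got$aligned_bases, unname(oracle$aligned))
      expect_equal(got$snp_count, unname(oracle$snp))
    }
  }
})

test_that("counts are invariant to block order and to splitting a block", {
  set.seed(303)
  grid <- make_windows(c(chr1 = 2000), L = 500)
  maf <- random_maf(n_blocks = 4)
  base <- accumulate_pair_counts(maf, grid, "ref", "q1")

  shuf <- accumulate_pair_counts(rev(maf), grid, "ref", "q1")
  expect_equal(shuf$aligned_bases, base$aligned_bases)
  expect_equal(shuf$snp_count, base$snp_count)

  # split the first block at an arbitrary column
  blk <- maf[[1]]
  cut <- 25
  split_block <- function(blk, cut) {
    lapply(list(1:cut, (cut + 1):nchar(blk$text[1])), function(cols) {
      b <- blk
      b$text <- substring(blk$text, cols[1], cols[length(cols)])
      pre <- substring(blk$text, 1, cols[1] - 1)
      pre_ungap <- nchar(gsub("-", "", pre))
      b$start <- blk$start + pre_ungap
      b$size <- nchar(gsub("-", "", b$text))
      b$fstart <- ifelse(b$strand == "+", b$start,
                         b$src_size - (b$start + b$size))
      b
    })
  }
  halves <- split_block(blk, cut)
  halves <- Filter(function(b) any(b$size > 0), halves)
  maf2 <- c(halves, maf[-1])
  split <- accumulate_pair_counts(maf2, grid, "ref", "q1")
  expect_equal(split$aligned_bases, base$aligned_bases)
  expect_equal(split$snp_count, base$snp_count)
})

test_that("query identical to reference gives zero SNPs everywhere", {
  set.seed(404)
  grid <- make_windows(c(chr1 = 2000), L = 500)
  txt <- rand_seq(300)
  blk <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 100, src_size = 2000,
         text = txt),
    list(species = "qry", chrom = "c", text = txt)))
  cnt <- accumulate_pair_counts(list(blk), grid, "ref", "qry")
  expect_equal(sum(cnt$snp_count), 0)
  expect_equal(sum(cnt$aligned_bases), 300)
})

test_that("overlapping reference coverage is counted once, first block wins", {
  grid <- make_windows(c(chr1 = 1000), L = 1000)
  b1 <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 0, src_size = 1000,
         text = "AAAA"),
    list(species = "qry", chrom = "c", text = "AAAA")))
  b2 <- maf_block(list(
    list(species = "ref", chrom = "chr1", start = 2, src_size = 1000,
         text = "AAAA"),
    list(species = "qry", chrom = "c", text = "CCCC")))
  expect_message(
    cnt <- accumulate_pair_counts(list(b1, b2), grid, "ref", "qry"),
    "duplicated")
  # positions 0-3 from b1 (0 SNPs), positions 4-5 only from b2 (2 SNPs)
  expect_equal(cnt$aligned_bases, 6)
  expect_equal(cnt$snp_count, 2)
})

test_that("compute_proportions applies the aligned-base and class filters", {
  counts <- data.frame(
    window_id = rep(c("chr1:0", "chr1:1", "chrW:0"), 2),
    chrom = rep(c("chr1", "chr1", "chrW"), 2),
    start = 0, end = 10000,
    pair = rep(c("p1", "p2"), each = 3),
    a = "x", b = "y",
    aligned_bases = c(5000, 2999, 8000, 5000, 3000, 8000),
    snp_count = c(150, 100, 100, 200, 100, 100))
  st <- compute_proportions(counts, c(chr1 = "autosome", chrW = "W"),
                            A_min = 3000)
  expect_equal(st$proportion[1], 0.030)
  # chr1:1 fails: 2999 aligned in p1 (filter is over all pairs)
  expect_false(any(st$pass_filter[st$window_id == "chr1:1"]))
  expect_true(all(st$pass_filter[st$window_id == "chr1:0"]))
  # W chromosome excluded regardless of alignment depth
  expect_false(any(st$pass_filter[st$chrom == "chrW"]))

  zero <- counts
  zero$aligned_bases[1] <- 0
  st0 <- compute_proportions(zero, c(chr1 = "autosome", chrW = "W"))
  expect_true(is.na(st0$proportion[1]))
  expect_false(st0$pass_filter[1])

  expect_error(compute_proportions(counts, c(chr1 = "autosome")), "missing")
})

test_that("per-window aligned bases sum to total aligned reference positions", {
  set.seed(505)
  grid <- make_windows(c(chr1 = 2000), L = 500)
  maf <- random_maf(n_blocks = 3)
  cnt <- accumulate_pair_counts(maf, grid, "ref", "q1")
  oracle <- naive_pair_counts(maf, grid, "ref", "ref", "q1")
  expect_equal(sum(cnt$aligned_bases), sum(oracle$aligned))
})
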