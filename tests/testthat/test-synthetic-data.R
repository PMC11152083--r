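test_that("realized divergence tracks the tree path length", {
  # two species, 0.015 + 0.015 substitutions/site, 1-Mb chromosome:
  # expected observed difference under Jukes-Cantor is within the
  # multiple-hit correction of 0.03; binomial noise at n = 1e6 is tiny
  cfg <- sim_config(seed = 5, chrom_sizes = c(chr1 = 1e6),
                    tree = "(sp1:0.015,sp2:0.015);", focal_species = "sp1",
                    planted_windows = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                    planted_inversions = data.frame(
                      species = character(), chrom = character(),
                      start = numeric(), end = numeric()),
                    n_genes = 0, gap_fraction = 0)
  sim <- simulate_alignment(cfg)
  d <- sim$truth$realized_divergence$divergence
  expect_lt(abs(d - 0.03), 0.004)
})

test_that("zero-length branches give identical sequences and zero SNPs", {
  cfg <- sim_config(seed = 6, chrom_sizes = c(chr1 = 5e4),
                    tree = "(sp1:0,sp2:0);", focal_species = "sp1",
                    planted_windows = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                    planted_inversions = data.frame(
                      species = character(), chrom = character(),
                      start = numeric(), end = numeric()),
                    n_genes = 0, gap_fraction = 0)
  sim <- simulate_alignment(cfg)
  expect_identical(sim$sequences$sp1$chr1, sim$sequences$sp2$chr1)
  grid <- make_windows(cfg$chrom_sizes, 10000)
  cnt <- accumulate_pair_counts(sim$maf, grid, "sp1", "sp2")
  expect_equal(sum(cnt$snp_count), 0)
  expect_equal(sum(cnt$aligned_bases), 5e4)
})

test_that("planted windows are elevated only in focal comparisons", {
  ts <- tiny_sim()
  grid <- make_windows(ts$cfg$chrom_sizes, 10000)
  des <- swallow_design()
  pairs <- rbind(des$focal_pairs, des$control_pairs)
  counts <- accumulate_pair_counts(ts$sim$maf, grid, "martin", pairs)
  st <- compute_proportions(counts, ts$cfg$classes)
  planted <- planted_ids(ts$cfg)
  focal <- paste0("martin_vs_", c("barn_swallow", "bank_swallow",
                                  "tree_swallow"))
  for (p in unique(st$pair)) {
    sp <- st[st$pair == p & !is.na(st$proportion), ]
    bg <- mean(sp$proportion[!(sp$window_id %in% planted)])
    pl <- mean(sp$proportion[sp$window_id %in% planted])
    if (p %in% focal) {
      expect_gt(pl, bg * 1.8)   # strong focal-branch elevation
    } else {
      expect_lt(abs(pl - bg), bg * 0.25)  # controls at background
    }
  }
})

test_that("a null simulation yields no systematic intersection", {
  cfg <- sim_config(seed = 77,
                    chrom_sizes = c(chr1 = 1e6, chr2 = 1e6, chrZ = 5e5),
                    planted_windows = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                    planted_inversions = data.frame(
                      species = character(), chrom = character(),
                      start = numeric(), end = numeric()),
                    n_genes = 0)
  sim <- simulate_alignment(cfg)
  grid <- make_windows(cfg$chrom_sizes, 10000)
  des <- swallow_design(q = 0.9)
  pairs <- rbind(des$focal_pairs, des$control_pairs)
  st <- compute_proportions(
    accumulate_pair_counts(sim$maf, grid, "martin", pairs), cfg$classes)
  sc <- suppressWarnings(delta_scan(st, des))
  # top 10% in three essentially independent rankings: expect the
  # intersection to be near the chance rate (0.1^3), far below one ranking
  expect_lt(length(sc$selected), 0.05 * nrow(sc$delta_table))
})

test_that("truth PAF encodes planted inversions by construction", {
  ts <- tiny_sim()
  pv <- plant_inversions(ts$sim)
  truth <- ts$cfg$planted_inversions
  minus <- pv$paf[pv$paf$strand == "-", ]
  expect_equal(sum(minus$tend - minus$tstart),
               sum(truth$end - truth$start))
  for (i in seq_len(nrow(truth))) {
    m <- minus[minus$tname == truth$chrom[i], ]
    expect_equal(min(m$tstart), truth$start[i])
    expect_equal(max(m$tend), truth$end[i])
  }
  # inverted segments are reverse-complemented in the query assembly
  chrom <- truth$chrom[1]
  idx <- (truth$start[1] + 1):truth$end[1]
  orig <- ts$sim$sequences[[truth$species[1]]][[chrom]][idx]
  expect_identical(pv$sequences[[chrom]][idx], rev(5L - orig))

  # no planted inversions -> all records forward
  cfg0 <- sim_config(seed = 8, chrom_sizes = c(chr1 = 2e5),
                     tree = "(sp1:0.01,sp2:0.01);", focal_species = "sp1",
                     planted_windows = data.frame(chrom = character(),
                                                  start = numeric(),
                                                  end = numeric()),
                     planted_inversions = data.frame(
                       species = character(), chrom = character(),
                       start = numeric(), end = numeric()),
                     n_genes = 0)
  pv0 <- plant_inversions(simulate_alignment(cfg0))
  expect_true(all(pv0$paf$strand == "+"))
})

test_that("an inversion flush with the chromosome start is still encoded", {
  cfg <- sim_config(seed = 9, chrom_sizes = c(chr1 = 5e5),
                    tree = "(sp1:0.01,sp2:0.01);", focal_species = "sp1",
                    planted_windows = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                    planted_inversions = data.frame(
                      species = "sp2", chrom = "chr1", start = 0,
                      end = 8e4),
                    n_genes = 0)
  pv <- plant_inversions(simulate_alignment(cfg))
  minus <- pv$paf[pv$paf$strand == "-", ]
  expect_equal(min(minus$tstart), 0)
  expect_equal(max(minus$tend), 8e4)
  calls <- detect_inversions(pv$paf)
  expect_equal(nrow(calls), 1)
})

test_that("overlapping planted inversions are rejected", {
  cfg <- sim_config(seed = 10, chrom_sizes = c(chr1 = 5e5),
                    tree = "(sp1:0.01,sp2:0.01);", focal_species = "sp1",
                    planted_windows = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                    planted_inversions = data.frame(
                      species = "sp2", chrom = "chr1",
                      start = c(1e5, 1.5e5), end = c(2e5, 2.5e5)),
                    n_genes = 0)
  expect_error(plant_inversions(simulate_alignment(cfg)), "overlapping")
})

test_that("fixture emission is deterministic and round-trips through readers", {
  cfg <- sim_config(seed = 12, chrom_sizes = c(chr1 = 2e5, chrZ = 1e5),
                    n_planted = 2, n_genes = 15,
                    planted_inversions = data.frame(
                      species = "barn_swallow", chrom = "chr1",
                      start = 5e4, end = 11e4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_fixture_set(cfg, d1)
  p2 <- emit_fixture_set(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # every artifact parses through the matching reader
  a <- read_fasta(p1$fasta_martin)
  expect_equal(unname(scaffold_lengths(a)), unname(as.integer(cfg$chrom_sizes)))
  maf <- read_maf(p1$maf)
  expect_gt(length(maf), 0)
  paf <- read_paf(p1$paf)
  expect_true(any(paf$strand == "-"))
  genes <- read_gff_genes(p1$gff)
  expect_equal(nrow(genes), 15)
  cm <- read_class_map(p1$class_map)
  expect_identical(unname(cm[c("chr1", "chrZ")]), c("autosome", "Z"))
  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth$planted_windows), 2)

  # empty gene set still yields a valid GFF3
  cfg0 <- sim_config(seed = 12, chrom_sizes = c(chr1 = 1e5), n_planted = 1,
                     n_genes = 0,
                     planted_inversions = data.frame(
                       species = character(), chrom = character(),
                       start = numeric(), end = numeric()))
  d3 <- withr::local_tempdir()
  p3 <- emit_fixture_set(cfg0, d3)
  expect_equal(nrow(read_gff_genes(p3$gff)), 0)
})
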