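#' Configuration for the four-species alignment simulator
#'
#' The generator emulates the input structure of a comparative divergence
#' scan: four swallow-like genomes related by a known guide tree with
#' background pairwise divergences near 0.030-0.039 substitutions/site,
#' focal-branch windows with an elevated substitution rate, unaligned
#' reference tracts, gene annotations, and reverse-complemented (inverted)
#' segments in one query genome.
#'
#' Default genome: three 8-Mb autosomes, a 4-Mb Z and a 1-Mb W scaffold.
#' Sizing keeps planted divergent windows (20 of them, 17 autosomal + 3 on Z)
#' below 1\% of each analyzed stratum, mirroring the real regime where
#' trait-associated outliers are far rarer than the selection quantile.
#' Default branch lengths give focal-pair divergences of 0.030 / 0.038 /
#' 0.039 substitutions/site.
#'
#' @param seed Integer seed governing all randomness.
#' @param chrom_sizes Named scaffold lengths; names ending \code{"Z"} /
#'   \code{"W"} are classed Z / W, others autosome.
#' @param tree Newick guide tree with branch lengths in substitutions/site.
#' @param focal_species Focal taxon (a leaf of \code{tree}).
#' @param rate_multiplier Substitution-rate multiplier applied on the focal
#'   terminal branch inside planted windows (default 5).
#' @param n_planted Number of planted divergent windows when
#'   \code{planted_windows} is \code{NULL}.
#' @param planted_windows \code{data.frame(chrom, start, end)} of divergent
#'   windows, or \code{NULL} to sample \code{n_planted} grid-aligned 10-kb
#'   windows (with \code{seed}) on analyzed scaffolds.
#' @param planted_inversions \code{data.frame(species, chrom, start, end)} of
#'   segments to reverse-complement in a query assembly. Default: 40-kb,
#'   60-kb and 500-kb segments in \code{barn_swallow}.
#' @param n_genes Number of non-overlapping genes annotated on the reference.
#' @param gap_fraction Fraction of the reference left out of the alignment,
#'   in contiguous tracts (default 0.1).
#' @param window_size Window width used to grid-align planted windows.
#' @param base_composition Root base frequencies (A, C, G, T).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 8e6, chr2 = 8e6, chr3 = 8e6,
                                       chrZ = 4e6, chrW = 1e6),
                       tree = paste0("((martin:0.013,barn_swallow:0.017):",
                                     "0.005,bank_swallow:0.02,",
                                     "tree_swallow:0.021);"),
                       focal_species = "martin",
                       rate_multiplier = 5,
                       n_planted = 20,
                       planted_windows = NULL,
                       planted_inversions = NULL,
                       n_genes = 200,
                       gap_fraction = 0.1,
                       window_size = 10000,
                       base_composition = c(A = 0.29, C = 0.21,
                                            G = 0.21, T = 0.29)) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 0.5, rate_multiplier >= 1,
            abs(sum(base_composition) - 1) < 1e-8)
  phy <- ape::read.tree(text = tree)
  stopifnot(focal_species %in% phy$tip.label, length(phy$tip.label) >= 2)
  classes <- ifelse(grepl("Z$", names(chrom_sizes)), "Z",
                    ifelse(grepl("W$", names(chrom_sizes)), "W", "autosome"))
  names(classes) <- names(chrom_sizes)
  if (is.null(planted_windows)) {
    set.seed(seed)
    analyzed <- names(chrom_sizes)[classes %in% c("autosome", "Z")]
    grid <- make_windows(chrom_sizes[analyzed], window_size)
    grid <- grid[grid$end - grid$start == window_size, ]  # full windows only
    # proportional to scaffold share, at least 1 on Z when present
    pick <- sort(sample.int(nrow(grid), min(n_planted, nrow(grid))))
    planted_windows <- grid[pick, c("chrom", "start", "end")]
    rownames(planted_windows) <- NULL
  }
  stopifnot(all(planted_windows$end <= chrom_sizes[planted_windows$chrom]))
  if (is.null(planted_inversions)) {
    query <- setdiff(phy$tip.label, focal_species)[1L]
    planted_inversions <- data.frame(
      species = query,
      chrom = c("chr1", "chr2", "chr3"),
      start = c(3e6, 5e6, 1e6),
      end = c(3e6 + 4e4, 5e6 + 6e4, 1e6 + 5e5),
      stringsAsFactors = FALSE)
    planted_inversions <-
      planted_inversions[planted_inversions$chrom %in% names(chrom_sizes) &
                         planted_inversions$end <=
                           chrom_sizes[planted_inversions$chrom], ]
  }
  structure(list(seed = seed, chrom_sizes = chrom_sizes, classes = classes,
                 tree = tree, focal_species = focal_species,
                 rate_multiplier = rate_multiplier,
                 planted_windows = planted_windows,
                 planted_inversions = planted_inversions,
                 n_genes = n_genes, gap_fraction = gap_fraction,
                 window_size = window_size,
                 base_composition = base_composition),
            class = "sim_config")
}

# Jukes-Cantor transition: seq is an integer vector in 1:4, t the expected
# substitutions/site; sites listed in `hot` evolve at mult * t.
.jc_mutate <- function(seq, t, hot = integer(), mult = 1) {
  p <- 0.75 * (1 - exp(-4 / 3 * t))
  change <- stats::runif(length(seq)) < p
  if (length(hot) && mult > 1) {
    p_hot <- 0.75 * (1 - exp(-4 / 3 * mult * t))
    change[hot] <- stats::runif(length(hot)) < p_hot
  }
  i <- which(change)
  if (length(i)) {
    seq[i] <- ((seq[i] - 1L + sample.int(3L, length(i), replace = TRUE)) %% 4L) + 1L
  }
  seq
}

.BASES <- c("A", "C", "G", "T")

.int_to_seq <- function(x) paste(.BASES[x], collapse = "")

.revcomp_int <- function(x) rev(5L - x)

#' Simulate a multi-species alignment with planted divergent windows
#'
#' Draws an ancestral sequence per scaffold from the configured base
#' composition and evolves it along the guide tree under a Jukes-Cantor
#' substitution process (no indels). Inside planted windows, sites on the
#' focal species' terminal branch only evolve at \code{rate_multiplier}
#' times the branch rate, producing focal-specific divergence elevation —
#' elevated in every focal comparison, background-level in every control
#' comparison. A configured fraction of the reference is dropped from the
#' alignment in contiguous unaligned tracts; each aligned tract becomes one
#' MAF block with the focal species as reference.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list: \code{sequences} (per species, list of integer-coded
#'   scaffold vectors), \code{maf} (list of MAF blocks as in
#'   \code{\link{read_maf}}), \code{genes} (gene \code{data.frame}),
#'   \code{truth} (planted windows/inversions, realized pairwise divergences,
#'   aligned tracts), \code{config}.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phy <- stats::reorder(ape::read.tree(text = config$tree), "cladewise")
  ntips <- length(phy$tip.label)
  root <- ntips + 1L
  species <- phy$tip.label
  chroms <- names(config$chrom_sizes)
  focal_edge_child <- match(config$focal_species, species)

  seqs <- stats::setNames(
    lapply(species, function(s) vector("list", length(chroms))), species)
  tracts <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    n <- as.integer(config$chrom_sizes[[ci]])
    node_seq <- vector("list", max(phy$edge))
    node_seq[[root]] <- sample.int(4L, n, replace = TRUE,
                                   prob = config$base_composition)
    pw <- config$planted_windows
    pw <- pw[pw$chrom == chrom, , drop = FALSE]
    hot <- if (nrow(pw)) unlist(lapply(seq_len(nrow(pw)), function(i)
      seq.int(pw$start[i] + 1L, pw$end[i]))) else integer()
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
      is_focal_tip <- child == focal_edge_child
      node_seq[[child]] <- .jc_mutate(
        node_seq[[parent]], phy$edge.length[e],
        hot = if (is_focal_tip) hot else integer(),
        mult = if (is_focal_tip) config$rate_multiplier else 1)
    }
    for (s in species) seqs[[s]][[ci]] <- node_seq[[match(s, species)]]

    # unaligned tracts: alternate aligned / gap segments with exponential
    # lengths so that the expected unaligned fraction is gap_fraction;
    # tract scale chosen so gaps are frequent but short, as in practice
    mean_aligned <- 10000
    gf <- config$gap_fraction
    mean_gap <- if (gf > 0) mean_aligned * gf / (1 - gf) else 0
    pos <- 0
    ct <- list()
    while (pos < n) {
      len <- max(500, round(stats::rexp(1, 1 / mean_aligned)))
      a_end <- min(pos + len, n)
      ct[[length(ct) + 1L]] <- c(pos, a_end)
      pos <- a_end
      if (gf > 0 && pos < n) {
        pos <- min(pos + max(100, round(stats::rexp(1, 1 / mean_gap))), n)
      }
    }
    tracts[[chrom]] <- do.call(rbind, ct)
  }
  names(seqs) <- species
  for (s in species) names(seqs[[s]]) <- chroms

  maf <- list()
  for (chrom in chroms) {
    n <- config$chrom_sizes[[chrom]]
    tr <- tracts[[chrom]]
    for (i in seq_len(nrow(tr))) {
      a <- tr[i, 1L]; b <- tr[i, 2L]
      rows <- data.frame(
        species = c(config$focal_species,
                    setdiff(species, config$focal_species)),
        chrom = chrom, start = a, size = b - a, strand = "+",
        src_size = n, fstart = a, text = NA_character_,
        stringsAsFactors = FALSE)
      rows$text <- vapply(rows$species, function(s)
        .int_to_seq(seqs[[s]][[chrom]][(a + 1):b]), character(1))
      maf[[length(maf) + 1L]] <- rows
    }
  }

  genes <- .simulate_genes(config)

  div <- utils::combn(species, 2)
  realized <- apply(div, 2L, function(pr) {
    num <- 0; den <- 0
    for (chrom in chroms) {
      tr <- tracts[[chrom]]
      for (i in seq_len(nrow(tr))) {
        idx <- (tr[i, 1L] + 1):tr[i, 2L]
        num <- num + sum(seqs[[pr[1L]]][[chrom]][idx] !=
                         seqs[[pr[2L]]][[chrom]][idx])
        den <- den + length(idx)
      }
    }
    num / den
  })
  realized <- data.frame(a = div[1L, ], b = div[2L, ], divergence = realized,
                         stringsAsFactors = FALSE)

  list(sequences = seqs, maf = maf, genes = genes,
       truth = list(planted_windows = config$planted_windows,
                    planted_inversions = config$planted_inversions,
                    realized_divergence = realized,
                    aligned_tracts = tracts),
       config = config)
}

# Uniformly placed non-overlapping genes (1-20 kb, random strand) on the
# reference scaffolds. Rejection sampling against previously placed genes.
.simulate_genes <- function(config) {
  if (config$n_genes == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), start_codon_pos = numeric()))
  }
  sizes <- config$chrom_sizes
  placed <- list()
  occ <- stats::setNames(rep(list(IRanges::IRanges()), length(sizes)),
                         names(sizes))
  tries <- 0
  while (length(placed) < config$n_genes && tries < config$n_genes * 50) {
    tries <- tries + 1
    len <- round(stats::runif(1, 1000, 20000))
    chrom <- sample(names(sizes), 1L, prob = sizes / sum(sizes))
    if (sizes[[chrom]] <= len) next
    start <- floor(stats::runif(1, 0, sizes[[chrom]] - len))
    ir <- IRanges::IRanges(start + 1, start + len)
    if (IRanges::overlapsAny(ir, occ[[chrom]])) next
    occ[[chrom]] <- c(occ[[chrom]], ir)
    strand <- sample(c("+", "-"), 1L)
    placed[[length(placed) + 1L]] <- data.frame(
      chrom = chrom, start = start, end = start + len, strand = strand,
      stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, placed)
  g <- g[order(g$chrom, g$start), ]
  g$gene_id <- sprintf("gene%04d", seq_len(nrow(g)))
  g$start_codon_pos <- ifelse(g$strand == "+", g$start, g$end - 1)
  rownames(g) <- NULL
  g[, c("gene_id", "chrom", "start", "end", "strand", "start_codon_pos")]
}

#' Apply planted inversions and emit a truth PAF
#'
#' Reverse-complements the configured segments in the named query species'
#' scaffolds and constructs the pairwise alignment records that a
#' whole-genome aligner would produce for this query-versus-reference pair:
#' forward-strand records over collinear segments and one or more
#' minus-strand records spanning each inverted segment, all chunked to at
#' most \code{chunk} bp. Residue matches are estimated from the realized
#' divergence of the pair.
#'
#' @param sim Result of \code{\link{simulate_alignment}}.
#' @param chunk Maximum record span in bp (default 500000).
#' @param mapq Mapping quality written to every record (default 60).
#' @return A list: \code{sequences} (query species' mutated scaffolds,
#'   integer-coded), \code{paf} (truth PAF \code{data.frame}, reference in
#'   the target columns), \code{species} (the query species).
#' @export
plant_inversions <- function(sim, chunk = 500000, mapq = 60) {
  config <- sim$config
  inv <- config$planted_inversions
  if (nrow(inv) && length(unique(inv$species)) > 1L) {
    stop("planted inversions must target a single query species")
  }
  query <- if (nrow(inv)) inv$species[1L] else
    setdiff(names(sim$sequences), config$focal_species)[1L]
  qseqs <- sim$sequences[[query]]
  # overlap check
  if (nrow(inv)) {
    for (chrom in unique(inv$chrom)) {
      ir <- inv[inv$chrom == chrom, ]
      ir <- ir[order(ir$start), ]
      if (nrow(ir) > 1L && any(ir$start[-1L] < ir$end[-nrow(ir)])) {
        stop("overlapping planted inversions on ", chrom)
      }
    }
  }
  for (i in seq_len(nrow(inv))) {
    chrom <- inv$chrom[i]
    idx <- (inv$start[i] + 1):inv$end[i]
    qseqs[[chrom]][idx] <- .revcomp_int(qseqs[[chrom]][idx])
  }
  d <- sim$truth$realized_divergence
  dpair <- d$divergence[(d$a == query & d$b == config$focal_species) |
                        (d$b == query & d$a == config$focal_species)]
  recs <- list()
  for (chrom in names(config$chrom_sizes)) {
    n <- config$chrom_sizes[[chrom]]
    ci <- inv[inv$chrom == chrom, , drop = FALSE]
    ci <- ci[order(ci$start), , drop = FALSE]
    bounds <- sort(unique(c(0, n, ci$start, ci$end)))
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i]; e <- bounds[i + 1L]
      inverted <- any(ci$start <= s & ci$end >= e)
      n_chunks <- max(1L, ceiling((e - s) / chunk))
      cuts <- round(seq(s, e, length.out = n_chunks + 1L))
      for (j in seq_len(n_chunks)) {
        cs <- cuts[j]; ce <- cuts[j + 1L]
        if (ce <= cs) next
        recs[[length(recs) + 1L]] <- data.frame(
          qname = chrom, qlen = n, qstart = cs, qend = ce,
          strand = if (inverted) "-" else "+",
          tname = chrom, tlen = n, tstart = cs, tend = ce,
          n_match = round((ce - cs) * (1 - dpair)), block_len = ce - cs,
          mapq = mapq, stringsAsFactors = FALSE)
      }
    }
  }
  list(sequences = qseqs, paf = do.call(rbind, recs), species = query)
}

#' Write a complete synthetic fixture set to disk
#'
#' Runs the simulator and writes every artifact the pipeline consumes: one
#' FASTA per species (inversions applied to the query assembly), the MAF
#' alignment, the truth PAF for the inversion query, a GFF3 of simulated
#' genes, the chromosome-class map, the truth JSON and a config echo.
#' Identical seeds give identical files.
#'
#' @param config A \code{\link{sim_config}}.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly; the simulation result in
#'   attribute \code{"sim"}.
#' @export
emit_fixture_set <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, mode = 2L) != 0L) {
    stop("output directory not writable: ", outdir)
  }
  sim <- simulate_alignment(config)
  pv <- plant_inversions(sim)
  paths <- list()
  for (s in names(sim$sequences)) {
    seqs <- if (s == pv$species) pv$sequences else sim$sequences[[s]]
    dss <- Biostrings::DNAStringSet(vapply(seqs, .int_to_seq, character(1)))
    names(dss) <- names(seqs)
    p <- file.path(outdir, paste0(s, ".fa"))
    Biostrings::writeXStringSet(dss, p, width = 80L)
    paths[[paste0("fasta_", s)]] <- p
  }
  paths$maf <- write_maf(sim$maf, file.path(outdir, "alignment.maf"))
  paths$paf <- write_paf(pv$paf, file.path(
    outdir, paste0(pv$species, "_vs_", config$focal_species, ".paf")))
  paths$gff <- write_gff_genes(sim$genes, file.path(outdir, "genes.gff3"))
  paths$class_map <- write_class_map(config$classes,
                                     file.path(outdir, "class_map.tsv"))
  truth <- sim$truth
  truth$aligned_tracts <- lapply(truth$aligned_tracts, function(m)
    data.frame(start = m[, 1L], end = m[, 2L]))
  paths$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  cfg$classes <- as.list(cfg$classes)
  cfg$base_composition <- as.list(cfg$base_composition)
  paths$config <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA)
  out <- invisible(paths)
  attr(out, "sim") <- sim
  out
}
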