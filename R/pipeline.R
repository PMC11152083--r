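#' Assemble a run configuration for the full scan
#'
#' @param maf Path to the MAF alignment (reference = focal species).
#' @param gff Path to a GFF3 of gene models on the reference (optional;
#'   without it the enrichment and proximity stages are skipped).
#' @param paf Path to a PAF of a query genome mapped onto the reference
#'   (optional; without it the inversion stage is skipped).
#' @param class_map Path to the chromosome-class map TSV.
#' @param focal_species,others Focal taxon and the non-focal taxa (>= 2).
#' @param outdir Output directory for stage artifacts.
#' @param window_size Window width in bp (default 10000).
#' @param min_aligned Aligned-base filter per window per pair (default 3000).
#' @param q Selection quantile (default 0.99).
#' @param proximity_bp Start-codon proximity range (default 250000).
#' @param n_perm Permutations for the enrichment test (default 10000).
#' @param inversion \code{\link{inversion_params}} for the inversion stage.
#' @param seed Seed for the permutation test.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(maf, class_map, focal_species, others, outdir,
                       gff = NULL, paf = NULL, window_size = 10000,
                       min_aligned = 3000, q = 0.99, proximity_bp = 250000,
                       n_perm = 10000, inversion = inversion_params(),
                       seed = 1) {
  structure(list(maf = maf, gff = gff, paf = paf, class_map = class_map,
                 focal_species = focal_species, others = others,
                 outdir = outdir, window_size = window_size,
                 min_aligned = min_aligned, q = q,
                 proximity_bp = proximity_bp, n_perm = n_perm,
                 inversion = inversion, seed = seed),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks paths, species names and parameter ranges without raising on
#' content problems; returns the problems found.
#'
#' @param config A \code{\link{run_config}}.
#' @return Character vector of errors (empty when valid); non-default
#'   parameter warnings in attribute \code{"warnings"}.
#' @export
validate_config <- function(config) {
  errs <- character()
  warns <- character()
  chk_file <- function(path, what) {
    if (!is.null(path) && !file.exists(path)) {
      errs <<- c(errs, paste0(what, " file not found: ", path))
    }
  }
  chk_file(config$maf, "MAF")
  chk_file(config$gff, "GFF3")
  chk_file(config$paf, "PAF")
  chk_file(config$class_map, "class map")
  if (length(config$others) < 2) {
    errs <- c(errs, "need >= 2 non-focal species for control comparisons")
  }
  if (config$focal_species %in% config$others) {
    errs <- c(errs, "focal species listed among the non-focal species")
  }
  if (!is.numeric(config$q) || config$q <= 0 || config$q >= 1) {
    errs <- c(errs, paste0("selection quantile q = ", config$q,
                           " outside (0, 1)"))
  }
  if (config$window_size < 1) errs <- c(errs, "window_size must be >= 1")
  if (config$min_aligned < 0) errs <- c(errs, "min_aligned must be >= 0")
  if (config$n_perm < 100) errs <- c(errs, "n_perm must be >= 100")
  if (config$proximity_bp < 0) errs <- c(errs, "proximity_bp must be >= 0")
  defaults <- c(window_size = 10000, min_aligned = 3000, q = 0.99,
                proximity_bp = 250000)
  for (p in names(defaults)) {
    if (is.numeric(config[[p]]) && config[[p]] != defaults[[p]]) {
      warns <- c(warns, paste0("non-default ", p, " = ", config[[p]],
                               " (default ", defaults[[p]], ")"))
    }
  }
  attr(errs, "warnings") <- warns
  errs
}

#' Run the full divergence scan
#'
#' Executes the pipeline end to end: window the reference, accumulate
#' aligned-base/SNP counts for every focal and control pair from the MAF,
#' filter and standardize SNP proportions, compute delta-SNP and select the
#' intersected top-quantile windows, test genic enrichment by permutation,
#' report genes with start codons within the proximity range, and call
#' inversions from the PAF. Stages lacking their input (no GFF3, no PAF) are
#' skipped. Stage artifacts are written to \code{config$outdir} as TSV/BED/
#' JSON; a run report echoing every parameter is returned and written as
#' JSON.
#'
#' @param config A \code{\link{run_config}}.
#' @return A list of class \code{"run_report"}: \code{window_stats},
#'   \code{scan} (from \code{\link{delta_scan}}), \code{selected_windows}
#'   (interval \code{data.frame}), \code{enrichment}, \code{proximal_genes},
#'   \code{inversions}, \code{inversion_genes}, \code{counts} (per-stage
#'   tallies), \code{params}.
#' @export
run_scan <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  for (w in attr(errs, "warnings")) message(w)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  maf <- read_maf(config$maf)
  class_map <- read_class_map(config$class_map)
  species_seen <- unique(unlist(lapply(maf, `[[`, "species")))
  absent <- setdiff(c(config$focal_species, config$others), species_seen)
  if (length(absent)) {
    stop("species absent from alignment: ", paste(absent, collapse = ", "))
  }
  # reference scaffold sizes from the MAF's focal rows
  ref_rows <- do.call(rbind, lapply(maf, function(b)
    b[b$species == config$focal_species, c("chrom", "src_size")]))
  sizes <- tapply(ref_rows$src_size, ref_rows$chrom, unique)
  chrom_sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  grid <- make_windows(chrom_sizes, config$window_size)
  write_intervals(cbind(grid[, c("chrom", "start", "end")],
                        name = grid$window_id), out("windows.bed"), "BED")

  design <- comparison_design(config$focal_species, config$others,
                              q = config$q)
  pairs <- rbind(design$focal_pairs, design$control_pairs)
  counts <- accumulate_pair_counts(maf, grid, config$focal_species, pairs)
  stats_table <- compute_proportions(counts, class_map,
                                     A_min = config$min_aligned)
  utils::write.table(stats_table, out("window_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  scan <- delta_scan(stats_table, design)
  utils::write.table(scan$delta_table, out("delta_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sel <- scan$delta_table[scan$delta_table$window_id %in% scan$selected,
                          c("window_id", "chrom", "start", "end", "class")]
  rownames(sel) <- NULL
  write_intervals(cbind(sel[, c("chrom", "start", "end")],
                        name = sel$window_id),
                  out("selected_windows.bed"), "BED")
  utils::write.table(sel, out("selected_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- NULL; enrichment <- NULL; proximal <- NULL
  if (!is.null(config$gff)) {
    genes <- read_gff_genes(config$gff)
    enrichment <- permutation_enrichment(
      sel, genes[, c("chrom", "start", "end")], chrom_sizes,
      n_perm = config$n_perm, seed = config$seed)
    jsonlite::write_json(
      enrichment[c("observed_overlap", "null_mean", "null_sd", "z",
                   "p_greater", "p_less", "n_perm", "seed", "scope")],
      out("enrichment.json"), auto_unbox = TRUE, digits = NA)
    proximal <- genes_near_windows(sel, genes, D = config$proximity_bp)
    utils::write.table(proximal$genes, out("proximal_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  inversions <- NULL; inv_genes <- NULL
  if (!is.null(config$paf)) {
    paf <- read_paf(config$paf)
    inversions <- detect_inversions(paf, config$inversion)
    utils::write.table(inversions, out("inversions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(inversions)) {
      write_intervals(inversions[, c("chrom", "start", "end")],
                      out("inversions.bed"), "BED")
    }
    if (!is.null(genes)) {
      inv_genes <- genes_in_inversions(inversions, genes)
      utils::write.table(inv_genes$per_call, out("inversion_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  tallies <- list(
    n_windows = nrow(grid),
    n_windows_pass = length(unique(
      stats_table$window_id[stats_table$pass_filter])),
    n_windows_scanned = nrow(scan$delta_table),
    n_selected = length(scan$selected),
    n_selected_by_class = lapply(scan$selected_by_class, length),
    n_proximal_genes = if (is.null(proximal)) NA else nrow(proximal$genes),
    n_inversions = if (is.null(inversions)) NA else nrow(inversions),
    n_inversion_genes = if (is.null(inv_genes)) NA else
      length(inv_genes$genes))
  params <- config[c("focal_species", "others", "window_size", "min_aligned",
                     "q", "proximity_bp", "n_perm", "seed")]
  params$inversion <- unclass(config$inversion)
  report_json <- list(
    package_version = as.character(utils::packageVersion("deltasnp")),
    params = params, counts = tallies)
  jsonlite::write_json(report_json, out("run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(window_stats = stats_table, scan = scan,
                 selected_windows = sel, enrichment = enrichment,
                 proximal_genes = proximal, inversions = inversions,
                 inversion_genes = inv_genes, counts = tallies,
                 params = params),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  c0 <- function(v) if (is.null(v) || is.na(v)) "-" else v
  cat("delta-SNP scan report\n",
      "  windows: ", x$counts$n_windows,
      " (", x$counts$n_windows_pass, " pass filter, ",
      x$counts$n_windows_scanned, " scanned)\n",
      "  selected windows: ", x$counts$n_selected, "\n",
      "  proximal genes: ", c0(x$counts$n_proximal_genes), "\n",
      "  inversions: ", c0(x$counts$n_inversions),
      " (", c0(x$counts$n_inversion_genes), " genes)\n", sep = "")
  invisible(x)
}
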