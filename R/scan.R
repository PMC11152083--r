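#' Define a focal-versus-control comparison design
#'
#' The scan contrasts comparisons that include the focal species (focal
#' comparisons) against comparisons among the remaining species (control
#' comparisons), which absorb divergence shared among the non-focal lineages.
#'
#' @param focal_species Name of the focal species.
#' @param others Character vector of the non-focal species (>= 2).
#' @param q Selection quantile for the top-outlier rule (default 0.99, the
#'   top 1\% of windows).
#' @param classes Chromosome classes analyzed (default autosomes and Z,
#'   handled separately).
#' @return A list of class \code{"comparison_design"} with elements
#'   \code{focal_species}, \code{focal_pairs}, \code{control_pairs},
#'   \code{q}, \code{classes}.
#' @export
comparison_design <- function(focal_species, others, q = 0.99,
                              classes = c("autosome", "Z")) {
  stopifnot(length(others) >= 2, !(focal_species %in% others),
            q > 0, q < 1)
  focal_pairs <- data.frame(a = focal_species, b = others,
                            stringsAsFactors = FALSE)
  cmb <- utils::combn(others, 2)
  control_pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ],
                              stringsAsFactors = FALSE)
  structure(list(focal_species = focal_species,
                 focal_pairs = focal_pairs,
                 control_pairs = control_pairs,
                 q = q, classes = classes),
            class = "comparison_design")
}

#' Z-transform values within a stratum partition
#'
#' Standardizes values to zero mean and unit standard deviation (sample sd,
#' n - 1 denominator) separately within each level of \code{class_partition}.
#' In the scan this is applied to per-window SNP proportions within each
#' (comparison, chromosome class) stratum, so that autosomes and the faster
#' evolving Z chromosome are each expressed in their own standard-deviation
#' units.
#'
#' @param values Numeric vector.
#' @param class_partition Factor-like vector of the same length giving each
#'   value's stratum; default puts everything in one stratum.
#' @return Numeric vector of z-scores.
#' @export
z_transform <- function(values, class_partition = rep("all", length(values))) {
  stopifnot(length(values) == length(class_partition))
  out <- rep(NA_real_, length(values))
  for (cl in unique(class_partition)) {
    i <- which(class_partition == cl)
    x <- values[i]
    if (sum(is.finite(x)) < 2L) {
      stop("stratum '", cl, "' has fewer than 2 finite values")
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("degenerate stratum '", cl, "': zero standard deviation")
    }
    out[i] <- (x - mean(x, na.rm = TRUE)) / s
  }
  out
}

#' Delta-SNP contrast of a focal comparison against controls
#'
#' \code{delta = z_focal - max(z_controls)}: positive values mark windows
#' whose standardized divergence in the focal comparison exceeds the most
#' divergent control comparison, i.e. focal-branch-specific elevation.
#'
#' @param z_focal Numeric vector of focal-comparison z-scores.
#' @param z_controls Numeric matrix (windows x control comparisons) or vector.
#' @return Numeric vector of deltas; \code{NA} wherever any input is missing.
#' @export
delta_snp <- function(z_focal, z_controls) {
  z_controls <- as.matrix(z_controls)
  stopifnot(length(z_focal) == nrow(z_controls))
  mx <- apply(z_controls, 1L, function(r) {
    if (anyNA(r)) NA_real_ else max(r)
  })
  ifelse(is.na(z_focal) | is.na(mx), NA_real_, z_focal - mx)
}

#' Select top-quantile windows by delta
#'
#' The threshold is the empirical \code{q}-quantile (linear interpolation,
#' \code{\link[stats]{quantile}} type 7) of the defined deltas; all windows
#' at or above the threshold are selected, so ties at the threshold are
#' included.
#'
#' @param delta Named numeric vector (names are window ids).
#' @param q Quantile in (0, 1).
#' @return Character vector of selected window ids.
#' @export
select_top_quantile <- function(delta, q = 0.99) {
  stopifnot(q > 0, q < 1, !is.null(names(delta)))
  delta <- delta[!is.na(delta)]
  if (length(delta) == 0L) return(character())
  if (length(delta) < 1 / (1 - q)) {
    warning("fewer than ", ceiling(1 / (1 - q)),
            " defined deltas; selecting at least the maximum")
  }
  thr <- stats::quantile(delta, probs = q, names = FALSE, type = 7)
  sel <- names(delta)[delta >= thr]
  if (length(sel) == 0L) sel <- names(delta)[which.max(delta)]
  sel
}

#' Intersect per-focal-comparison window selections
#'
#' @param per_focal_sets Named list of character vectors of window ids, one
#'   per focal comparison.
#' @return Character vector: the windows selected in every focal comparison
#'   (the "selected windows").
#' @export
intersect_selected <- function(per_focal_sets) {
  stopifnot(length(per_focal_sets) >= 1)
  Reduce(intersect, per_focal_sets)
}

#' Run the delta-SNP scan on a window statistics table
#'
#' Full outlier-selection chain: restrict to windows passing the
#' aligned-base filter and defined in every comparison, z-transform SNP
#' proportions within each (comparison, chromosome class) stratum, compute
#' per-focal-comparison deltas against the maximum control z, select the top
#' \code{q} quantile per focal comparison and class, and intersect the focal
#' selections.
#'
#' @param stats_table Long table from \code{\link{compute_proportions}}.
#' @param design A \code{\link{comparison_design}}.
#' @return A list with \code{delta_table} (wide \code{data.frame}: window
#'   metadata, per-comparison z columns \code{z.<pair>}, per-focal delta
#'   columns \code{delta.<pair>}), \code{per_focal} (named list of selected
#'   window-id vectors), \code{selected} (their intersection),
#'   \code{selected_by_class} (intersection split by chromosome class).
#' @export
delta_scan <- function(stats_table, design) {
  stopifnot(inherits(design, "comparison_design"))
  focal_lab <- paste0(design$focal_pairs$a, "_vs_", design$focal_pairs$b)
  control_lab <- paste0(design$control_pairs$a, "_vs_", design$control_pairs$b)
  need <- c(focal_lab, control_lab)
  have <- unique(stats_table$pair)
  if (!all(need %in% have)) {
    stop("comparison(s) missing from stats table: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  st <- stats_table[stats_table$pair %in% need &
                    stats_table$pass_filter &
                    stats_table$class %in% design$classes &
                    !is.na(stats_table$proportion), , drop = FALSE]
  # keep only windows defined in every comparison
  tab <- table(st$window_id)
  st <- st[st$window_id %in% names(tab)[tab == length(need)], , drop = FALSE]
  if (nrow(st) == 0L) stop("no window passes the filter in all comparisons")

  meta <- unique(st[st$pair == need[1L],
                    c("window_id", "chrom", "start", "end", "class")])
  meta <- meta[order(meta$chrom, meta$start), ]
  zs <- matrix(NA_real_, nrow = nrow(meta), ncol = length(need),
               dimnames = list(meta$window_id, need))
  for (p in need) {
    sp <- st[st$pair == p, ]
    sp <- sp[match(meta$window_id, sp$window_id), ]
    zs[, p] <- z_transform(sp$proportion, sp$class)
  }
  deltas <- matrix(NA_real_, nrow = nrow(meta), ncol = length(focal_lab),
                   dimnames = list(meta$window_id, focal_lab))
  for (p in focal_lab) {
    deltas[, p] <- delta_snp(zs[, p], zs[, control_lab, drop = FALSE])
  }
  per_focal <- lapply(focal_lab, function(p) {
    unlist(lapply(design$classes, function(cl) {
      i <- meta$class == cl
      if (!any(i)) return(character())
      select_top_quantile(stats::setNames(deltas[i, p], meta$window_id[i]),
                          design$q)
    }), use.names = FALSE)
  })
  names(per_focal) <- focal_lab
  selected <- intersect_selected(per_focal)
  delta_table <- cbind(meta,
                       stats::setNames(as.data.frame(zs), paste0("z.", need)),
                       stats::setNames(as.data.frame(deltas),
                                       paste0("delta.", focal_lab)))
  rownames(delta_table) <- NULL
  by_class <- split(selected, meta$class[match(selected, meta$window_id)])
  list(delta_table = delta_table, per_focal = per_focal,
       selected = selected, selected_by_class = by_class)
}

#' Approximate per-base divergence from pairwise alignment records
#'
#' \code{1 - sum(n_match) / sum(block_len)} over records passing the mapping
#' quality threshold: the fraction of non-matching positions in the aligned
#' blocks, an approximation of per-base sequence divergence used to build
#' the guide tree.
#'
#' @param paf PAF \code{data.frame} from \code{\link{read_paf}}.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A single divergence value in [0, 1].
#' @export
estimate_pairwise_distance <- function(paf, min_mapq = 0) {
  paf <- paf[paf$mapq >= min_mapq, , drop = FALSE]
  if (nrow(paf) == 0L) stop("no alignment records (after mapq filter)")
  1 - sum(paf$n_match) / sum(paf$block_len)
}

#' Neighbor-joining guide tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration on per-base divergences. Negative
#' branch lengths (possible on non-additive inputs) are clamped to zero with
#' a message.
#'
#' @param d Symmetric numeric matrix of pairwise distances with row/column
#'   names, or a \code{\link[stats]{dist}}.
#' @return Newick string of the unrooted tree.
#' @export
build_nj_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0),
              !is.null(rownames(d)))
    if (nrow(d) == 2L) {
      return(sprintf("(%s:%s,%s:%s);", rownames(d)[1L], d[1L, 2L] / 2,
                     rownames(d)[2L], d[1L, 2L] / 2))
    }
    d <- stats::as.dist(d)
  }
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    message("clamped ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  ape::write.tree(tree)
}
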