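---
title: "Methods: windowed delta-SNP divergence scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed delta-SNP divergence scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the statistic

Given a focal genome aligned against a small set of close relatives (here:
four swallow species, with the feather-footed Asian house martin as the
focal taxon), we want to nominate genomic regions whose divergence is
elevated *specifically on the focal lineage* — candidate regions for a
focal-specific trait — while discounting regions that are simply fast
evolving in the whole clade.

The reference genome is tiled with non-overlapping windows of width
L = 10 kb. For each window and each species pair, the alignment yields the
number of aligned bases (reference positions where both members of the pair
contribute an unambiguous A/C/G/T) and the number of SNPs (aligned
positions where the two bases differ). The **SNP proportion** of a window is
SNPs per aligned base — a per-aligned-base divergence density.

Comparisons are split into *focal* pairs (focal species vs each relative)
and *control* pairs (each pair of relatives). Controls absorb divergence
shared among the non-focal lineages: a window that is divergent in a focal
pair *and* in some control pair reflects evolution on a non-focal branch.

Within each (comparison, chromosome class) stratum, SNP proportions of the
windows passing the aligned-base filter are Z-transformed,
z = (x − mean) / sd (sample sd), putting every comparison on a common
standard-deviation scale. The per-window contrast is then

delta = z_focal − max(z_control over all control pairs)

and, per focal comparison and class, the windows in the top quantile
(q = 0.99) of delta are selected. The final "selected windows" are the
intersection of the three focal selections — windows elevated against
*every* relative but not in *any* control comparison.

A note on the sign convention: descriptions of this contrast sometimes read
as "subtract the focal proportion from the maximum control". Computed that
way the outliers of interest would sit in the *bottom* tail; since the
selection explicitly targets focal-specific *elevation* and reported delta
ranges for selected windows are positive, `delta_snp()` computes
z_focal − max(z_controls) and selection takes the upper tail. The
documentation flags this deliberately.

## Stratification and filtering choices

* **Aligned-base filter.** Windows need ≥ 3,000 aligned bases (the lowest
  1% of a 10-kb grid) in *every* analyzed pair; otherwise ratios become
  noisy and comparisons would be computed over different window sets. The
  "all pairs" semantics (rather than per-pair) keeps one common window set;
  it is configurable via `compute_proportions(A_min = )`.
* **Chromosome classes.** Autosomes and the Z chromosome are standardized
  and selected separately, because the avian Z evolves measurably faster
  (the fast-Z effect) and would otherwise dominate the upper tail. The W is
  excluded outright: a trait expressed in both sexes cannot map to the
  female-limited W. Class labels come from a user-supplied scaffold map.
* **Quantile definition.** The empirical q-quantile uses linear
  interpolation (R type 7) and ties at the threshold are included, so the
  selection is deterministic and slightly conservative in the presence of
  ties. Windows with an undefined delta in any focal comparison cannot be
  selected.
* **Duplicated alignment depth.** Where MAF blocks overlap on the
  reference, each reference position is counted at most once per pair —
  the first-encountered block wins and the dropped multiplicity is logged.
  This is the simplest reproducible contract for depth > 1.
* **Ambiguity and masking.** N and all non-ACGT ambiguity codes are treated
  as unaligned; soft-masked lowercase counts as its base (masking guides the
  aligner but is still a confident base call).

## Companion analyses

**Genic enrichment.** Whether selected windows fall inside genes more or
less than chance is tested by permutation: each permutation re-places every
window, length preserved, uniformly at random over the genome (every valid
start position equally likely; windows may land on any scaffold where they
fit, and shuffled windows may overlap — overlaps are not double counted
because overlap is measured between interval *unions*). The statistic is
the overlapped bp with the genic union; we report the null mean/sd, the
z-score, and both one-sided empirical p-values with the add-one correction
p = (1 + #{null ≥ obs}) / (1 + n_perm). A `scope = "chromosome"` variant
keeps each window on its own scaffold. Published implementations of
interval-shuffling tests differ in whether placements are constrained
(non-overlap, within-chromosome); we chose the least constrained null
because it is exactly enumerable on toy inputs (a 10-bp window on a 100-bp
chromosome against genic [0, 50) has 91 placements and expected overlap
exactly 455/91 = 5.0 bp, which the test suite checks by enumeration), and
we expose the scope rather than mimic any one tool. The seed is recorded in
every result.

**Gene proximity.** Candidate genes are those whose start codon lies within
D = 250 kb upstream or downstream of a selected window — a deliberately
wide envelope for cis-regulatory effects. The start codon is approximated
by the strand-aware 5' end of the annotated gene interval (start for `+`,
end − 1 for `-`); with transcript-level annotations the two can differ by
the 5' UTR length, which is well below D in practice. Boundaries are
inclusive upstream and half-open downstream, matching the package-wide
0-based half-open convention; distance is 0 for start codons inside the
window.

**Inversion detection.** Dot-plot screening of a query genome mapped onto
the reference is formalized as strand-run analysis of PAF records. Within
each (reference scaffold, query scaffold) pairing, blocks passing
`min_block` (5 kb) and `min_mapq` (30) are binned into 20-Mb screening
windows; the majority strand of each screening window (weighted by aligned
reference bp) defines the locally "direct" orientation, so a scaffold that
is wholesale reverse-complemented relative to the reference is not itself
an inversion. Maximal runs of opposite-strand blocks with inter-block
reference gaps ≤ `merge_gap` (100 kb) are merged, and merged runs spanning
more than `min_len` (50 kb) on the reference are reported. The 50-kb floor
and 20-Mb screen are the published screening scale; `min_block`,
`merge_gap` and `min_mapq` have no published values and are engineering
choices (suppress repeat-driven micro-blocks; bridge unaligned gaps smaller
than the features of interest) echoed in the output metadata. No breakpoint
refinement is attempted.

**Guide tree.** Pairwise per-base divergence is estimated from PAF records
as 1 − Σmatches/Σblock lengths and fed to standard neighbor joining
(`ape::nj`); negative branch lengths, which can arise on non-additive
inputs, are clamped to zero with a message. The tree is returned as newick.

## The synthetic data generator

`sim_config()` / `simulate_alignment()` generate the study conditions every
recovery test runs under:

* Four species on the guide tree
  `((martin:0.013, barn_swallow:0.017):0.005, bank_swallow:0.020,
  tree_swallow:0.021)` — branch lengths chosen so focal-pair path lengths
  are 0.030 / 0.038 / 0.039 substitutions/site, the background divergence
  regime of the real swallow alignment.
* Sequences evolve by a Jukes–Cantor substitution process (per-site change
  probability 3/4·(1 − e^(−4t/3)) per branch of length t). No indels are
  simulated inside aligned blocks; alignment incompleteness is modelled
  instead by leaving a fraction (`gap_fraction` = 0.1) of the reference out
  of the alignment in contiguous unaligned tracts (exponential lengths,
  mean aligned tract 10 kb), which is what drives windows below the
  aligned-base filter in practice.
* **Planted divergent windows**: 20 grid-aligned 10-kb windows where sites
  on the focal *terminal* branch only evolve at 5× the branch rate. This
  produces the exact signature the scan assumes — elevation in all three
  focal comparisons, background level in all controls.
* **Planted inversions**: segments of 40 kb, 60 kb and 500 kb
  reverse-complemented in the one relative with a chromosome-level
  assembly, with a truth PAF (forward flanks, minus-strand inverted
  segments, records chunked to ≤ 500 kb). The 40-kb segment sits below the
  50-kb reporting floor on purpose.
* 200 non-overlapping genes (1–20 kb, random strand) on the reference, a
  scaffold class map, and a truth JSON sufficient to score recovery.

Default genome size is 3 autosomes × 8 Mb + a 4-Mb Z + a 1-Mb W (29 Mb,
2,900 windows). The sizing is deliberate: with q = 0.99 the scan selects
about 1% of windows per stratum, so planted outliers must be *rarer* than
1% of each stratum for full recovery to be possible — here 17 autosomal
planted windows against 2,400 autosomal windows (0.7%) and 3 against 400 on
Z (0.75%). This mirrors the real regime, where trait-associated outliers
are orders of magnitude rarer than the selection fraction (a real run
partitions the focal genome into >115k windows). A simulation small enough
to make planted windows common would make the stated recovery property
arithmetically unattainable, not because the method fails but because the
quantile rule caps the selection size. The 29-Mb default runs end-to-end in
roughly a minute.

What the generator does **not** emulate: incomplete lineage sorting and
gene-tree discordance, context-dependent mutation, indels within aligned
blocks, repeat content and alignment error correlated with repeats, and
gene structure beyond a single interval per gene. Passing recovery tests
therefore demonstrate the correctness of the counting, standardization,
selection, shuffling and strand-run machinery under the model's
assumptions — not robustness to alignment artefacts in real data.

## Numerical and degenerate-input conventions

* All in-memory coordinates are 0-based half-open; GFF3 (1-based inclusive)
  is converted at the parse/write boundary; minus-strand MAF rows are
  normalized to forward-strand coordinates at parse time.
* `z_transform()` refuses strata with < 2 finite values or zero sd rather
  than emitting NaN.
* `select_top_quantile()` warns when fewer than 1/(1−q) deltas are defined
  and always selects at least the argmax window.
* A zero-sd permutation null (windows tiling the genome) reports z as
  undefined while both p-values remain valid (= 1).
* Trailing partial windows are kept in the grid; they rarely pass the
  aligned-base filter and are never special-cased.
* Assembly N50 is the largest L such that scaffolds ≥ L cover half the
  filtered assembly; the scaffold filter default (> 500 bp) matches common
  assembly-QC reporting. GC% excludes N and ambiguity codes from the
  denominator and counts soft-masked bases.

## Problem sizes used by the test suite

Unit and property tests run on 1–4 Mb simulated genomes and on randomly
generated MAF/PAF fixtures of a few kilobases; the planted-recovery and
inversion-recovery acceptance checks run the full 29-Mb default
configuration once (memoized across tests). The permutation calibration
uses the enumerable 100-bp toy at 10,000 permutations and 1,000 true-null
replicates at 200 permutations each. Two checks compare against the
published summary metrics of the deposited focal assembly (GenBank
JBBAXF000000000); they require that ~1-GB FASTA on local disk and fail with
an explicit pointer when it is absent, rather than passing vacuously.

## Known limitations

* Depth handling ("first block wins") is one defensible convention;
  alignment pipelines that project duplications differently will give
  slightly different counts in duplicated regions.
* The permutation null ignores scaffold-boundary and composition
  heterogeneity (no GC- or gap-matched shuffling).
* Inversion calls inherit the resolution of the input alignment blocks;
  boundaries are only as precise as `merge_gap`, and nested or complex
  rearrangements are reported as plain inversions.
* The scan statistic is a rank/outlier device, not a model-based test: it
  nominates regions, it does not assign significance to them.
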