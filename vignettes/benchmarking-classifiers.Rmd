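---
title: "Benchmarking taxonomic classifiers against defined mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking taxonomic classifiers against defined mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcbench)
```

## The evaluation problem

A defined mock community (DMC) is a deliberately constructed mixture of
known organisms with known — or at least intended — relative abundances.
Because its composition is a certificate rather than an inference, a DMC
turns the output of a metagenomic taxonomic classifier into something that
can be scored: every taxon the classifier reports is either really in the
mixture or it is not, and every expected taxon is either found or missed.
dmcbench implements that scoring pipeline for profile-level classifier
output (kraken-style reports, mpa-style clade profiles, or a generic
tabular dialect), from taxon-identifier synchronization through detection
and abundance metrics to per-classifier aggregation across samples.

Two practical complications shape the design. First, taxon identifiers
drift: reference databases built at different times disagree about NCBI
taxids, because ids get merged and deleted. Comparing a classifier's output
with a ground truth without synchronizing both to one taxonomy time point
produces false mismatches, so every evaluation here starts by resolving ids
against a single taxonomy dump. Second, classifiers report at heterogeneous
depths — some emit strains, some stop at genus — so all comparisons are
made after projection to a fixed rank, genus or species. Ranks above genus
are deliberately not evaluated.

## Detection metrics

Let the classifier's rank-projected output and the DMC define taxon sets.
A reported taxon present in the DMC is a true positive (TP), a reported
taxon absent from it a false positive (FP), and a DMC taxon that is not
reported a false negative (FN). Then

$$\mathrm{precision} = \frac{TP}{TP + FP}, \qquad
  \mathrm{recall} = \frac{TP}{TP + FN}, \qquad
  F1 = \frac{2\,\mathrm{precision}\cdot\mathrm{recall}}
            {\mathrm{precision} + \mathrm{recall}},$$

with the convention that each metric is 0 when its denominator is 0, so an
empty prediction scores 0 rather than NaN. F1 is the harmonic mean of
precision and recall and punishes an extreme value of either.

### Rank projection and the genus-only "unclassified" entries

At species rank, a read classified only to genus cannot name a species.
Such entries are kept as `"<Genus> unclassified"` pseudo-entries: they are
visible in the projected profile (and their mass is conserved and
reported), but they are excluded from the species-level detection sets and
abundance vectors. The rationale is that a pseudo-entry names no species,
so it can neither match nor mismatch a ground-truth species; counting it as
an FP would penalize cautious classifiers for refusing to overcall, while
counting it as a TP would reward them for information they did not provide.
This counting rule is a documented package decision — the convention of
marking genus-only calls "unclassified" at species level is standard, but
no single counting rule is. Mass at ranks above the target (family and up)
is likewise excluded and tallied separately rather than substituted by a
higher-rank match.

Taxa whose lineage simply lacks the target rank are treated as absent at
that rank, never remapped upward.

## Relative abundance

All relative abundances are computed over classified reads only: the
unclassified fraction, higher-rank mass, and species-level pseudo-entries
are excluded from the denominator. The resulting vector is the *sequence
abundance* — the fraction of classified reads per taxon — which
over-represents large genomes. When a ground truth is stated on the
organism scale (or a marker-based classifier is being scored), sequence
abundance is converted to *taxonomic abundance* by genome-length
correction:

$$w_i' = \frac{w_i / L_i}{\sum_j w_j / L_j},$$

where $L_i$ is the genome length of taxon $i$. The conversion is invariant
to a common rescaling of the lengths and is its own inverse under
reciprocal lengths. Whole-genome lengths are the expected input; no
copy-number correction is attempted.

The agreement between the expected composition $\mathbf{p}$ and the
estimated composition $\mathbf{q}$ is the L1 distance over the union of
their supports,

$$d_{L1}(\mathbf{p}, \mathbf{q}) = \sum_i |p_i - q_i|,$$

which ranges from 0 (every expected taxon recovered at exactly its
expected abundance) to 2 (no overlap at all). A DMC distributed without an
exact abundance certificate is still scored on detection metrics, but its
L1 is reported as unavailable and excluded from aggregation denominators —
never silently set to 0.

## Abundance-threshold filtering, PR curves and AUPRC

False positives tend to surface at low relative abundance, so a common
mitigation is to declare taxa below a relative-abundance threshold absent.
`apply_abundance_filter()` implements this with two pinned conventions:

* a weight exactly equal to the threshold is retained ("below the
  threshold" reads as strictly less than), and
* surviving weights are *not* renormalized — filtering decides which taxa
  count as detected; renormalizing would silently push every survivor
  over the next threshold.

Sweeping the threshold trades recall for precision. `pr_curve()` sweeps
over 0 plus every distinct observed weight; `threshold_sweep_table()`
sweeps a fixed grid (default 0 % to 1.20 % in 0.05 % steps, 25 rows) so
that tables from different samples can be aggregated row-wise. Both grids
are provided because either choice is defensible: the observed-weights
sweep captures every achievable operating point, the fixed grid is what
cross-sample medians need. Recall and the FP count are non-increasing in
the threshold; precision is not guaranteed monotone (one high-abundance FP
makes it collapse at large thresholds, a behavior the simulator can
reproduce via its heavy-tailed FP weights).

The curve is summarized by the area under the precision-recall curve
(AUPRC), integrated by the trapezoid rule with two pinned construction
details: for each distinct recall only the maximum precision attained
there is kept, and an anchor point at recall 0 carries the precision of
the smallest-recall point. With this construction the analytic extremes
are attainable exactly — a profile whose TPs all outrank its FPs scores 1,
and a profile that never contains a truth taxon collapses to the single
point (0, 0) and scores 0. L1 is intentionally *not* recomputed per
threshold: it is a property of the unfiltered classified-only vector, one
value per sample.

## Read-set preprocessing

DMC read sets from different studies differ in yield, read length and
quality, so comparisons start from standardized inputs.
`compute_read_stats()` reports the conventional summary (read count, total
bases, min/mean/max and quartile lengths, N50, Q20/Q30 base percentages).
Numerical conventions, each chosen once:

* **N50** is the smallest length $L$ such that reads of length $\ge L$
  contain at least half the total bases.
* **Q20/Q30** count bases with Phred $\ge 20$ (resp. $\ge 30$): the
  inclusive comparison matches the common sequence-statistics tools even
  where prose says "greater than".
* **Mean read quality** averages error probabilities,
  $-10\log_{10}\!\big(\tfrac1n\sum_b 10^{-q_b/10}\big)$, the nanopore
  community convention; an arithmetic-mean alternative is available via
  `convention = "arithmetic"` since not every tool states its formula.
* **Quartiles** use linear interpolation between order statistics
  (`quantile()` type 7), here and in all aggregation.

`filter_reads()` retains reads with length strictly greater than 1000
bases and mean quality strictly greater than Phred 7 by default — the
boundaries are exclusive, so a read of exactly 1000 bases or mean quality
exactly 7.0 is removed. `subsample_to_bases()` shuffles reads with a
seeded Mersenne-Twister generator and accumulates until the base target is
reached; the last read may overshoot, and the output records the RNG
algorithm and seed so the byte-level result is reproducible across
sessions. `match_length_distribution()` strips the read-length effect when
comparing flowcell chemistries: reference lengths are cut into quantile
bins and candidates are sampled without replacement per bin to match the
reference counts, with unfillable bins reported as shortfalls rather than
padded.

## Aggregation across samples

`aggregate_classifier()` summarizes each metric over samples by median,
quartiles (linear interpolation), IQR, minimum and maximum, and computes
the same five-number summary of precision, recall and F1 at every grid
threshold. `dotplot_data()` extracts the overview-plot quantities: the
unfiltered medians with IQRs plus the shifted medians at 0.05 % and 0.1 %
thresholds. Chemistry comparisons (`compare_reports()`) are kept as paired
single-sample tables with relative percentage change
$100\,(x_{\mathrm{new}} - x_{\mathrm{ref}})/x_{\mathrm{ref}}$, undefined
(reported `NA`, never 0) for a non-positive reference; a lone sample from
a newer chemistry is deliberately not folded into aggregates.

## The synthetic-data generator

Everything above is testable offline because the package generates its own
inputs with the statistical structure the evaluation assumes:

* `make_mini_taxonomy()` writes a structurally faithful taxdump (root,
  superkingdom, genera, species, decoy species, merged pairs, deleted ids)
  in the real pipe-delimited dialect, so the production parser is
  exercised bit-identically.
* `make_truth()` realizes the three canonical DMC composition shapes:
  *even* (equal fractions), *logarithmic* (each consecutive abundance one
  tenth of the previous) and *staggered* (a seeded draw of distinct
  magnitudes spanning at least two orders). Genome lengths are drawn
  uniformly from 2–8 Mbp, the span of typical bacterial genomes.
* `simulate_classifier_profile()` plants errors with known rates: each
  truth taxon is missed with probability `fn_prob`; detected abundances
  get mean-one lognormal noise with coefficient of variation `noise_cv`;
  `n_fp` off-truth species are added with log-uniform weights within a
  factor of ten of `fp_weight_scale` (heavy-tailed, so occasional
  high-abundance FPs appear and threshold sweeps show the realistic
  precision dip); and `unclassified_frac` of the mass is left
  unclassified. With all knobs at zero the evaluation is perfect by
  construction, which pins the no-error calibration of the whole pipeline.
* `simulate_reads()` draws lognormal read lengths (default median 3 kb,
  log-sd 0.6 — the shape of a typical nanopore metagenomic run) and
  per-read Gaussian quality, constant within a read so that a read's mean
  quality equals its drawn value under either averaging convention.

Simulation is at *profile* level, not read level: the system under test is
the evaluation framework, not the classifiers, so classifier internals
(k-mer matching, alignment, database incompleteness beyond FN planting)
and nanopore error profiles are out of scope. Consequently, passing tests
demonstrate that the metrics, conventions and aggregation behave exactly
as specified on inputs with known structure — they say nothing about how
any real classifier performs on real reads.

Parameter recovery closes the loop: over replicated simulations with
planted miss probability $f$ and $k$ planted FPs on an $n$-species truth,
measured mean recall matches $1-f$ and measured mean precision matches the
binomial-enumeration expectation
$\mathbb{E}\!\left[\tfrac{T}{T+k}\right]$ with
$T \sim \mathrm{Bin}(n, 1-f)$ (within sampling error, three standard
errors; the enumeration sits within rounding of the plug-in ratio
$n(1-f)/(n(1-f)+k)$).

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
instances — mini-taxonomies of a dozen-odd nodes, communities of 3–8
species, read sets of tens to hundreds of reads, 200 simulation replicates
and 1000-instance oracle batches — sizes at which brute-force oracles
(path enumeration, exhaustive set comparison, rectangle-refinement
integration, sort-based order statistics) are exact and fast. Abundance
vectors are validated to sum to 1 within $10^{-9}$; mass conservation in
projection and synchronization is exact by construction and asserted to
$10^{-9}$; AUPRC agrees with its refinement oracle to $10^{-9}$.
Merged-taxid chains are followed transitively with a cycle guard (real
dumps are single-hop; robustness is cheap), and name-based rescue of
deleted/unknown taxids uses case-insensitive *exact* scientific-name
matching only — fuzzy matching would trade silent misassignment for
recall.

## Known limitations

* Name-only profile entries that are absent from the taxonomy's
  scientific-name index are dropped (with their mass reported); synonyms
  and misspellings are not resolved.
* The sequence-to-taxonomic conversion assumes one genome length per
  taxon; plasmid content, copy number and intraspecies size variation are
  ignored.
* Ground truths with partially known abundances are not modelled: either
  every taxon has an expected fraction or none does.
* The staggered composition generator is parametric, not a replica of any
  particular commercial mock community.
* No statistical comparison between classifiers is performed; outputs are
  descriptive summaries.
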