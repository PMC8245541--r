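---
title: "Methods: coincidence-detection analysis of BONLAC de novo proteome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coincidence-detection analysis of BONLAC de novo proteome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonlac)
```

## The measurement and its quirks

BONLAC combines BONCAT (azidohomoalanine incorporation into nascent
proteins, enabling click-chemistry enrichment of the de novo proteome)
with pulsed SILAC (medium/heavy lysine and arginine distinguishing two
genotypes in one MS run). Its quantitation unit is the *normalized
heavy/medium ratio* per protein group per replicate: a dimensionless
fold change of de novo synthesis between an affected genotype and its
control, as exported by MaxQuant-style search software.

Two properties of this design drive everything in this package:

* **Label swaps.** Which genotype carries which isotope channel is
  alternated between biological replicates so channel-specific biases
  cancel. Before replicates can be pooled, each swapped replicate's
  ratio must be inverted so that every column reads
  affected/control. `orient_ratios()` applies this, driven by a
  `label_design()` that records each replicate's orientation.
* **Ratios can simply be absent.** If a protein is not synthesized
  during the labeling window — or falls below detection in one
  channel — no ratio is produced. Because the affected genotype in
  this setting synthesizes globally *less* protein, absence is
  informative (missing not at random), and it biases which proteins
  yield ratios at all. The simulator makes this mechanism explicit
  (below), and the pipeline never imputes a missing replicate ratio
  during screening.

## The coincidence-detection screen

`classify_protein()` calls each protein by three coincident filters,
with defaults matching common practice for this assay family:

1. **Majority detection.** The ratio must be quantified in a strict
   majority of replicates (`majority_min()`: 3 of 5, 4 of 7). The
   stricter variant used in some reports (e.g. at least 5 of 7) is
   available through `min_detected`.
2. **Average fold change.** The mean oriented ratio over detected
   replicates must reach ±20%: at or above 1.2 for up, at or below 0.8
   for down. The 20% window reflects what western blotting can
   reliably confirm downstream.
3. **Direction consistency.** A strict majority of the detected
   replicates must individually shift in the called direction. A
   ratio of exactly 1 votes for neither side, and a tied vote is
   always called `unchanged`.

Everything else is `unchanged`, or `insufficient` when detection
fails. There is deliberately no p-value or multiple-testing machinery
here: replicate coincidence is the error control, which mirrors how
these screens are actually run. `summarize_screen()` reports cohort
counts and percentages of the majority-detected denominator, rounded
half-up to one decimal — the convention of the published summary
figures (e.g. 107 of 1826 prints as 5.9%).

**Averaging choice.** "Average ratio" is the arithmetic mean by
default, mirroring the stated procedure; a geometric mean is exposed
as `mean_type = "geometric"` because it is the principled choice for
ratios — it makes the screen exactly symmetric under inverting every
ratio (when thresholds are reciprocal), a property the arithmetic mean
only approximates. Tests assert the exact symmetry in geometric mode
only.

## Cross-cohort concordance

`concordance_table()` intersects two cohorts' candidate lists
(candidacy means a call of `up` or `down`; `unchanged` and
`insufficient` both exclude a protein) and classifies each overlapping
protein as `both_up`, `both_down` or `reversed`. Matching is strictly
by the protein-group leading accession: gene symbols are annotation
and never create or destroy overlap, since protein groups are the
quantitation unit of the upstream search.

## Clustering of mean-normalized log fold changes

`build_fc_matrix()` restricts to proteins majority-detected in every
cohort, takes each cohort's mean oriented ratio, applies log2 and
centers each protein's row at zero ("mean-normalized log fold
change"). Both the log base and the centering axis are configurable;
row centering in log2 is the default reading because it makes a
protein's profile describe *relative* regulation across cohorts, which
is what the heatmap visualizations compare. A ±15% ratio window can be
attached as an annotation (`in_window`) to mark proteins whose
regulation is modest everywhere; it is an annotation, not a filter. A
replicate-level mode exists (`values = "replicates"`), in which a cell
missing for a majority-detected protein is filled with that protein's
cohort mean so the matrix is complete; cohort means are the default
columns.

`average_linkage_tree()` is an in-package implementation of
agglomerative clustering with *unweighted average linkage* (UPGMA
update) on Euclidean row distances — the documented default of the
Cytoscape clustering plug-in this reproduces. Implementation notes:

* Distances to a merged cluster are updated by the size-weighted
  Lance–Williams rule, which keeps every inter-cluster distance equal
  to the arithmetic mean over all cross-cluster leaf pairs.
* **Tie-break:** when two candidate merges are at exactly equal
  distance, the pair whose smallest original row indices are
  lexicographically least is merged. This makes the tree fully
  deterministic across platforms.
* Average linkage is inversion-free, so merge heights are
  non-decreasing; `cut_tree(tree, k)` therefore equals removing the
  k−1 highest merges, implemented directly by union-find over the
  first n−k merges.
* The result inherits from `hclust`, so `stats::cutree()`, `plot()`
  and `ape::as.phylo()` (used by `write_newick()`) all apply.

Tests verify the implementation two independent ways: against a
brute-force oracle that recomputes every inter-cluster mean distance
from scratch at every step (hundreds of random matrices of up to 8
rows, including forced exact ties), and against
`stats::hclust(method = "average")` heights on larger matrices.

## Validation statistics

`normalize_blot()` implements the western-blot convention: band
density divided by the lane's total-protein density (MemCode/Ponceau
loading control), expressed relative to the mean of the wild-type
lanes within each blot, so the WT mean is exactly 1 and values compare
across blots. The reference requires at least two WT lanes; a single
transgenic lane is permitted for normalization (the downstream t test
still demands two per group).

`unpaired_t_test()` is the pooled-variance Student form with
`df = n1 + n2 − 2` — the integer degrees of freedom printed in the
validation legends identify this rather than the Welch form. It
reports t, df, two-tailed p, the 95% CI of the mean difference, and
the effect as mean(first) − mean(second) with its pooled standard
error, so `sign(t)` always matches the effect's sign. p-values print
half-up at 4 decimals, with anything below 0.0001 shown as
`"< 0.0001"` (`format_p()`). Degenerate inputs follow fixed
conventions instead of erroring: two identical constant groups give
t = 0, p = 1; two unequal constant groups give an infinite statistic
and a floored p with a `degenerate` flag. `linear_regression()` is
ordinary least squares via `stats::lm()`, reporting slope, intercept,
r², and the slope's two-tailed p on n − 2 df.

## The synthetic-data generator

`simulate_experiment()` provides ground-truth data with the
statistical structure the screen assumes, so the whole pipeline is
testable without raw MS data. The model, per protein *i* and
replicate *j*:

* a latent log10 abundance $a_i \sim N(\mu, \sigma^2)$ (defaults 6, 1,
  an iBAQ-like scale);
* a true fold change $f_i$: 1 for nulls, a planted effect for a
  minority of up/down proteins (defaults 1.6 and 0.625 at 4% and 6%,
  the order of the published candidate rates);
* per-channel multiplicative noise: independent log2 components with
  sd `noise_sd_log2`/√2 per channel, so their difference — the
  observed log2 ratio noise — has sd `noise_sd_log2` (default 0.25);
* the affected channel's intensity additionally carries
  `global_synthesis_scale` (default 0.8, a ~20% global synthesis
  deficit). This scale affects *detectability only*, not emitted
  ratios, because ratio normalization removes global shifts;
* per-channel detection follows a logistic curve in realized log10
  channel intensity (`dropout_midpoint`, `dropout_slope`; defaults 5
  and 2 put roughly 70% of proteins over the majority-detection bar,
  the order of the published detection fraction); a ratio exists only
  if **both** channels are detected. `dropout_midpoint = NA` disables
  dropout for calibration runs.

Because dropout responds to the *realized* channel intensity, a null
protein whose affected-channel draw happened to be low is both more
likely to read as "down" and more likely to be missing — so among
detected nulls, up-calls outnumber down-calls whenever the global
synthesis deficit and dropout are active. This reproduces, as an
emergent property, the detection bias this assay is known for, and the
test suite asserts its direction (never a magnitude).

Raw tables are emitted with each replicate's ratio following its swap
flag, so the orientation step is always exercised;
`write_maxquant_fixture()` serializes a table into the proteinGroups
dialect (with optional decoy/contaminant rows) for reader tests.
`simulate_blot()` generates densitometry tables whose lane band/total
ratio is exactly group mean + Gaussian noise, making the downstream
pooled t test follow the closed-form noncentral-t power — the
calibration oracle used in the tests.

What the generator does **not** emulate: peptide-level evidence,
intensity-dependent ratio *variance* (noise is homoskedastic in log
space), correlated dropout across replicates, shared-peptide protein
group ambiguity, and two-species proteome mixes. Passing tests
therefore demonstrate correctness of the pipeline's logic and its
calibration under this model, not robustness to every pathology of
real MS data.

## Numerical choices

* All randomness flows from a single stream seeded by the config, with
  a fixed protein-order draw sequence: identical configs give
  byte-identical outputs, and the caller's RNG state is restored.
* Percentages and p-values round half *up* (away from zero), matching
  figure-legend arithmetic; `base::round()`'s half-even rule would
  print 5.85 as 5.8.
* Orienting a label-swapped replicate twice is an involution only up
  to floating point (1/(1/x) is not bitwise x for ~14% of doubles), so
  the pipeline's swap-flip invariance is asserted at 1e-12 relative
  tolerance for ratios and exactly for the resulting calls.
* Ratio cells exported as `0`, empty, or `NaN` all map to missing — a
  zero SILAC ratio is non-physical and marks failed quantification.
* "Only identified by site" rows are filtered by default but the
  filter is configurable, since search-output conventions differ.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data at deliberately modest sizes — hundreds to a few thousand
proteins, 5–7 replicates, tens of seeds per property — chosen so the
Monte-Carlo assertions (screen recovery ≥ 95%, null-rate bounds,
power calibration within 5 points of the closed form) have comfortable
margins while the whole suite completes in seconds. The algorithms
themselves are used unchanged at full cohort scale (the clustering is
quadratic in proteins per merge step; a ~800-protein matrix clusters
in seconds).

## Known limitations

* The screen's published counts (e.g. 180 young / 113 aged candidates)
  depend on the deposited raw spectra and a full MaxQuant search;
  this package reproduces the *procedure* and its printed arithmetic,
  not those dataset-specific totals.
* The arithmetic-mean screen is asymmetric under ratio inversion by
  construction; use geometric mode when symmetry matters.
* The logistic dropout parameters are free knobs of the simulator,
  not estimates from data — no public quantification of the
  dropout-abundance relationship exists for this assay.
* Western-blot quantification upstream of `normalize_blot()`
  (densitometry from images) is out of scope.
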