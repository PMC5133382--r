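---
title: "Anchored coverage profiles, heatmaps and clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored coverage profiles, heatmaps and clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprofiler)
```

This vignette is the package's own account of what it computes and why
the open design choices were made the way they were.

## The data model

**Coordinates.** Features are held as `GRanges`, the native R container
for stranded genomic intervals; BED (0-based half-open) and GFF/GTF
(1-based inclusive) are both converted at parse time, so a single
convention rules everything downstream. All *track-query* coordinates —
`query_bins()`, anchor positions, BED/CSV exports — are 0-based
half-open, matching the bigWig/BED convention those files use on disk.
Conversion happens only at the container boundary, never in the middle
of a computation.

**Missing versus zero.** A bigWig gap means "no observation"; a zero
means "observed, and it was zero". The two average very differently, so
tracks keep an explicit missing marker (`NA`) per base. BAM-derived
coverage, by contrast, is defined everywhere the header declares a
chromosome, so it is zero-filled. BAM coverage counts *every aligned
read's* reference span — primaries, secondaries, duplicates, any
mapping quality, no fragment extension — which is the simplest
well-defined convention when nothing more is known about the library.

**Multi-resolution summaries.** Each track carries binned sums and
non-missing counts at power-of-two block widths (2, 4, 8, … below the
chromosome length), mirroring bigWig zoom levels. A query takes the
coarsest level whose block width is at most half the requested bin
width and patches the bin edges at base level; because the levels store
exact sums and counts rather than means, the summary path agrees with
the base-level path to within float association error (well under the
1e-6 the package promises, and tested). The matrix engine itself uses
the exact base-level path, since its accuracy contract (1e-9 against a
naive reference) is stricter.

## The binned matrix

For each feature, bins tile the anchored window left-to-right in
biological (5′→3′) orientation; minus-strand windows are mirrored in
genomic space and the bin vector reversed, so column *j* always means
the same signed offset from the anchor. The anchor sits at offset 0 at
the *left edge* of the first downstream bin — the TSS-at-zero
convention of metaplots. Each bin is a length-weighted mean: a base
overlapping a bin boundary contributes in proportion to the overlap,
missing bases drop out of both numerator and denominator, and a bin
with no data at all is missing. Windows that run past a chromosome edge
are missing (not zero) in the out-of-bounds part, which keeps averages
unbiased near chromosome ends; a feature on a chromosome the track does
not know yields an all-missing row plus a logged warning rather than an
error, because real feature files routinely name scaffolds a track
lacks.

When the flank length is not a multiple of the bin width, the remainder
bin sits at the *outer* edge of the flank, so the bins adjacent to the
anchor are always full-width. In scaled ("both ends") mode the feature
body is divided into `body_bins` equal, possibly fractional, windows
between the two flanks, and the flanks reuse the point-mode bin width;
the body is rendered as `body_bins × bin` pseudo-bp on the offset axis.
The center anchor uses the floor midpoint, a deterministic tie-break
for odd lengths.

Defaults: `bin = 10` bp — fine enough for 1–2 kb windows, coarse enough
to keep matrices small — and the worked examples use 1 kb upstream /
1.5 kb downstream of the TSS, a window that comfortably spans promoter
and early gene-body signal in compact genomes.

## Profile summaries

Per bin the package reports the sample mean, the standard error
s/√n (sample standard deviation, n−1 denominator), and a 95% band
mean ± 1.959964·se. The normal quantile is used rather than Student-t
because feature sets are typically hundreds to thousands of rows, where
the two are indistinguishable; with fewer than 2 observations the
spread is undefined and reported missing, and an empty bin has a
missing mean. Missing entries are excluded per column, never by
dropping whole rows, so a feature near a chromosome edge still
contributes wherever it has data.

## Clustering

All three algorithms see the same input: the column-wise concatenation
of the *included* matrices (clustering may run on a subset of the
displayed signals), with missing entries imputed as 0 *in that input
only* — distances need complete vectors, zeros are neutral for
coverage-like data, and the displayed matrices are untouched.

* **k-means** runs Lloyd iterations (≤ 300) from a seeded greedy
  farthest-point initialisation: the first center is a seeded random
  row, each next is the row farthest from its nearest chosen center.
  This is deterministic given the seed; reproducibility of a published
  figure was judged worth more than the marginal loss improvement of
  random restarts.
* **Hierarchical** is Euclidean distance with Ward linkage, cut to *k*.
  Ward shares k-means' variance objective, so the two methods are
  directly comparable.
* **SOM** is a rectangular batch self-organizing map: codebook
  initialised from seeded random rows, 100 epochs, Gaussian
  neighbourhood whose radius decays linearly from `max(grid dims)/2` to
  0.5, rows labelled by best-matching unit, empty units dropped. A
  plain neuron count *n* (the way such maps are usually requested for
  heatmap re-clustering) maps to a 1×*n* grid; any rows×cols topology
  can be given explicitly.

Cluster ids are renumbered 1..C by decreasing mean row strength (the
missing-aware row mean over the included matrices), so cluster 1 is
always the strongest; rows are ordered by cluster and optionally by
descending strength within each cluster. The numbering is therefore
stable across methods, seeds and runs, and the exported spreadsheet
(chrom, 0-based start, end, name, strand, cluster, display rank, in
display order) round-trips: filtering one cluster and converting to BED
reproduces the export/re-upload workflow bit-exactly.

## Plotting

Plots are ggplot2 renderings written to PDF. Profile panels draw one
line per summary with an optional translucent ±se or 95% ribbon and a
dashed marker at offset 0; when autoscaled, the y range covers the full
extent of the drawn bands. Heatmaps draw one panel per signal in a
shared row order with separators at cluster boundaries; each panel's
color scale is clipped at the (0.01, 0.99) quantiles of its own
non-missing values by default, because a handful of coverage outliers
otherwise flattens the gradient, and missing cells render in a neutral
grey distinct from the gradient. Since images are otherwise untestable,
every render also writes a JSON manifest (row ids top-to-bottom, color
limits, axis limits, labels); the test suite and the batch-determinism
check compare manifests, not pixels.

## The collection and cache

The file "database" is a plain directory: `registry.json`, a `files/`
store keyed by the sha256 of the input content (re-adding identical
content is a no-op), and a `cache/` of one matrix (TSV + JSON manifest)
per (signal, feature, anchor) fingerprint. The fingerprint is a pure
function of the two content hashes and the anchor fields, so changing
any anchor parameter invalidates exactly the affected entries, and
reruns are pure cache hits. Signals arriving as wiggle/bedGraph/BAM are
converted to indexed bigWig at add time; features are stored as
normalized BED. A plain directory was preferred to an embedded database
because it is inspectable, portable and trivially testable.

## Motif-density tracks

An IUPAC pattern is scanned (via Biostrings) against each chromosome;
the value at base *i* is the number of match starts in the
`window`-wide window centered on *i*. Design decisions, all
configurable: the default window 200 is rounded up to 201 so a center
exists; both strands are counted by default, with reverse-complement
matches reported at their leftmost base — palindromes therefore count
exactly twice, a predictable and documented behaviour preferred over
silent de-duplication; densities are reported per kb by default so
tracks remain comparable across window choices, with truncated edge
windows using the truncated width as denominator; and N in the genome
matches nothing, including pattern N, so assembly gaps cannot create
phantom density.

## The synthetic-data generator

`make_scenario()` emulates the shape of a TSS-anchored chromatin study:
five feature classes (expression-quintile-like, with promoter-mark
height graded 5 → 1 across classes), three signal models — a Gaussian
promoter peak centered +150 bp of the anchor (sd 100 bp), an
elongation-like body block over +50..+1400 bp, and a two-peak flanking
mark — plus Gaussian noise (default sd 0.25, about 8% of the body-block
height, i.e. clearly visible but not overwhelming). Each feature
carries a planted body-signal type (bidirectional / unidirectional /
absent, balanced within each class), giving clustering a known ground
truth: strength ranks the three types in that order, so the
"unidirectional" set is always cluster 2, mirroring the classic
elongation-mark heatmap structure. Tracks are written as ordinary
fixedStep wiggle at a 10 bp value resolution — coverage tracks are
commonly binned at this granularity anyway, and it keeps generated
files small; anchors carry sub-bin jitter so windows are deliberately
*not* aligned to the value blocks. Default problem size is 5 classes ×
40 features on a two-chromosome ~800 kb genome, which keeps the full
4×5 precompute-and-cluster workflow under a couple of minutes on one
core while leaving enough rows (≈13 per planted type per class) for
stable clustering.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level sampling noise (signals are
shape-plus-Gaussian, not Poisson counts), mappability artefacts,
copy-number variation, overlapping or nested genes, unbalanced class
sizes, and biological heterogeneity within a planted type. Recovery of
planted clusters at ARI 1.0 demonstrates the correctness of the
machinery, not that three clusters is the right model for any real
locus set.

## Numerical choices and degenerate inputs

* Bin means are computed from cumulative sums with fractional-edge
  interpolation; unit-width integer bins short-circuit to the raw base
  values so per-base queries are exact.
* bigWig stores float32; the package's round-trip contract (≤ 1e-6
  absolute) therefore presumes track magnitudes in the usual
  normalized-coverage range (|v| ≲ 16).
* k-means ties in the farthest-point initialisation break to the lowest
  row index; duplicate initial centers fall back to distinct rows, and
  `k` larger than the number of distinct rows is an error.
* Zero-variance columns give se = 0 and a degenerate CI equal to the
  mean; single-observation columns give a mean with missing spread.
* An empty pair list batch-renders zero files successfully; an empty
  cluster id never appears (numbering is dense).
* Strength sorting places all-missing rows last within their cluster.

## Known limitations

Coverage models are unspliced and unpaired (no fragment extension, no
RPKM/CPM normalisation); bedGraph intervals must be non-overlapping
(overlap is ambiguous for a value track and is an error, not a sum);
BED thick/block columns are ignored for anchoring; matrices are not
z-scored per row (display scaling belongs to the plot layer); and the
SOM has no toroidal topology. Tracks are held in memory per
chromosome, which is comfortable for the compact genomes this tool
targets but would need chunking for mammalian-scale per-base analysis.
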