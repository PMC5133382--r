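# metaprofiler

Feature-anchored coverage profiles, heatmaps and clustering for genomic
signal tracks.

High-throughput sequencing assays — ChIP-seq for chromatin marks and
factor binding, chromatin accessibility digests, RNA-seq coverage — are
routinely interrogated by asking *what does the signal look like around
a set of genomic anchors?* (transcription start sites, peak calls, gene
bodies). `metaprofiler` is an R toolkit for exactly that workflow: it
ingests coverage tracks in any of the common formats (bigWig, wiggle,
bedGraph, BAM) and feature sets (BED, GFF, GTF), can synthesise
genome-wide motif-density tracks from IUPAC patterns, computes binned
signal matrices for every signal × feature combination under flexible
anchoring, summarises them as average profiles with error bands,
clusters heatmap rows with k-means, Ward hierarchical clustering or a
self-organizing map, and batch-renders publication-ready PDFs. It is
aimed at genomicists who want wide, scriptable data exploration —
many signals against many feature sets at once — rather than one plot
at a time.

## The computation

For a feature *i* with anchor position *aᵢ* (its 5′ start, 3′ end or
midpoint, strand-aware) and a signal track *v*(x), the profile matrix
holds length-weighted bin means

> Mᵢⱼ = ( Σₓ wⱼ(x) · v(x) ) / ( Σₓ wⱼ(x) ),  over non-missing bases x,

where bin *j* tiles the window `[aᵢ − upstream, aᵢ + downstream)` in
5′→3′ orientation (minus-strand windows are mirrored and the bin vector
reversed, so a column always means the same biological offset) and
wⱼ(x) is the overlap of base x with bin j (fractional at bin edges).
Missing data — bigWig gaps, bases beyond chromosome ends, chromosomes
absent from a track — stays missing, distinct from zero coverage, and
drops out of numerator and denominator alike. A "scaled" mode
additionally stretches each feature body onto a fixed number of
pseudo-bins between the two flanks so features of different lengths
align at both boundaries.

The average profile over *n* features reports, per bin,
μⱼ ± z·sⱼ/√nⱼ with z = 1.959964 (a normal 95% band; *nⱼ* counts
non-missing rows in bin *j*). Heatmap rows can be ordered by mean row
signal, or clustered — on any subset of the displayed signals — with
k-means (seeded greedy farthest-point initialisation, Lloyd
iterations), hierarchical clustering (Euclidean, Ward linkage) or a
rectangular batch SOM (Gaussian neighbourhood, radius decaying linearly
to 0.5 over 100 epochs). Clusters are renumbered by decreasing mean
strength, so "cluster 1" is always the strongest and numbering is
stable across methods, seeds and runs. Cluster memberships export as a
spreadsheet whose per-cluster subsets re-import as BED for follow-up
analyses.

Motif-density tracks count, at every base, the IUPAC-pattern match
starts within a centered window (default 201 bp, both strands, reported
per kb), with N in the genome matching nothing so assembly gaps never
create phantom density.

## Worked example

```r
library(metaprofiler)

# a small synthetic study: 5 TSS classes x 40 features, 3 signal tracks
scen <- make_scenario(file.path(tempdir(), "demo"), seed = 42, n_per_class = 40)

coll <- collection_open(file.path(tempdir(), "demo_coll"))
for (s in names(scen$signals))
  collection_add(coll, scen$signals[[s]], "signal", label = s)
collection_add_motif(coll, "CG", scen$genome, window = 201, label = "CG_density")
for (f in names(scen$features))
  collection_add(coll, scen$features[[f]], "feature", label = f)

# precompute all 4 x 5 matrices: TSS-anchored, 1 kb upstream, 1.5 kb
# downstream, 10 bp bins -> 250 columns each
anchor <- anchor_spec("start", upstream = 1000, downstream = 1500, bin = 10)
grid <- precompute(coll, c(names(scen$signals), "CG_density"),
                   names(scen$features), anchor)

m <- cached_matrix(coll, "promoter_peak", "tss_q1", anchor)
s <- summarize_profile(m)
s[s$offset %in% c(-495, 5, 145, 155, 1495), ]
#>   offset    mean     se   ci_lo   ci_hi     n
#> 1   -495 -0.0689 0.0296 -0.127  -0.0109    40
#> 2      5  1.72   0.0418  1.64    1.80      40
#> 3    145  4.96   0.0293  4.90    5.02      40
#> 4    155  4.98   0.0341  4.92    5.05      40
#> 5   1495 -0.0147 0.0396 -0.0922  0.0629    40
```

The promoter-mark profile is flat at baseline 1 kb upstream, rises
through the anchor and peaks (mean ≈ 5.0, the planted class-1 height)
at +150 bp — the offset where the generator centers its promoter peak —
with tight 95% bands from the 40 rows per bin.

```r
signals <- c(names(scen$signals), "CG_density")
mats <- lapply(signals, function(x) cached_matrix(coll, x, "tss_q1", anchor))
res <- cluster_rows(mats, method = "kmeans", k = 3,
                    include_mask = signals == "body_mark", seed = 1)
res
#> ClusterResult: kmeans, 40 rows, 3 cluster(s) [sizes: 14, 13, 13]
truth <- scen$truth[scen$truth$class == "tss_q1", ]
adjusted_rand_index(res$labels, as.integer(factor(truth$body_type)))
#> [1] 1
```

Clustering on the elongation-type body mark alone (while displaying all
four signals) recovers the planted bidirectional / unidirectional /
absent classes perfectly (ARI = 1). `plot_profile()`, `plot_heatmap()`
and `batch_render()` write the PDFs, each with a JSON manifest (row
order, color and axis limits) so rendered output is machine-checkable;
`export_clusters()` writes the annotation spreadsheet and
`cluster_to_bed()` turns any one cluster back into a BED file for
re-upload.

The same workflow is scriptable from a shell via the bundled CLI
(`inst/exec/metaprofiler`): subcommands `add`, `list`, `motif-track`,
`precompute`, `profile`, `heatmap`, `batch`, `export-clusters`, with
`--collection`, `--config` (YAML), `--seed` and `--log-level` globals.

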