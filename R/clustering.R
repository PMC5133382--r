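# Heatmap row clustering: k-means (seeded greedy farthest-point init +
# Lloyd), Ward hierarchical, or a rectangular batch SOM. Clustering can
# run on a subset of the displayed signals (include_mask); cluster ids
# are renumbered 1..C by decreasing mean row strength, so cluster 1 is
# always the strongest and numbering is stable across methods and runs.

#' Assemble the clustering input from one or more profile matrices
#'
#' Column-wise concatenation of the included matrices only. Missing
#' entries are imputed as 0 *in the clustering input only* (distance
#' computations need complete vectors; zeros are neutral for
#' coverage-like signal) — display matrices are untouched.
#'
#' @param matrices list of `ProfileMatrix` over the same features, in
#'   the same row order
#' @param include_mask logical vector, one per matrix: which signals
#'   feed the clustering (default: all)
#' @return numeric matrix, rows = features, columns = included bins
#' @export
assemble_cluster_input <- function(matrices, include_mask = NULL) {
  if (inherits(matrices, "ProfileMatrix")) matrices <- list(matrices)
  include_mask <- include_mask %||% rep(TRUE, length(matrices))
  stopifnot(length(include_mask) == length(matrices), any(include_mask))
  nr <- vapply(matrices, function(m) nrow(m$values), integer(1))
  if (length(unique(nr)) != 1)
    stopf("matrices have differing row counts (%s): not the same features",
          paste(nr, collapse = ", "))
  input <- do.call(cbind, lapply(matrices[include_mask], `[[`, "values"))
  input[is.na(input)] <- 0
  input
}

# Greedy farthest-point initial centers: first center is a seeded random
# row, each next is the row farthest from its nearest chosen center.
# Deterministic given the seed; ties break to the lowest row index.
farthest_point_init <- function(input, k, seed) {
  n <- nrow(input)
  set.seed(seed)
  chosen <- sample.int(n, 1)
  mind <- rowSums(sweep(input, 2, input[chosen, ], "-")^2)
  while (length(chosen) < k) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    d <- rowSums(sweep(input, 2, input[nxt, ], "-")^2)
    mind <- pmin(mind, d)
  }
  input[chosen, , drop = FALSE]
}

# Shared post-processing: renumber clusters 1..C by decreasing mean
# strength, order rows by cluster then (optionally) descending strength,
# record boundaries. All-missing-strength rows sort last within cluster.
finalize_clusters <- function(raw_labels, strength, method, seed,
                              include_mask, sort_within) {
  cl_means <- vapply(split(strength, raw_labels), mean, numeric(1),
                     na.rm = TRUE)
  rank_map <- setNames(rank(-cl_means, ties.method = "first"),
                       names(cl_means))
  labels <- unname(rank_map[as.character(raw_labels)])
  key2 <- if (sort_within) -ifelse(is.na(strength), -Inf, strength)
          else seq_along(labels)
  ord <- order(labels, key2, seq_along(labels))
  boundaries <- which(diff(labels[ord]) != 0)
  structure(list(labels = labels, order = ord, boundaries = boundaries,
                 method_used = method, seed = seed,
                 include_mask = include_mask,
                 sort_within = sort_within),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %s, %d rows, %d cluster(s) [sizes: %s]\n",
              x$method_used, length(x$labels), length(unique(x$labels)),
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}

#' K-means clustering of heatmap rows
#'
#' Lloyd iterations (at most 300) from a seeded greedy farthest-point
#' initialisation, so results are reproducible given the seed. Clusters
#' are renumbered by decreasing mean strength.
#'
#' @param input matrix from [assemble_cluster_input()]
#' @param k number of clusters (<= number of rows)
#' @param seed integer seed for the initialisation
#' @param sort_within sort rows by descending strength within clusters
#' @param strength per-row strength used for numbering/sorting; default
#'   is the row mean of `input`
#' @param include_mask provenance copy stored in the result
#' @return a `ClusterResult` with `labels`, display `order`, cluster
#'   `boundaries`, and provenance (`method_used`, `seed`,
#'   `include_mask`)
#' @export
kmeans_rows <- function(input, k, seed = 1L, sort_within = TRUE,
                        strength = NULL, include_mask = NULL) {
  n <- nrow(input)
  if (!is_count(k) || k < 1) stopf("`k` must be a positive integer")
  if (k > n) stopf("k (%d) exceeds the number of rows (%d)", k, n)
  strength <- strength %||% row_strength(input)
  centers <- unique(farthest_point_init(input, k, seed))
  if (nrow(centers) < k) {
    # degenerate duplicates: fall back to distinct rows where possible
    uin <- unique(input)
    if (nrow(uin) < k) stopf("fewer than k distinct rows")
    centers <- uin[seq_len(k), , drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::kmeans(input, centers = centers, iter.max = 300,
                  algorithm = "Lloyd"))
  finalize_clusters(fit$cluster, strength, "kmeans", seed,
                    include_mask, sort_within)
}

#' Hierarchical (Ward) clustering of heatmap rows
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`), cut to `k` clusters. Deterministic given the input; Ward
#' shares k-means' variance objective so the two are comparable.
#'
#' @inheritParams kmeans_rows
#' @return a `ClusterResult`
#' @export
hierarchical_rows <- function(input, k, sort_within = TRUE,
                              strength = NULL, include_mask = NULL) {
  n <- nrow(input)
  if (!is_count(k) || k < 1 || k > n)
    stopf("`k` must be an integer in [1, %d]", n)
  strength <- strength %||% row_strength(input)
  hc <- stats::hclust(stats::dist(input), method = "ward.D2")
  finalize_clusters(stats::cutree(hc, k = k), strength, "hierarchical",
                    NA_integer_, include_mask, sort_within)
}

#' Self-organizing map clustering of heatmap rows
#'
#' A rectangular batch SOM: the codebook is initialised from seeded
#' random rows of the input and trained for 100 epochs with a Gaussian
#' neighbourhood whose radius decays linearly from `max(grid dims)/2` to
#' 0.5. Each row is labelled by its best-matching unit; empty units are
#' dropped before renumbering. A plain neuron count `n` maps to a 1 x n
#' grid.
#'
#' @inheritParams kmeans_rows
#' @param som_grid `c(rows, cols)` of the unit grid, or a single neuron
#'   count (taken as `c(1, n)`)
#' @param epochs training epochs
#' @return a `ClusterResult`; unit coordinates of the non-empty units
#'   are kept in `$units`
#' @export
som_rows <- function(input, som_grid = c(1, 6), seed = 1L,
                     sort_within = TRUE, epochs = 100,
                     strength = NULL, include_mask = NULL) {
  if (length(som_grid) == 1) som_grid <- c(1L, as.integer(som_grid))
  stopifnot(length(som_grid) == 2, all(som_grid >= 1))
  n <- nrow(input)
  m <- prod(som_grid)
  strength <- strength %||% row_strength(input)
  grid_xy <- cbind(rep(seq_len(som_grid[1]), each = som_grid[2]),
                   rep(seq_len(som_grid[2]), times = som_grid[1]))
  grid_d2 <- as.matrix(stats::dist(grid_xy))^2
  set.seed(seed)
  codebook <- input[sample.int(n, m, replace = m > n), , drop = FALSE]
  r0 <- max(som_grid) / 2
  bmu <- function(cb) {
    d <- outer(rowSums(input^2), rowSums(cb^2), "+") - 2 * input %*% t(cb)
    max.col(-d, ties.method = "first")
  }
  for (e in seq_len(epochs)) {
    radius <- r0 + (0.5 - r0) * (e - 1) / max(epochs - 1, 1)
    b <- bmu(codebook)
    h <- exp(-grid_d2[b, , drop = FALSE] / (2 * radius^2))  # n x m weights
    denom <- colSums(h)
    upd <- t(h) %*% input / denom
    keep <- denom > 0
    codebook[keep, ] <- upd[keep, ]
  }
  labels <- bmu(codebook)
  res <- finalize_clusters(labels, strength, "som", seed,
                           include_mask, sort_within)
  res$units <- grid_xy[sort(unique(labels)), , drop = FALSE]
  res$raw_units <- labels
  res
}

#' Strength-sorted (unclustered) row order
#'
#' The `method = "none"` path: a single cluster, rows sorted by
#' descending strength when requested.
#'
#' @inheritParams kmeans_rows
#' @return a `ClusterResult` with one cluster and no boundaries
#' @export
sort_rows <- function(input, sort_within = TRUE, strength = NULL) {
  strength <- strength %||% row_strength(input)
  finalize_clusters(rep(1L, nrow(input)), strength, "none", NA_integer_,
                    NULL, sort_within)
}

#' Cluster heatmap rows with a chosen algorithm
#'
#' Front door over [kmeans_rows()], [hierarchical_rows()], [som_rows()]
#' and [sort_rows()], operating directly on profile matrices with an
#' inclusion mask (cluster on a subset of signals while displaying all).
#'
#' @param matrices list of `ProfileMatrix` over the same features
#' @param method `"kmeans"`, `"hierarchical"`, `"som"` or `"none"`
#' @param k cluster count (kmeans/hierarchical)
#' @param som_grid SOM grid, `c(rows, cols)` or a neuron count
#' @param include_mask which matrices feed the clustering (default all)
#' @param sort_within sort rows by strength within clusters
#' @param seed seed for the seeded methods
#' @return a `ClusterResult`
#' @export
cluster_rows <- function(matrices,
                         method = c("kmeans", "hierarchical", "som", "none"),
                         k = 3, som_grid = c(1, 6), include_mask = NULL,
                         sort_within = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (inherits(matrices, "ProfileMatrix")) matrices <- list(matrices)
  include_mask <- include_mask %||% rep(TRUE, length(matrices))
  input <- assemble_cluster_input(matrices, include_mask)
  # strength over the *included* matrices, missing-aware (pre-imputation)
  strength <- row_strength(do.call(cbind, lapply(
    matrices[include_mask], `[[`, "values")))
  switch(method,
    kmeans = kmeans_rows(input, k, seed, sort_within, strength, include_mask),
    hierarchical = hierarchical_rows(input, k, sort_within, strength,
                                     include_mask),
    som = som_rows(input, som_grid, seed, sort_within, strength = strength,
                   include_mask = include_mask),
    none = sort_rows(input, sort_within, strength))
}

#' Export cluster annotations as a spreadsheet
#'
#' One row per feature in display order, with 0-based half-open
#' coordinates, the cluster id and the display rank. Filtering to one
#' cluster and converting to BED (see [cluster_to_bed()]) reproduces
#' the export/re-upload workflow.
#'
#' @param result a `ClusterResult`
#' @param features the clustered `GRanges`, in original row order
#' @param out_path output CSV path
#' @return the exported tibble, invisibly
#' @export
export_clusters <- function(result, features, out_path) {
  stopifnot(inherits(result, "ClusterResult"),
            length(features) == length(result$labels))
  ord <- result$order
  strand <- as.character(BiocGenerics::strand(features))[ord]
  strand[strand == "*"] <- "."
  nm <- S4Vectors::mcols(features)$name %||% rep("", length(features))
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(features))[ord],
    start = GenomicRanges::start(features)[ord] - 1L,
    end = GenomicRanges::end(features)[ord],
    name = nm[ord],
    strand = strand,
    cluster = result$labels[ord],
    display_rank = seq_along(ord))
  utils::write.csv(df, out_path, row.names = FALSE)
  invisible(df)
}

#' Extract one cluster from a spreadsheet as a BED file
#'
#' @param csv_path CSV written by [export_clusters()]
#' @param cluster cluster id to keep
#' @param out_path output BED path
#' @return `out_path`, invisibly
#' @export
cluster_to_bed <- function(csv_path, cluster, out_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  df <- df[df$cluster == cluster, , drop = FALSE]
  if (nrow(df) == 0) stopf("no rows in cluster %s", cluster)
  nm <- ifelse(is.na(df$name) | df$name == "", ".", df$name)
  out <- data.frame(df$chrom, df$start, df$end, nm, 0L, df$strand)
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out_path)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement; 1 means identical partitions up to label
#' renaming. Thin wrapper over `mclust::adjustedRandIndex`.
#'
#' @param a,b integer label vectors of equal length
#' @return scalar ARI
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
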