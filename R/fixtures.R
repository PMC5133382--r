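# Deterministic synthetic genomes, signal tracks and feature files.
# Every module and the end-to-end workflow is testable from these
# generators alone; no external data is downloaded. Signal shapes are
# placed relative to each feature's anchor (strand-aware), so noise-free
# scenarios have analytically predictable profile matrices.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic analysis scenario on disk
#'
#' Writes a random genome (FASTA), one BED file of anchor features per
#' class, and one wiggle file per signal model. Features carry a planted
#' `body_type` — `"bidirectional"`, `"unidirectional"` or `"absent"`
#' body signal around the anchor — mimicking the cluster structure that
#' TSS-anchored elongation-mark heatmaps show in real data, so
#' clustering methods have a known ground truth to recover.
#'
#' Signal models (one track each):
#' \describe{
#'   \item{promoter_peak}{Gaussian peak just downstream of the anchor,
#'     height scaled by class (mimicking expression-graded promoter
#'     marks)}
#'   \item{body_mark}{a block over 50-1400 bp downstream (and also
#'     upstream for bidirectional features; absent for `"absent"`
#'     features) — the track the planted clusters are recoverable from}
#'   \item{flank_mark}{two Gaussian peaks flanking the anchor}
#' }
#'
#' @param dir output directory (created)
#' @param seed integer; the same seed gives byte-identical files
#' @param n_per_class features per class
#' @param classes class labels (one BED file each)
#' @param noise_sd standard deviation of Gaussian noise added to every
#'   signal value (0 gives exactly the model shapes)
#' @param spacing_bp distance between consecutive anchors
#' @param value_resolution signal tracks are piecewise constant over
#'   blocks of this many bp (wiggle `fixedStep` span); keeps generated
#'   files small
#' @return list with file paths (`genome`, `features` named by class,
#'   `signals` named by signal) and the ground-truth tibble `truth`
#'   (class, index within class, chrom, anchor position, strand,
#'   body_type)
#' @export
make_scenario <- function(dir, seed = 1L, n_per_class = 40L,
                          classes = paste0("tss_q", 1:5),
                          noise_sd = 0.25, spacing_bp = 4000L,
                          value_resolution = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n_classes <- length(classes)
  n_total <- n_per_class * n_classes
  body_types <- c("bidirectional", "unidirectional", "absent")

  # two chromosomes, features laid out on a regular grid with jitter
  half <- ceiling(n_total / 2)
  counts <- c(chrI = half, chrII = n_total - half)
  sizes <- counts * spacing_bp + 4000L
  truth <- do.call(rbind, lapply(names(counts), function(ch) {
    k <- counts[[ch]]
    tibble::tibble(
      chrom = ch,
      anchor = 2000L + spacing_bp * (seq_len(k) - 1L) +
        sample(0:(spacing_bp %/% 8L), k, replace = TRUE),
      strand = sample(c("+", "-"), k, replace = TRUE))
  }))
  idx <- sample.int(n_total)  # assign classes/body types at random
  truth$class <- rep(classes, each = n_per_class)[order(idx)]
  truth$body_type <- rep(rep(body_types, length.out = n_per_class),
                         n_classes)[order(idx)]
  truth <- truth[, c("class", "chrom", "anchor", "strand", "body_type")]

  genome_path <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(sizes), function(ch) {
    c(paste0(">", ch), substring(random_dna(sizes[[ch]]),
                                 seq(1, sizes[[ch]], 60),
                                 pmin(seq(60, sizes[[ch]] + 59, 60),
                                      sizes[[ch]])))
  })), genome_path)

  # class-graded promoter peak heights: q1 strongest ... q5 weakest
  class_height <- setNames(seq(5, 1, length.out = n_classes), classes)

  shape_value <- function(signal, offset, feat) {
    # offset is bp relative to the anchor, positive = downstream (5'->3')
    switch(signal,
      promoter_peak = class_height[[feat$class]] *
        exp(-(offset - 150)^2 / (2 * 100^2)),
      body_mark = {
        h <- 3
        down <- as.numeric(offset >= 50 & offset < 1400)
        up <- as.numeric(offset <= -50 & offset > -1400)
        switch(feat$body_type,
               bidirectional = h * (down + up),
               unidirectional = h * down,
               absent = 0)
      },
      flank_mark = 2 * exp(-(offset + 300)^2 / (2 * 120^2)) +
        2 * exp(-(offset - 600)^2 / (2 * 120^2)))
  }

  signals <- c("promoter_peak", "body_mark", "flank_mark")
  signal_paths <- setNames(file.path(dir, paste0(signals, ".wig")), signals)
  res <- value_resolution
  for (sig in signals) {
    lines <- character(0)
    for (ch in names(sizes)) {
      L <- sizes[[ch]]
      nblock <- ceiling(L / res)
      block_mid <- (seq_len(nblock) - 1L) * res + (res - 1) / 2  # 0-based
      v <- numeric(nblock)
      feats <- truth[truth$chrom == ch, ]
      for (r in seq_len(nrow(feats))) {
        f <- feats[r, ]
        rel <- block_mid - f$anchor
        if (f$strand == "-") rel <- -rel
        v <- v + shape_value(sig, rel, f)
      }
      if (noise_sd > 0) v <- v + stats::rnorm(nblock, 0, noise_sd)
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         ch, res, res),
                 sprintf("%.6g", v))
    }
    writeLines(lines, signal_paths[[sig]])
  }

  feature_paths <- setNames(file.path(dir, paste0(classes, ".bed")), classes)
  for (cl in classes) {
    rows <- truth[truth$class == cl, ]
    # 1 bp anchor features named by class + planted type + index
    df <- data.frame(rows$chrom, rows$anchor, rows$anchor + 1L,
                     sprintf("%s_%s_%03d", cl, substr(rows$body_type, 1, 3),
                             seq_len(nrow(rows))),
                     0L, rows$strand)
    utils::write.table(df, feature_paths[[cl]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  list(genome = genome_path, features = feature_paths,
       signals = signal_paths, truth = truth,
       chrom_sizes = sizes, value_resolution = res)
}

#' Planted-partition matrix for clustering tests
#'
#' Rows drawn `Normal(center, sd * I)` per group, then shuffled with a
#' recorded permutation, so clustering methods can be checked against
#' ground truth.
#'
#' @param seed integer seed
#' @param groups list of `list(n, center, sd)`; `center` is the group's
#'   mean vector (all centers must share a length)
#' @return list with `x` (matrix), `labels` (true group per row) and
#'   `permutation`
#' @export
planted_matrix <- function(seed, groups) {
  stopifnot(length(groups) >= 1)
  set.seed(seed)
  d <- length(groups[[1]]$center)
  x <- do.call(rbind, lapply(groups, function(g) {
    stopifnot(length(g$center) == d)
    matrix(stats::rnorm(g$n * d, mean = rep(g$center, each = g$n),
                        sd = g$sd), nrow = g$n)
  }))
  labels <- rep(seq_along(groups), vapply(groups, `[[`, numeric(1), "n"))
  perm <- sample.int(nrow(x))
  list(x = x[perm, , drop = FALSE], labels = labels[perm],
       permutation = perm)
}
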