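# The core computation: a features x bins matrix of mean signal under an
# anchoring specification. Bins tile each feature's window left-to-right
# in biological (5'->3') orientation after strand flip, so column j means
# the same offset from the anchor for every row; the anchor sits at
# offset 0, at the left edge of the first downstream bin (the
# TSS-at-zero convention of metaplots).

#' Specify window anchoring for profile matrices
#'
#' @param mode `"start"`, `"end"`, `"center"` (point anchors) or
#'   `"scaled"` (both-ends anchoring: flanks plus a fixed number of
#'   pseudo-bins stretched across each feature body)
#' @param upstream,downstream flank lengths in bp (>= 0; their sum must
#'   be positive for point anchors)
#' @param bin bin width in bp (default 10); the outermost bin on each
#'   side may be fractional when `bin` does not divide the flank
#' @param body_bins number of equal-width (possibly fractional) windows
#'   across the feature body, `"scaled"` mode only
#' @param ignore_strand treat every feature as plus-strand
#' @return an `AnchorSpec` object
#' @export
anchor_spec <- function(mode = c("start", "end", "center", "scaled"),
                        upstream = 1000, downstream = 1000, bin = 10,
                        body_bins = 100, ignore_strand = FALSE) {
  mode <- match.arg(mode)
  stopifnot(upstream >= 0, downstream >= 0, bin >= 1)
  if (mode != "scaled" && upstream + downstream <= 0)
    stopf("upstream + downstream must be positive for point anchors")
  if (mode == "scaled" && (!is_count(body_bins) || body_bins < 1))
    stopf("`body_bins` must be a positive integer")
  structure(list(mode = mode, upstream = upstream, downstream = downstream,
                 bin = bin, body_bins = as.integer(body_bins),
                 ignore_strand = isTRUE(ignore_strand)),
            class = "AnchorSpec")
}

anchor_fingerprint <- function(anchor) {
  digest::digest(unclass(anchor), algo = "sha256")
}

#' Anchor position of an interval
#'
#' Returns the 0-based genomic position of the biological start, end or
#' center of a feature. For a minus-strand feature the biological start
#' is its right edge and vice versa; the center uses the floor midpoint
#' (deterministic for odd lengths) and is strand-invariant.
#'
#' @param features a `GRanges`
#' @param mode `"start"`, `"end"` or `"center"`
#' @param ignore_strand treat all features as plus-strand
#' @return integer vector of 0-based anchor positions
#' @export
anchor_point <- function(features, mode = c("start", "end", "center"),
                         ignore_strand = FALSE) {
  mode <- match.arg(mode)
  s0 <- GenomicRanges::start(features) - 1L
  e0 <- GenomicRanges::end(features)
  minus <- as.character(BiocGenerics::strand(features)) == "-" & !ignore_strand
  switch(mode,
    start = ifelse(minus, e0, s0),
    end = ifelse(minus, s0, e0),
    center = (s0 + e0) %/% 2L)
}

# Bin boundaries (in bp, relative to the anchor at 0, increasing) for the
# two flanks. The outermost bin on each side absorbs any remainder.
flank_breaks <- function(upstream, downstream, bin) {
  nup <- ceiling(upstream / bin)
  ndown <- ceiling(downstream / bin)
  up <- if (nup > 0) c(-upstream, -bin * ((nup - 1L):0)) else 0
  down <- if (ndown > 0) c(bin * (0:(ndown - 1L)), downstream) else numeric(0)
  unique(c(up, down))
}

#' Compute a profile matrix for one signal x feature pair
#'
#' Point modes tile `[anchor - upstream, anchor + downstream)` with bins
#' of width `bin` (edge bins may be fractional); minus-strand rows use
#' the mirrored genomic window and are reversed, so every column means
#' the same biological offset. Scaled mode inserts `body_bins`
#' equal-width windows across each feature body between the flanks. Bins
#' are length-weighted means of per-base values; bases beyond chromosome
#' edges or without data are missing, and a fully-missing bin is `NA`.
#'
#' @param features a `GRanges` (see [read_features()])
#' @param track a [signal_track()]
#' @param anchor an [anchor_spec()]
#' @param signal_label,feature_label labels carried into plots/exports
#' @return a `ProfileMatrix`: list with `values` (features x bins),
#'   `bin_centers` (bp offsets, negative upstream; in scaled mode the
#'   body is rendered as `body_bins * bin` pseudo-bp), `feature_ids`,
#'   labels and the anchor spec
#' @export
compute_matrix <- function(features, track, anchor,
                           signal_label = "signal",
                           feature_label = "features") {
  stopifnot(inherits(track, "SignalTrack"), inherits(anchor, "AnchorSpec"))
  n <- length(features)
  chroms <- as.character(GenomicRanges::seqnames(features))
  minus <- as.character(BiocGenerics::strand(features)) == "-" &
    !anchor$ignore_strand

  if (anchor$mode != "scaled") {
    rel <- flank_breaks(anchor$upstream, anchor$downstream, anchor$bin)
    centers <- (rel[-1] + rel[-length(rel)]) / 2
    apos <- anchor_point(features, anchor$mode, anchor$ignore_strand)
    rows <- lapply(seq_len(n), function(i) {
      breaks <- if (minus[i]) apos[i] - rev(rel) else apos[i] + rel
      v <- track_bin_query_safe(track, chroms[i], breaks)
      if (minus[i]) rev(v) else v
    })
  } else {
    upb <- flank_breaks(anchor$upstream, 0, anchor$bin)
    downb <- flank_breaks(0, anchor$downstream, anchor$bin)
    body_len <- anchor$body_bins * anchor$bin  # pseudo-bp for plotting
    rel_centers <- c((upb[-1] + upb[-length(upb)]) / 2,
                     (0:(anchor$body_bins - 1) + 0.5) * anchor$bin,
                     body_len + (downb[-1] + downb[-length(downb)]) / 2)
    centers <- rel_centers
    s0 <- GenomicRanges::start(features) - 1L
    e0 <- GenomicRanges::end(features)
    rows <- lapply(seq_len(n), function(i) {
      L <- e0[i] - s0[i]
      body <- s0[i] + L * (0:anchor$body_bins) / anchor$body_bins
      breaks <- if (minus[i]) {
        c(s0[i] - rev(downb[-1]), body, e0[i] + rev(-upb[-length(upb)]))
      } else {
        c(s0[i] + upb[-length(upb)], body, e0[i] + downb[-1])
      }
      v <- track_bin_query_safe(track, chroms[i], breaks)
      if (minus[i]) rev(v) else v
    })
  }
  values <- if (n == 0) matrix(numeric(0), 0, length(centers)) else
    do.call(rbind, rows)
  rownames(values) <- NULL
  structure(list(values = values, bin_centers = centers,
                 feature_ids = feature_ids(features),
                 signal_label = signal_label, feature_label = feature_label,
                 anchor = anchor),
            class = "ProfileMatrix")
}

# As track_bin_query, but an unknown chromosome gives an all-NA row with
# one logged warning rather than an error.
track_bin_query_safe <- function(track, chrom, breaks) {
  if (!chrom %in% names(track$chrom_sizes)) {
    spl_log("warn", "chromosome '", chrom,
            "' absent from track; row set to missing")
    return(rep(NA_real_, length(breaks) - 1L))
  }
  track_bin_query(track, chrom, breaks)
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix: %s @ %s, %d features x %d bins (%s anchor)\n",
              x$signal_label, x$feature_label, nrow(x$values),
              ncol(x$values), x$anchor$mode))
  invisible(x)
}

#' @export
dim.ProfileMatrix <- function(x) dim(x$values)

#' Rescale a per-base vector to a fixed number of body bins
#'
#' Partitions the index range into `body_bins` contiguous windows of
#' (possibly fractional) width `length(x)/body_bins`; each output value
#' is the length-weighted mean of the covered values, with missing bases
#' excluded from numerator and denominator.
#'
#' @param x numeric vector (NA allowed)
#' @param body_bins number of output bins
#' @return numeric vector of length `body_bins`
#' @export
scale_body <- function(x, body_bins) {
  stopifnot(length(x) >= 1, is_count(body_bins), body_bins >= 1)
  frac_bin_means(x, length(x) * (0:body_bins) / body_bins)
}

#' Export a profile matrix as TSV
#'
#' Rows are features, columns are bin offsets (bp relative to the
#' anchor); row names are the feature ids.
#'
#' @param matrix a `ProfileMatrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "ProfileMatrix"))
  df <- as.data.frame(matrix$values)
  colnames(df) <- format(matrix$bin_centers, trim = TRUE)
  df <- cbind(feature = matrix$feature_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
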