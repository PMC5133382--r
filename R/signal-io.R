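# Signal track ingestion. Wiggle (1-based), bedGraph (0-based half-open)
# and bigWig all land on identical internal per-base values; BAM is
# converted to coverage counting every aligned read's reference span (no
# MAPQ filter, no deduplication, no fragment extension). bigWig "no data"
# is NA internally, distinct from zero coverage.

#' Read a signal track file
#'
#' @param path track file (bigWig, wiggle fixedStep/variableStep,
#'   bedGraph, or BAM)
#' @param format `"bigwig"`, `"wig"`, `"bedgraph"`, `"bam"` or `"auto"`
#' @param chrom_sizes optional named vector of chromosome lengths; needed
#'   when the format carries none (wiggle/bedGraph default to the last
#'   covered base per chromosome)
#' @return a [signal_track()]
#' @export
read_signal <- function(path, format = "auto", chrom_sizes = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- detect_format(path, format, SIGNAL_FORMATS)
  if (format == "wig") format <- "wiggle"
  switch(format,
    bigwig = read_signal_granges(rtracklayer::import.bw(path), "bigwig", chrom_sizes),
    wiggle = read_signal_granges(rtracklayer::import(path, format = "wig"),
                                 "wiggle", chrom_sizes),
    bedgraph = read_signal_granges(rtracklayer::import(path, format = "bedGraph"),
                                   "bedgraph", chrom_sizes),
    bam = read_signal_bam(path))
}

read_signal_granges <- function(gr, source_format, chrom_sizes = NULL) {
  if (!GenomicRanges::isDisjoint(gr))
    stopf("%s track has overlapping intervals: signal value is ambiguous",
          source_format)
  sl <- GenomeInfoDb::seqlengths(gr)
  sizes <- chrom_sizes
  if (is.null(sizes)) {
    covered <- vapply(split(GenomicRanges::end(gr),
                            as.character(GenomicRanges::seqnames(gr))),
                      max, numeric(1))
    sizes <- covered
    known <- !is.na(sl[names(covered)])
    sizes[known] <- sl[names(covered)][known]
  }
  miss <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), names(sizes))
  if (length(miss) > 0)
    stopf("track data on chromosome(s) %s absent from chrom_sizes",
          paste(miss, collapse = ", "))
  values <- lapply(setNames(names(sizes), names(sizes)), function(ch) {
    v <- rep(NA_real_, sizes[[ch]])
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    if (any(sel)) {
      s <- GenomicRanges::start(gr)[sel]
      w <- GenomicRanges::width(gr)[sel]
      sc <- gr$score[sel]
      keep <- s <= sizes[[ch]]
      s <- s[keep]; w <- pmin(w[keep], sizes[[ch]] - s[keep] + 1L); sc <- sc[keep]
      v[sequence(w, from = s)] <- rep(sc, w)
    }
    v
  })
  signal_track(values, source_format)
}

read_signal_bam <- function(path) {
  # All aligned reads count: primaries, secondaries, duplicates, any MAPQ.
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  sizes <- GenomeInfoDb::seqlengths(ga)
  if (any(is.na(sizes))) stopf("BAM header lacks sequence lengths")
  cov <- GenomicRanges::coverage(GenomicRanges::granges(ga))
  values <- lapply(setNames(names(sizes), names(sizes)), function(ch) {
    as.numeric(cov[[ch]])
  })
  signal_track(values, "bam")
}

#' Write a track to indexed bigWig
#'
#' Non-missing runs are written with the track's chromosome sizes; the
#' result is a standard bigWig readable by third-party tools, and
#' re-reading it reproduces the original values (missing stays missing).
#'
#' @param track a [signal_track()]
#' @param out_path output `.bw` path
#' @return `out_path`, invisibly
#' @export
convert_to_indexed <- function(track, out_path) {
  stopifnot(inherits(track, "SignalTrack"))
  pieces <- lapply(names(track$chrom_sizes), function(ch) {
    r <- S4Vectors::Rle(track$values[[ch]])
    keep <- !is.na(S4Vectors::runValue(r))
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    GenomicRanges::GRanges(ch,
      IRanges::IRanges(starts[keep], ends[keep]),
      score = S4Vectors::runValue(r)[keep])
  })
  gr <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(gr) <- names(track$chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(track$chrom_sizes)
  rtracklayer::export.bw(gr, out_path)
  invisible(out_path)
}
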