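# Feature files (BED / GFF / GTF) are parsed through rtracklayer into a
# GRanges, the internal feature model. BED 0-based half-open and GFF/GTF
# 1-based inclusive coordinates both land on the same 1-based closed
# GRanges at parse time; exports back to BED/CSV re-emit 0-based starts.
# Row order is preserved exactly as read: row identity matters for
# heatmaps.

FEATURE_FORMATS <- c(bed = "bed", gff = "gff", gff3 = "gff", gtf = "gtf")
SIGNAL_FORMATS <- c(bw = "bigwig", bigwig = "bigwig", wig = "wiggle",
                    bdg = "bedgraph", bedgraph = "bedgraph", bam = "bam")

detect_format <- function(path, format, table) {
  if (!identical(format, "auto")) {
    format <- tolower(format)
    if (!format %in% table) stopf(
      "unsupported format '%s' (accepted: %s)", format,
      paste(unique(table), collapse = ", "))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% names(table)) stopf(
    "cannot infer format of '%s': extension '.%s' not recognized (accepted: %s)",
    basename(path), ext, paste(names(table), collapse = ", "))
  table[[ext]]
}

# Line-numbered validation before handing the file to rtracklayer, so a
# malformed record is reported by its line, which rtracklayer does not do.
validate_feature_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  min_cols <- if (format == "bed") 3L else 8L
  for (i in which(!skip)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (format == "bed" && length(f) == 1L)
      f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < min_cols)
      stopf("%s line %d: expected >= %d columns, found %d",
            format, i, min_cols, length(f))
    sc <- if (format == "bed") c(2L, 3L) else c(4L, 5L)
    st <- suppressWarnings(as.numeric(f[sc[1]]))
    en <- suppressWarnings(as.numeric(f[sc[2]]))
    if (is.na(st) || is.na(en))
      stopf("%s line %d: non-numeric coordinates '%s', '%s'",
            format, i, f[sc[1]], f[sc[2]])
    if (format == "bed" && st < 0)
      stopf("bed line %d: negative start %s", i, f[sc[1]])
    if (format != "bed" && st < 1)
      stopf("%s line %d: start %s below 1 (format is 1-based)", format, i, f[sc[1]])
    lo <- if (format == "bed") st else st - 1
    if (!(lo < en))
      stopf("%s line %d: empty or inverted interval [%s, %s]",
            format, i, f[sc[1]], f[sc[2]])
  }
  sum(!skip)
}

#' Read a genomic feature file
#'
#' Accepts BED (3-6 columns; 0-based half-open), GFF/GFF3 and GTF
#' (1-based inclusive; converted at parse time). Header/comment/track
#' lines are skipped; data row order is preserved. Malformed records
#' raise an error naming the offending line.
#'
#' @param path feature file
#' @param format `"bed"`, `"gff"`, `"gtf"`, or `"auto"` (by extension)
#' @param genome_label free-text genome version tag stored in metadata
#' @return a `GRanges` with a `name` column (empty string where the file
#'   has none); `S4Vectors::metadata()` carries `source_path` and
#'   `genome_label`
#' @export
read_features <- function(path, format = "auto", genome_label = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- detect_format(path, format, FEATURE_FORMATS)
  n_expected <- validate_feature_lines(path, format)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) != n_expected)
    stopf("parsed %d records but file has %d data lines", length(gr), n_expected)
  nm <- rep("", length(gr))
  for (col in c("name", "Name", "ID", "gene_id", "transcript_id")) {
    cand <- S4Vectors::mcols(gr)[[col]]
    if (!is.null(cand)) {
      cand <- as.character(cand)
      cand[is.na(cand) | cand == "."] <- ""
      fill <- nm == "" & cand != ""
      nm[fill] <- cand[fill]
    }
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm)
  S4Vectors::metadata(gr) <- list(source_path = path, genome_label = genome_label)
  gr
}

#' Write features as a 6-column BED file
#'
#' Starts are written 0-based half-open; empty names become the BED
#' placeholder `"."` and round-trip back to empty through
#' [read_features()].
#'
#' @param features a `GRanges` (a `name` column is used when present)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(features, path) {
  nm <- S4Vectors::mcols(features)$name %||% rep("", length(features))
  nm <- ifelse(is.na(nm) | nm == "", ".", nm)
  strand <- as.character(BiocGenerics::strand(features))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(features)),
    start = GenomicRanges::start(features) - 1L,
    end = GenomicRanges::end(features),
    name = nm, score = 0L, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Stable row labels for matrices: the name when present, else the locus.
feature_ids <- function(features) {
  nm <- S4Vectors::mcols(features)$name %||% rep("", length(features))
  loc <- sprintf("%s:%d-%d(%s)",
                 as.character(GenomicRanges::seqnames(features)),
                 GenomicRanges::start(features) - 1L,
                 GenomicRanges::end(features),
                 as.character(BiocGenerics::strand(features)))
  ifelse(is.na(nm) | nm == "", loc, nm)
}
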