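# In-memory coverage model. Values are per-base numeric vectors, one per
# chromosome, with NA marking "no data" (bigWig gaps) as distinct from an
# observed zero. All query coordinates on this object are 0-based
# half-open, matching the bigWig/BED convention.

#' Construct a signal track from per-base values
#'
#' @param values named list of numeric vectors, one per chromosome, with
#'   `NA` marking bases that carry no data (distinct from zero coverage)
#' @param source_format provenance tag: one of `"bigwig"`, `"wiggle"`,
#'   `"bedgraph"`, `"bam"`, `"motif"`, `"memory"`
#' @param build_summaries build multi-resolution binned summaries (power
#'   of two zoom factors), mirroring bigWig zoom levels
#' @return a `SignalTrack` object with fields `values`, `chrom_sizes`,
#'   `summary_levels`, `source_format`
#' @export
signal_track <- function(values, source_format = "memory",
                         build_summaries = TRUE) {
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stopf("`values` must be a named list of per-chromosome numeric vectors")
  values <- lapply(values, as.numeric)
  sizes <- vapply(values, length, integer(1))
  if (any(sizes == 0L)) stopf("zero-length chromosome in track")
  obj <- structure(
    list(values = values,
         chrom_sizes = sizes,
         summary_levels = NULL,
         source_format = source_format),
    class = "SignalTrack")
  if (build_summaries) obj$summary_levels <- build_summary_levels(values)
  obj
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack [%s]: %d chromosome(s), %s bp total\n",
              x$source_format, length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  for (ch in names(x$chrom_sizes)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %d bp, %.1f%% covered\n", ch, length(v),
                100 * mean(!is.na(v))))
  }
  invisible(x)
}

# Zoom levels at widths 2, 4, 8, ... < chromosome length. Each level keeps
# the sum of non-missing base values and the count of non-missing bases
# per block, so aggregation from levels is exact up to float association.
build_summary_levels <- function(values) {
  lapply(values, function(v) {
    L <- length(v)
    s <- ifelse(is.na(v), 0, v)
    n <- as.numeric(!is.na(v))
    levels <- list()
    width <- 1L
    while (width * 2L < L) {
      width <- width * 2L
      if (length(s) %% 2L == 1L) {
        s <- c(s, 0)
        n <- c(n, 0)
      }
      odd <- seq(1L, length(s), by = 2L)
      s <- s[odd] + s[odd + 1L]
      n <- n[odd] + n[odd + 1L]
      levels[[as.character(width)]] <- list(width = width, sum = s, n = n)
    }
    levels
  })
}

# Fetch per-base values over a 0-based half-open window, NA-padded where
# the window leaves the chromosome. Unknown chromosome gives all-NA plus a
# logged warning (feature files may name scaffolds a track lacks).
track_values <- function(track, chrom, from, to) {
  stopifnot(from < to)
  if (!chrom %in% names(track$chrom_sizes)) {
    spl_log("warn", "chromosome '", chrom, "' absent from track; ",
            "returning missing values")
    return(rep(NA_real_, to - from))
  }
  L <- track$chrom_sizes[[chrom]]
  out <- rep(NA_real_, to - from)
  lo <- max(from, 0L)
  hi <- min(to, L)
  if (lo < hi) out[(lo - from + 1L):(hi - from)] <- track$values[[chrom]][(lo + 1L):hi]
  out
}

# Length-weighted means over fractional windows of a per-base vector.
# `breaks` (relative, in [0, length(values)], non-decreasing) delimits the
# windows; a base overlapping a window boundary contributes with weight
# equal to the overlap length. Missing bases drop out of numerator and
# denominator; an all-missing window is NA.
frac_bin_means <- function(values, breaks) {
  L <- length(values)
  # unit-width integer bins are the raw per-base values, exactly
  if (all(breaks == floor(breaks)) && all(diff(breaks) == 1) &&
      breaks[1] >= 0 && breaks[length(breaks)] <= L)
    return(values[(breaks[1] + 1):breaks[length(breaks)]])
  v0 <- ifelse(is.na(values), 0, values)
  n0 <- as.numeric(!is.na(values))
  cs <- c(0, cumsum(v0))
  cn <- c(0, cumsum(n0))
  interp <- function(cum, per) {
    i <- floor(breaks)
    f <- breaks - i
    i <- pmin(pmax(i, 0), L)
    idx <- pmin(i + 1L, L)
    cum[i + 1L] + ifelse(f > 0 & i < L, f * per[idx], 0)
  }
  sums <- diff(interp(cs, v0))
  ns <- diff(interp(cn, n0))
  ifelse(ns > 0, sums / ns, NA_real_)
}

# Weighted means over fractional genomic windows given absolute 0-based
# breaks. This is the exact base-level path used by the matrix engine.
track_bin_query <- function(track, chrom, breaks) {
  lo <- floor(min(breaks))
  hi <- ceiling(max(breaks))
  v <- track_values(track, chrom, lo, hi)
  frac_bin_means(v, breaks - lo)
}

#' Query a track as fixed-count bins over a range
#'
#' Bins partition the 0-based half-open range `[start, end)` as evenly as
#' possible (fractional boundaries are resolved by length-weighted means).
#' Bases outside the chromosome or without data contribute as missing; a
#' bin that is entirely missing is `NA`.
#'
#' @param track a [signal_track()]
#' @param chrom chromosome name; an unknown chromosome yields all-`NA`
#'   bins with a logged warning, not an error
#' @param start,end 0-based half-open range, `start < end`
#' @param nbins number of bins (>= 1)
#' @param use_summary use the precomputed zoom levels: a bin is aggregated
#'   from the coarsest level whose block width is at most half the bin
#'   width, plus base-level edges; `FALSE` forces the base-level path. The
#'   two agree within 1e-6.
#' @return numeric vector of `nbins` bin means (with `NA` for missing)
#' @export
query_bins <- function(track, chrom, start, end, nbins, use_summary = TRUE) {
  stopifnot(inherits(track, "SignalTrack"))
  if (!is_count(nbins) || nbins < 1) stopf("`nbins` must be a positive integer")
  if (!(start < end)) stopf("`start` must be < `end`")
  breaks <- start + (end - start) * (0:nbins) / nbins
  if (!chrom %in% names(track$chrom_sizes)) {
    spl_log("warn", "chromosome '", chrom, "' absent from track; ",
            "returning missing values")
    return(rep(NA_real_, nbins))
  }
  if (!use_summary || is.null(track$summary_levels[[chrom]]))
    return(track_bin_query(track, chrom, breaks))
  vapply(seq_len(nbins), function(i) {
    summary_bin_value(track, chrom, breaks[i], breaks[i + 1L])
  }, numeric(1))
}

# One bin via zoom levels: whole blocks of the chosen level plus
# base-level fractional edges.
summary_bin_value <- function(track, chrom, a, b) {
  L <- track$chrom_sizes[[chrom]]
  a <- max(a, 0)
  b <- min(b, L)
  if (a >= b) return(NA_real_)
  levels <- track$summary_levels[[chrom]]
  widths <- vapply(levels, `[[`, numeric(1), "width")
  usable <- widths <= (b - a) / 2
  if (!any(usable)) {
    return(frac_bin_means(track_values(track, chrom, floor(a), ceiling(b)),
                          c(a, b) - floor(a)))
  }
  lev <- levels[[which(usable)[sum(usable)]]]
  w <- lev$width
  jlo <- ceiling(a / w)   # first fully-covered block index (0-based)
  jhi <- floor(b / w)     # one past the last fully-covered block
  s <- 0
  n <- 0
  if (jhi > jlo) {
    blocks <- (jlo + 1L):jhi
    s <- sum(lev$sum[blocks])
    n <- sum(lev$n[blocks])
  }
  edge <- function(x, y) {   # base-level [x, y) contribution
    if (x >= y) return(c(0, 0))
    v <- track_values(track, chrom, floor(x), ceiling(y))
    rel <- c(x, y) - floor(x)
    v0 <- ifelse(is.na(v), 0, v)
    n0 <- as.numeric(!is.na(v))
    cum <- function(per) {
      cs <- c(0, cumsum(per))
      i <- floor(rel); f <- rel - i
      i <- pmin(pmax(i, 0), length(v))
      idx <- pmin(i + 1L, length(v))
      cs[i + 1L] + ifelse(f > 0 & i < length(v), f * per[idx], 0)
    }
    c(diff(cum(v0)), diff(cum(n0)))
  }
  e1 <- edge(a, min(jlo * w, b))
  e2 <- edge(max(jhi * w, a), b)
  s <- s + e1[1] + e2[1]
  n <- n + e1[2] + e2[2]
  if (n > 0) s / n else NA_real_
}
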