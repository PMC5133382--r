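# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, direct window arithmetic, no reuse
# of package internals) so they check the package's fast paths from the
# outside.

# Length-weighted mean of per-base values over a fractional window
# [a, b), relative coordinates; NA bases drop out of both numerator and
# denominator.
naive_window_mean <- function(values, a, b) {
  num <- 0
  den <- 0
  for (base in floor(a):(ceiling(b) - 1)) {
    w <- min(b, base + 1) - max(a, base)
    if (w <= 0) next
    v <- if (base < 0 || base >= length(values)) NA else values[base + 1]
    if (!is.na(v)) {
      num <- num + w * v
      den <- den + w
    }
  }
  if (den > 0) num / den else NA_real_
}

# Naive equal-partition binning of [start, end) into nbins windows.
naive_query_bins <- function(per_base, start, end, nbins) {
  out <- numeric(nbins)
  for (i in seq_len(nbins)) {
    a <- start + (end - start) * (i - 1) / nbins
    b <- start + (end - start) * i / nbins
    out[i] <- naive_window_mean(per_base, a, b)
  }
  out
}

# Naive profile matrix: per feature, direct window arithmetic on the raw
# per-base chromosome vectors (values_list: named list, 0-based access
# via index+1). Point anchor modes only.
naive_point_matrix <- function(chroms, starts0, ends0, strands, values_list,
                               mode, upstream, downstream, bin,
                               ignore_strand = FALSE) {
  nup <- ceiling(upstream / bin)
  ndown <- ceiling(downstream / bin)
  nbins <- nup + ndown
  # offsets of bin edges from the anchor, in biological orientation
  edges <- c(-upstream, if (nup > 1) -bin * ((nup - 1):1), 0,
             if (ndown > 1) bin * (1:(ndown - 1)), downstream)
  edges <- edges[!duplicated(edges)]
  n <- length(chroms)
  out <- matrix(NA_real_, n, nbins)
  for (r in seq_len(n)) {
    minus <- strands[r] == "-" && !ignore_strand
    a <- switch(mode,
      start = if (minus) ends0[r] else starts0[r],
      end = if (minus) starts0[r] else ends0[r],
      center = floor((starts0[r] + ends0[r]) / 2))
    v <- values_list[[chroms[r]]]
    for (j in seq_len(nbins)) {
      lo_off <- edges[j]
      hi_off <- edges[j + 1]
      if (!minus) {
        out[r, j] <- naive_window_mean(v, a + lo_off, a + hi_off)
      } else {
        out[r, j] <- naive_window_mean(v, a - hi_off, a - lo_off)
      }
    }
  }
  out
}

# Naive IUPAC motif scan: nested loops over positions and pattern
# letters, with its own degeneracy table. N in the sequence matches
# nothing. Returns 0-based starts, with both-strand hits concatenated.
naive_scan <- function(sequence, pattern, both_strands) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  scan1 <- function(pat) {
    p <- strsplit(pat, "")[[1]]
    hits <- integer(0)
    for (s in 0:(length(seq_chars) - length(p))) {
      ok <- TRUE
      for (k in seq_along(p)) {
        ch <- seq_chars[s + k]
        if (ch == "N" || !(ch %in% tab[[p[k]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, s)
    }
    hits
  }
  hits <- scan1(pattern)
  if (both_strands) {
    rc <- paste(rev(unname(comp[strsplit(toupper(pattern), "")[[1]]])),
                collapse = "")
    hits <- c(hits, scan1(rc))
  }
  sort(hits)
}

# Brute-force motif density at one base (0-based i): match starts within
# the centered window, truncated at sequence ends.
naive_density_at <- function(starts0, L, i, window, per_kb) {
  h <- (window - 1) %/% 2
  lo <- max(0, i - h)
  hi <- min(L - 1, i + h)
  cnt <- sum(starts0 >= lo & starts0 <= hi)
  if (per_kb) cnt * 1000 / (hi - lo + 1) else cnt
}

# Small on-disk track writers for format-equivalence fixtures.
write_wig_fixed <- function(path, chrom, values, start1 = 1) {
  writeLines(c(sprintf("fixedStep chrom=%s start=%d step=1", chrom, start1),
               format(values, trim = TRUE, scientific = FALSE)), path)
}

write_bedgraph <- function(path, chrom, values, offset0 = 0) {
  # one line per run of equal values
  r <- rle(values)
  ends <- cumsum(r$lengths) + offset0
  starts <- ends - r$lengths
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%s", chrom, starts, ends,
                       format(r$values, trim = TRUE, scientific = FALSE))),
             path)
}

# A tiny SAM file (converted to BAM at test time) with given 0-based
# read starts and lengths, all perfect matches on the forward strand.
write_sam <- function(path, chrom, chrom_len, starts0, read_len = 50) {
  head <- c("@HD\tVN:1.6\tSO:coordinate",
            sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(seq_along(starts0), function(i) {
    sprintf("r%03d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*", i, chrom,
            starts0[i] + 1, read_len,
            paste(rep("A", read_len), collapse = ""))
  }, character(1))
  writeLines(c(head, body), path)
  path
}

random_track_values <- function(L, missing_frac = 0.1) {
  v <- round(stats::runif(L, 0, 10), 3)
  if (missing_frac > 0) v[sample.int(L, round(L * missing_frac))] <- NA
  v
}

expect_same_numeric <- function(x, y, tol = 1e-9) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
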