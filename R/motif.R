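# Genome-wide motif density tracks: an IUPAC pattern is scanned against
# the genome and the value at each base is the number of match starts in
# a centered window around it, optionally rescaled to occurrences per kb.
# The resulting SignalTrack is usable anywhere a file-based track is.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Specify a motif-density track
#'
#' @param pattern IUPAC nucleotide string (degenerate codes allowed)
#' @param window sliding-window width in bp, centered on each base; an
#'   even value is rounded up to the next odd so the window has a center
#'   (the default 200 becomes 201)
#' @param both_strands also count matches of the reverse complement,
#'   reported at the match's leftmost base. Palindromic patterns then
#'   count double — predictable, and documented.
#' @param per_kb report occurrences per kb (window counts scaled by
#'   1000/window) instead of raw per-window counts, so densities are
#'   comparable across window choices
#' @return a `MotifSpec` object
#' @export
motif_spec <- function(pattern, window = 200, both_strands = TRUE,
                       per_kb = TRUE) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) stopf("motif pattern is empty")
  bad <- setdiff(strsplit(pattern, "")[[1]], IUPAC_LETTERS)
  if (length(bad) > 0)
    stopf("invalid IUPAC letter(s) in pattern: %s", paste(bad, collapse = ", "))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window < nchar(pattern))
    stopf("window (%d) must be at least the pattern length (%d)",
          window, nchar(pattern))
  structure(list(pattern = pattern, window = window,
                 both_strands = both_strands, per_kb = per_kb),
            class = "MotifSpec")
}

#' Find motif occurrences in a sequence
#'
#' Matches under IUPAC degeneracy, with two deliberate rules: `N` in the
#' *sequence* matches nothing (including pattern `N`), so assembly gaps
#' never create phantom density; and with `both_strands` the reverse
#' complement's matches are reported at their leftmost base, so
#' palindromes are counted twice.
#'
#' @param sequence a `Biostrings::DNAString` or character (A/C/G/T/N)
#' @param spec a [motif_spec()]
#' @return sorted integer vector of 0-based match start positions
#'   (duplicated where both strands match at the same position)
#' @export
scan_occurrences <- function(sequence, spec) {
  stopifnot(inherits(spec, "MotifSpec"))
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  is_n <- integer(length(sequence))
  is_n[BiocGenerics::start(Biostrings::matchPattern("N", sequence,
                                                    fixed = TRUE))] <- 1L
  has_n <- c(0L, cumsum(is_n))
  scan_one <- function(pat) {
    m <- Biostrings::matchPattern(pat, sequence, fixed = "subject")
    s <- BiocGenerics::start(m)
    e <- BiocGenerics::end(m)
    s[has_n[e + 1L] - has_n[s] == 0]  # drop matches overlapping an N
  }
  starts <- scan_one(spec$pattern)
  if (spec$both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(spec$pattern)))
    starts <- c(starts, scan_one(rc))
  }
  sort(starts) - 1L
}

#' Build a genome-wide motif density track
#'
#' The value at base `i` is the number of match starts within the
#' `window`-wide window centered on `i`; windows truncated at chromosome
#' ends use the truncated width as denominator when `per_kb` scaling is
#' on. Output is invariant to FASTA line wrapping.
#'
#' @param genome path to a FASTA file, or a `Biostrings::DNAStringSet`
#' @param spec a [motif_spec()]
#' @return a [signal_track()] with `source_format = "motif"`
#' @export
build_motif_track <- function(genome, spec) {
  stopifnot(inherits(spec, "MotifSpec"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (length(genome) == 0) stopf("empty genome")
  names(genome) <- sub("\\s.*$", "", names(genome))
  h <- (spec$window - 1L) %/% 2L
  values <- lapply(setNames(seq_along(genome), names(genome)), function(k) {
    seq_k <- genome[[k]]
    L <- length(seq_k)
    starts <- scan_occurrences(seq_k, spec)
    cnt <- tabulate(starts + 1L, nbins = L)
    cs <- c(0, cumsum(cnt))
    i <- 0:(L - 1L)
    lo <- pmax(0L, i - h)
    hi <- pmin(L - 1L, i + h)
    wins <- cs[hi + 2L] - cs[lo + 1L]
    if (spec$per_kb) wins * (1000 / (hi - lo + 1L)) else as.numeric(wins)
  })
  signal_track(values, "motif")
}
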