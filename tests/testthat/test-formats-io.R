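# Feature and signal file parsing into the unified internal model.

test_that("BED parses 0-based half-open with order, names and strand kept", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=demo",
               "# a comment",
               "chrI\t100\t200\tgeneA\t0\t+",
               "chrI\t500\t900\tgeneB\t0\t-",
               "chrII\t0\t50\t.\t0\t."), bed)
  gr <- read_features(bed)
  expect_length(gr, 3)
  expect_equal(GenomicRanges::start(gr)[1] - 1L, 100L)  # back to 0-based
  expect_equal(GenomicRanges::end(gr)[1], 200L)
  expect_equal(gr$name, c("geneA", "geneB", ""))
  expect_equal(as.character(BiocGenerics::strand(gr)), c("+", "-", "*"))
  expect_equal(as.character(GenomicRanges::seqnames(gr)),
               c("chrI", "chrI", "chrII"))
})

test_that("GFF 1-based inclusive coordinates convert to the same model", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\tgene\t101\t200\t.\t-\t.\tID=g1"), gff)
  gr <- read_features(gff)
  # 1-based [101, 200] is 0-based half-open [100, 200)
  expect_equal(GenomicRanges::start(gr) - 1L, 100L)
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(as.character(BiocGenerics::strand(gr)), "-")
  expect_equal(gr$name, "g1")
})

test_that("malformed feature lines are reported by line number", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t200", "chrI\tfoo\t300"), bed)
  expect_error(read_features(bed), "line 2")
  writeLines(c("chrI\t100\t200", "chrI\t-5\t300"), bed)
  expect_error(read_features(bed), "line 2.*negative")
  noext <- tempfile(fileext = ".xyz")
  file.create(noext)
  expect_error(read_features(noext), "bed")
})

test_that("BED round trip preserves a FeatureSet exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:30, 1)
    starts0 <- sample(0:5000, n)
    widths <- sample(1:500, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(
      sample(c("chrI", "chrII", "scaffold_7"), n, replace = TRUE),
      IRanges::IRanges(starts0 + 1L, starts0 + widths),
      strand = sample(c("+", "-", "*"), n, replace = TRUE),
      name = ifelse(stats::runif(n) < 0.3, "",
                    sprintf("feat%03d", seq_len(n))))
    bed <- tempfile(fileext = ".bed")
    write_bed(gr, bed)
    back <- read_features(bed)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
    expect_equal(as.character(GenomicRanges::seqnames(back)),
                 as.character(GenomicRanges::seqnames(gr)))
    expect_equal(as.character(BiocGenerics::strand(back)),
                 as.character(BiocGenerics::strand(gr)))
    expect_equal(back$name, gr$name)
  }
})

test_that("wiggle fixedStep lands on exact per-base values", {
  wig <- tempfile(fileext = ".wig")
  write_wig_fixed(wig, "chrI", c(1, 2, 3))
  tr <- read_signal(wig)
  expect_equal(query_bins(tr, "chrI", 0, 3, 3), c(1, 2, 3))
})

test_that("bedGraph is 0-based half-open and beyond-data bases are missing", {
  bdg <- tempfile(fileext = ".bdg")
  writeLines(c("chrI\t0\t10\t4.0"), bdg)
  tr <- read_signal(bdg, chrom_sizes = c(chrI = 20))
  expect_equal(query_bins(tr, "chrI", 0, 10, 10), rep(4, 10))
  expect_true(is.na(query_bins(tr, "chrI", 10, 11, 1)))
})

test_that("overlapping bedGraph intervals are rejected as ambiguous", {
  bdg <- tempfile(fileext = ".bdg")
  writeLines(c("chrI\t0\t10\t4.0", "chrI\t5\t15\t2.0"), bdg)
  expect_error(read_signal(bdg), "overlap")
})

test_that("identical coverage via wiggle and bedGraph gives identical values", {
  set.seed(7)
  v <- round(stats::runif(200, 0, 5), 3)
  wig <- tempfile(fileext = ".wig")
  bdg <- tempfile(fileext = ".bdg")
  write_wig_fixed(wig, "chrI", v)
  write_bedgraph(bdg, "chrI", v)
  t1 <- read_signal(wig)
  t2 <- read_signal(bdg)
  expect_equal(query_bins(t1, "chrI", 0, 200, 200),
               query_bins(t2, "chrI", 0, 200, 200), tolerance = 1e-6)
})

test_that("BAM coverage counts every aligned read's reference span", {
  sam <- write_sam(tempfile(fileext = ".sam"), "chrI", 1000,
                   starts0 = c(100, 110), read_len = 50)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  tr <- read_signal(bam, format = "bam")
  # base 120 is covered by both reads ([100,150) and [110,160))
  expect_equal(query_bins(tr, "chrI", 120, 121, 1), 2)
  expect_equal(query_bins(tr, "chrI", 105, 106, 1), 1)
  expect_equal(query_bins(tr, "chrI", 500, 501, 1), 0)  # zero, not missing
  expect_equal(tr$chrom_sizes[["chrI"]], 1000)
})

test_that("bigWig conversion round-trips values, missing runs and sizes", {
  wig <- tempfile(fileext = ".wig")
  write_wig_fixed(wig, "chrI", c(1, 2, 3))
  tr <- read_signal(wig)
  bw <- tempfile(fileext = ".bw")
  convert_to_indexed(tr, bw)
  expect_equal(query_bins(read_signal(bw), "chrI", 0, 3, 3), c(1, 2, 3))

  # seeded random 10 kb track with missing gaps, two chromosomes
  set.seed(11)
  vals <- list(chrI = random_track_values(10000),
               chrII = random_track_values(3000))
  tr2 <- signal_track(vals)
  bw2 <- tempfile(fileext = ".bw")
  convert_to_indexed(tr2, bw2)
  back <- read_signal(bw2)
  expect_equal(back$chrom_sizes, tr2$chrom_sizes)
  for (ch in names(vals)) {
    a <- tr2$values[[ch]]
    b <- back$values[[ch]]
    expect_equal(is.na(a), is.na(b))
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-6)
  }
})

test_that("query_bins matches naive per-base binning on fractional bins", {
  expect_equal(query_bins(signal_track(list(chrI = rep(5, 100))),
                          "chrI", 13, 77, 7), rep(5, 7))
  tr <- signal_track(list(chrI = c(1, 2, 3, 4)))
  expect_equal(query_bins(tr, "chrI", 0, 4, 2), c(1.5, 3.5))
  # fractional boundaries: 3 bases into 2 bins; the middle base is split
  # half/half, so each window is a length-weighted mean over 1.5 bases
  expect_equal(query_bins(tr, "chrI", 0, 3, 2), c(2 / 1.5, 4 / 1.5))
  set.seed(3)
  v <- random_track_values(500)
  tr <- signal_track(list(chrI = v))
  for (i in 1:20) {
    start <- sample(0:400, 1)
    end <- start + sample(5:100, 1)
    nbins <- sample(1:13, 1)
    expect_same_numeric(query_bins(tr, "chrI", start, end, nbins,
                                   use_summary = FALSE),
                        naive_query_bins(v, start, end, nbins))
  }
})

test_that("bins beyond the chromosome end are missing, not zero", {
  tr <- signal_track(list(chrI = rep(2, 100)))
  v <- query_bins(tr, "chrI", 80, 130, 5)
  expect_equal(v[1:2], c(2, 2))
  expect_true(all(is.na(v[4:5])))     # bins fully past the end
  expect_true(is.na(query_bins(tr, "chrI", 200, 250, 1)))
})

test_that("unknown chromosome yields missing bins and a warning, not an error", {
  tr <- signal_track(list(chrI = rep(1, 50)))
  withr::local_options(metaprofiler.log_level = "warn")
  expect_message(v <- query_bins(tr, "scaffold_99", 0, 10, 2), "absent")
  expect_true(all(is.na(v)))
})

test_that("query_bins with nbins = end-start returns raw per-base values", {
  set.seed(5)
  v <- random_track_values(64, missing_frac = 0.2)
  tr <- signal_track(list(chrI = v))
  expect_identical(query_bins(tr, "chrI", 0, 64, 64, use_summary = FALSE),
                   v)
})

test_that("summary-level queries agree with base-level within 1e-6", {
  set.seed(9)
  v <- random_track_values(5000, missing_frac = 0.15)
  tr <- signal_track(list(chrI = v))
  for (i in 1:200) {
    start <- sample(0:4000, 1)
    end <- start + sample(20:900, 1)
    nbins <- sample(1:25, 1)
    a <- query_bins(tr, "chrI", start, end, nbins, use_summary = TRUE)
    b <- query_bins(tr, "chrI", start, end, nbins, use_summary = FALSE)
    expect_equal(is.na(a), is.na(b))
    if (any(!is.na(a)))
      expect_lt(max(abs(a - b), na.rm = TRUE), 1e-6)
  }
})
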