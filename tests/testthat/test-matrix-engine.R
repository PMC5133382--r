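# The core computation: anchoring, binned matrices, body scaling.

make_gr <- function(chrom, start0, end0, strand = "+", name = "") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand, name = name)
}

test_that("anchor points respect strand and the floor-midpoint convention", {
  expect_equal(anchor_point(make_gr("chrI", 100, 200, "+"), "start"), 100)
  expect_equal(anchor_point(make_gr("chrI", 100, 200, "-"), "start"), 200)
  expect_equal(anchor_point(make_gr("chrI", 100, 200, "+"), "end"), 200)
  expect_equal(anchor_point(make_gr("chrI", 100, 200, "-"), "end"), 100)
  expect_equal(anchor_point(make_gr("chrI", 100, 201, "+"), "center"), 150)
  expect_equal(anchor_point(make_gr("chrI", 100, 201, "-"), "center"), 150)
  expect_equal(anchor_point(make_gr("chrI", 100, 200, "-"), "start",
                            ignore_strand = TRUE), 100)
  # floor-midpoint checked against brute force over parity cases
  for (s0 in 100:103) for (e0 in 151:154) {
    expect_equal(anchor_point(make_gr("chrI", s0, e0), "center"),
                 floor((s0 + e0) / 2))
  }
})

test_that("the 1 kb / 1.5 kb / 10 bp window yields 250 bins at -995..1495", {
  a <- anchor_spec("start", upstream = 1000, downstream = 1500, bin = 10)
  tr <- signal_track(list(chrI = rep(1, 10000)))
  m <- compute_matrix(make_gr("chrI", 5000, 5400), tr, a)
  expect_equal(ncol(m$values), 250)
  expect_equal(m$bin_centers[1], -995)
  expect_equal(m$bin_centers[250], 1495)
  expect_true(all(m$values == 1))
})

test_that("bin-count formula holds across parameter combinations", {
  tr <- signal_track(list(chrI = rep(0, 4000)), build_summaries = FALSE)
  gr <- make_gr("chrI", 2000, 2100)
  set.seed(8)
  for (i in 1:25) {
    up <- sample(0:300, 1)
    down <- sample(0:300, 1)
    if (up + down == 0) up <- 7
    bin <- sample(1:40, 1)
    a <- anchor_spec(sample(c("start", "end", "center"), 1), up, down, bin)
    m <- compute_matrix(gr, tr, a)
    expect_equal(ncol(m$values), ceiling(up / bin) + ceiling(down / bin))
  }
  bb <- sample(1:30, 1)
  a <- anchor_spec("scaled", 95, 130, bin = 10, body_bins = bb)
  expect_equal(ncol(compute_matrix(gr, tr, a)$values),
               ceiling(95 / 10) + bb + ceiling(130 / 10))
})

test_that("constant tracks give constant matrices in every mode", {
  tr <- signal_track(list(chrI = rep(3.5, 6000)))
  gr <- c(make_gr("chrI", 2000, 2400, "+"),
          make_gr("chrI", 3000, 3700, "-"))
  for (mode in c("start", "end", "center", "scaled")) {
    a <- anchor_spec(mode, 500, 700, bin = 25, body_bins = 13)
    m <- compute_matrix(gr, tr, a)
    expect_equal(max(abs(m$values - 3.5)), 0, tolerance = 1e-12,
                 info = mode)
  }
})

test_that("a ramp track makes mirrored +/- rows exact reverses", {
  L <- 4000
  ramp <- seq_len(L)
  tr <- signal_track(list(chrI = ramp))
  # mirrored positions: minus feature where the plus one sits reflected
  plus <- make_gr("chrI", 1000, 1200, "+")
  minus <- make_gr("chrI", L - 1200, L - 1000, "-")
  a <- anchor_spec("start", 300, 500, bin = 10)
  m <- compute_matrix(c(plus, minus), tr, a)
  # reflecting the genome maps base x to L-1-x with value L-x: in genomic
  # reading the minus row is the reverse of the plus row, so after the
  # engine's strand flip the columns line up under the value relabelling
  # v -> L+1-v
  expect_equal(m$values[2, ], L + 1 - m$values[1, ])
})

test_that("ignore_strand makes +/- copies of an interval identical", {
  set.seed(14)
  tr <- signal_track(list(chrI = random_track_values(3000)))
  gr <- c(make_gr("chrI", 1500, 1700, "+"), make_gr("chrI", 1500, 1700, "-"))
  for (mode in c("start", "end", "center", "scaled")) {
    a <- anchor_spec(mode, 200, 300, bin = 7, body_bins = 9,
                     ignore_strand = TRUE)
    m <- compute_matrix(gr, tr, a)
    expect_equal(m$values[1, ], m$values[2, ], info = mode)
  }
})

test_that("point-mode matrices equal the naive per-base reference", {
  set.seed(101)
  for (rep in 1:30) {
    L <- sample(300:800, 1)
    values <- list(chrA = random_track_values(L, missing_frac = 0.1),
                   chrB = random_track_values(L))
    tr <- signal_track(values, build_summaries = FALSE)
    n <- sample(1:8, 1)
    chroms <- sample(names(values), n, replace = TRUE)
    starts0 <- sample(0:(L - 60), n, replace = TRUE)
    ends0 <- starts0 + sample(10:50, n, replace = TRUE)
    strands <- sample(c("+", "-", "*"), n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chroms,
                                 IRanges::IRanges(starts0 + 1, ends0),
                                 strand = strands)
    mode <- sample(c("start", "end", "center"), 1)
    up <- sample(0:120, 1)
    down <- sample(0:120, 1)
    if (up + down == 0) up <- 30
    bin <- sample(1:17, 1)
    ignore <- sample(c(TRUE, FALSE), 1)
    a <- anchor_spec(mode, up, down, bin, ignore_strand = ignore)
    got <- compute_matrix(gr, tr, a)$values
    want <- naive_point_matrix(chroms, starts0, ends0,
                               ifelse(strands == "*", ".", strands),
                               values, mode, up, down, bin, ignore)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("scaled mode matches a naive flank + stretched-body reference", {
  set.seed(55)
  L <- 1000
  v <- random_track_values(L, missing_frac = 0.05)
  tr <- signal_track(list(chrI = v), build_summaries = FALSE)
  for (rep in 1:10) {
    s0 <- sample(200:400, 1)
    e0 <- s0 + sample(30:300, 1)
    strand <- sample(c("+", "-"), 1)
    gr <- make_gr("chrI", s0, e0, strand)
    bb <- sample(2:12, 1)
    a <- anchor_spec("scaled", 100, 60, bin = 10, body_bins = bb)
    got <- compute_matrix(gr, tr, a)$values[1, ]
    flank_up <- naive_query_bins(v, s0 - 100, s0, 10)
    body <- naive_query_bins(v, s0, e0, bb)
    flank_down <- naive_query_bins(v, e0, e0 + 60, 6)
    want <- c(flank_up, body, flank_down)
    if (strand == "-") {
      flank_up_m <- naive_query_bins(v, e0, e0 + 100, 10)
      body_m <- naive_query_bins(v, s0, e0, bb)
      flank_down_m <- naive_query_bins(v, s0 - 60, s0, 6)
      want <- c(rev(flank_up_m), rev(body_m), rev(flank_down_m))
    }
    expect_equal(got, want, tolerance = 1e-9, info = strand)
  }
})

test_that("windows past chromosome edges are missing, and unknown
           chromosomes give all-missing rows with a warning", {
  tr <- signal_track(list(chrI = rep(1, 300)))
  a <- anchor_spec("start", 100, 100, bin = 50)
  m1 <- compute_matrix(make_gr("chrI", 20, 60), tr, a)
  expect_true(is.na(m1$values[1, 1]))       # fully upstream of base 0
  expect_equal(m1$values[1, 3:4], c(1, 1))
  expect_message(
    m2 <- compute_matrix(make_gr("chrZ", 100, 150), tr, a), "absent")
  expect_true(all(is.na(m2$values)))
})

test_that("scale_body computes length-weighted means with missing handling", {
  expect_equal(scale_body(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(scale_body(7, 3), c(7, 7, 7))
  # fractional windows of 1.5 bases: weighted means, not interpolation
  expect_equal(scale_body(c(1, 2, 3), 2), c(2 / 1.5, 4 / 1.5))
  expect_equal(scale_body(c(NA, 5), 2), c(NA, 5))
  expect_true(all(is.na(scale_body(c(NA, NA), 3))))
  # weighted-mean oracle on random vectors
  set.seed(6)
  for (i in 1:10) {
    v <- random_track_values(sample(3:40, 1), missing_frac = 0.2)
    b <- sample(1:9, 1)
    expect_same_numeric(scale_body(v, b), naive_query_bins(v, 0, length(v), b))
  }
})

test_that("matrix TSV export has one row per feature and labelled offsets", {
  tr <- signal_track(list(chrI = rep(2, 1000)))
  gr <- c(make_gr("chrI", 400, 420, "+", "f1"),
          make_gr("chrI", 600, 640, "-", "f2"))
  m <- compute_matrix(gr, tr, anchor_spec("start", 50, 50, bin = 25))
  tsv <- tempfile(fileext = ".tsv")
  export_matrix_tsv(m, tsv)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          check.names = FALSE)
  expect_equal(nrow(df), 2)
  expect_equal(df$feature, c("f1", "f2"))
  expect_equal(ncol(df), 1 + 4)
})
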