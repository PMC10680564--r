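test_that("BED3 fragments parse with coordinate conversion and validation", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t161", "chr1\t0\t51"), bed)
  suppressMessages(fr <- read_fragments(bed))
  expect_equal(length(fr), 2L)
  expect_equal(GenomicRanges::start(fr), c(101L, 1L))
  expect_equal(GenomicRanges::end(fr), c(161L, 51L))
  expect_equal(GenomicRanges::width(fr)[1], 61L)
  expect_equal(fragment_midpoints(fr)[1], 131L)  # 0-based 130

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  suppressMessages(fr0 <- read_fragments(empty))
  expect_equal(length(fr0), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t161", "chr1\t200\t150"), bad)
  expect_error(suppressMessages(read_fragments(bad)), "line 2")
})

test_that("BEDPE and SAM inputs yield the same inferred inserts", {
  pe <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t150\tchr1\t111\t161\tfragA\t0\t+\t-"), pe)
  suppressMessages(fr <- read_fragments(pe))
  expect_equal(GenomicRanges::start(fr), 101L)
  expect_equal(GenomicRanges::end(fr), 161L)

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", "99", "chr1", "101", "60", "50M", "=", "112", "61",
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r1", "147", "chr1", "112", "60", "50M", "=", "101", "-61",
          paste(rep("A", 50), collapse = ""), "*", sep = "\t")),
    sam)
  suppressMessages(frs <- read_fragments(sam))
  expect_equal(length(frs), 1L)
  expect_equal(GenomicRanges::start(frs), 101L)
  expect_equal(GenomicRanges::width(frs), 61L)

  expect_error(
    suppressMessages(read_fragments(pe, seqlens = c(chrX = 1000L))),
    "chr1")
})

test_that("depth tracks honor size selection, modes, and mass conservation", {
  fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 161))
  lens <- c(chr1 = 500L)
  full <- depth_track(fr, c(51, 100), "full_extent", lens)
  expect_equal(full$data$chr1[101:161], rep(1, 61))
  expect_equal(sum(full$data$chr1), 61)

  mid <- depth_track(fr, c(51, 100), "midpoint", lens)
  expect_equal(which(mid$data$chr1 != 0), 131L)
  expect_equal(mid$data$chr1[131], 1)

  short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 145))  # 45 bp
  expect_equal(sum(depth_track(short, c(46, 56), "full_extent",
                               lens)$data$chr1), 0)

  # mass conservation + additivity on a random set
  set.seed(7)
  n <- 300
  s <- sample.int(400, n, replace = TRUE)
  w <- sample(40:110, n, replace = TRUE)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, width = w))
  lens2 <- c(chr1 = 600L)
  kept <- sum(w >= 51 & w <= 100)
  expect_equal(sum(depth_track(gr, c(51, 100), "midpoint",
                               lens2)$data$chr1), kept)
  a <- gr[seq_len(150)]
  b <- gr[151:300]
  ta <- depth_track(a, c(51, 100), "full_extent", lens2)$data$chr1
  tb <- depth_track(b, c(51, 100), "full_extent", lens2)$data$chr1
  tab <- depth_track(gr, c(51, 100), "full_extent", lens2)$data$chr1
  expect_equal(ta + tb, tab)

  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(580, 640))
  expect_error(depth_track(far, c(51, 100), "full_extent", lens2),
               "past chromosome end")
})

test_that("smoothing is a truncated centered mean that preserves mass", {
  const <- signal_track(list(c1 = rep(3.5, 100)), "external")
  for (w in c(1, 4, 10, 51))
    expect_equal(smooth_track(const, w)$data$c1, rep(3.5, 100))

  x <- numeric(200)
  x[100] <- 11
  tr <- signal_track(list(c1 = x), "external")
  sm <- smooth_track(tr, 10)$data$c1
  expect_equal(sm[95:105], rep(1, 11))
  expect_equal(sum(sm != 0), 11L)
  expect_equal(sum(sm), 11)  # mass preserved away from edges

  # delta near the chromosome start: windows truncate, means renormalize
  y <- numeric(50)
  y[3] <- 11
  smy <- smooth_track(signal_track(list(c1 = y), "external"), 10)$data$c1
  expect_equal(smy[1], 11 / 6)  # positions 1..6 available
  expect_equal(smy[2], 11 / 7)
  expect_equal(smy[8], 11 / 11)

  expect_error(smooth_track(tr, 0), "positive")
})

test_that("bedGraph round trip is the identity and overlaps are rejected", {
  set.seed(11)
  x <- ifelse(runif(400) < 0.3, 0, runif(400) * 7)
  tr <- signal_track(list(chr1 = x, chr2 = numeric(50)), "external")
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, c(chr1 = 400L, chr2 = 50L))
  expect_identical(back$data$chr1, x)   # bitwise
  expect_identical(back$data$chr2, numeric(50))

  # a constant run collapses to a single line
  tr2 <- signal_track(list(chr1 = c(numeric(100), rep(1, 61),
                                    numeric(39))), "external")
  p2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr2, p2)
  expect_equal(readLines(p2), "chr1\t100\t161\t1")

  bad <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t1.0", "chr1\t50\t150\t2.0"), bad)
  expect_error(read_bedgraph(bad, c(chr1 = 400L)), "overlap")
})

test_that("chrom.sizes round trips through the reader", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrI\t230218", "chrII\t813184"), p)
  expect_equal(read_chrom_sizes(p), c(chrI = 230218L, chrII = 813184L))
})
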