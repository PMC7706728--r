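test_that("read_sequences slices, strand-flips and bounds-checks intervals", {
  genome <- Biostrings::DNAStringSet(c(chrI = "ACGTA", chrII = "TTTTTTTTTT"))
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(genome, fa)

  gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 4))
  expect_equal(as.character(read_sequences(genome, gr))[[1]], "ACGT")
  expect_equal(as.character(read_sequences(fa, gr))[[1]], "ACGT")

  # [1,5) 0-based = "CGTA"; minus strand with flip -> reverse complement
  grm <- GenomicRanges::GRanges("chrI", IRanges::IRanges(2, 5), strand = "-")
  expect_equal(as.character(read_sequences(genome, grm))[[1]], "TACG")
  expect_equal(as.character(read_sequences(genome, grm, flip_minus = FALSE))[[1]],
               "CGTA")

  # sequence length always equals interval width
  set.seed(1)
  rand <- GenomicRanges::GRanges("chrII",
    IRanges::IRanges(start = sample(1:5, 10, TRUE), width = sample(1:5, 10, TRUE)))
  expect_equal(Biostrings::width(read_sequences(genome, rand)),
               IRanges::width(rand))

  oob <- GenomicRanges::GRanges("chrI", IRanges::IRanges(4, 10))
  expect_error(read_sequences(genome, oob), "chrI:3-10")
  expect_error(read_sequences(fa, oob), "chrI:3-10")
  expect_error(
    read_sequences(genome, GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 2))),
    "unknown chromosome")
})

test_that("read_fragments parses BEDPE, conserves counts and filters lengths", {
  bedpe <- tempfile(fileext = ".bedpe")
  # fragment [100,200): length 100, midpoint 150
  writeLines(c("chrS\t100\t150\tchrS\t150\t200",
               "chrS\t500\t550\tchrS\t750\t800",   # length 300 -> filtered
               "chrS\t40\t80\tchrS\t50\t90"),      # length 50
             bedpe)
  frags <- suppressMessages(read_fragments(bedpe, length_range = c(30, 250)))
  expect_equal(length(frags), 2L)
  expect_equal(IRanges::width(frags)[1], 100L)
  expect_equal(fragment_midpoints(frags)[1], 150L)

  # n in-range synthetic records -> exactly n fragments
  set.seed(42)
  n <- 50
  s0 <- sample(1000:2000, n)
  len <- sample(30:250, n, replace = TRUE)
  r <- pmin(50, len)
  df <- data.frame("chrS", s0, s0 + r, "chrS", s0 + len - r, s0 + len)
  bedpe2 <- tempfile(fileext = ".bedpe")
  write.table(df, bedpe2, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  frags2 <- suppressMessages(read_fragments(bedpe2))
  expect_equal(length(frags2), n)
  expect_equal(sort(IRanges::width(frags2)), sort(len))

  expect_warning(
    suppressMessages(read_fragments(bedpe, length_range = c(998, 999))),
    "zero fragments")
})

test_that("read_fragments extracts one fragment per BAM proper pair", {
  sam <- tempfile(fileext = ".sam")
  # 3 proper pairs + 1 non-proper pair; fragment spans [pos-1, pos-1+TLEN)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrS\tLN:10000",
    "r1\t99\tchrS\t101\t60\t50M\t=\t151\t100\t*\t*",
    "r1\t147\tchrS\t151\t60\t50M\t=\t101\t-100\t*\t*",
    "r2\t99\tchrS\t201\t60\t50M\t=\t231\t80\t*\t*",
    "r2\t147\tchrS\t231\t60\t50M\t=\t201\t-80\t*\t*",
    "r3\t99\tchrS\t301\t60\t50M\t=\t391\t140\t*\t*",
    "r3\t147\tchrS\t391\t60\t50M\t=\t301\t-140\t*\t*",
    "r4\t97\tchrS\t401\t60\t50M\t=\t501\t150\t*\t*",
    "r4\t145\tchrS\t501\t60\t50M\t=\t401\t-150\t*\t*")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)

  # oracle: independent walk over SAM records, counting proper-pair flags
  flags <- as.integer(sub("^\\S+\t(\\d+)\t.*", "\\1", lines[-(1:2)]))
  n_expected <- sum(bitwAnd(flags, 2L) > 0 & bitwAnd(flags, 16L) == 0) # fwd mates
  frags <- suppressMessages(read_fragments(bam, length_range = c(1, 1000)))
  expect_equal(length(frags), n_expected)
  expect_equal(sort(IRanges::width(frags)), c(80L, 100L, 140L))
  expect_equal(IRanges::start(frags)[1] - 1L, 100L)  # 0-based start
})

test_that("signal tracks round-trip through bedGraph and bigWig", {
  tr <- signal_track("chrS", 100L, c(0.25, 1.5, -0.75), step = 10L)
  bg <- tempfile(fileext = ".bedgraph")
  write_track(tr, bg)
  expect_equal(length(readLines(bg)), 3L)
  back <- read_track(bg)
  expect_equal(back$score, tr$score, tolerance = 1e-6)
  expect_equal(IRanges::start(back), IRanges::start(tr))

  bw <- tempfile(fileext = ".bw")
  write_track(tr, bw)
  back2 <- read_track(bw)
  expect_equal(back2$score, tr$score, tolerance = 1e-6)

  # empty track: empty bedGraph without header; bigWig refused
  empty <- GenomicRanges::GRanges()
  bg0 <- tempfile(fileext = ".bedgraph")
  write_track(empty, bg0)
  expect_identical(readLines(bg0), character(0))
  expect_error(write_track(empty, tempfile(fileext = ".bw")), "empty bigWig")

  expect_error(suppressWarnings(
    write_track(tr, file.path(tempdir(), "no_dir_here", "x.bedgraph"))))
})

test_that("track_values returns per-base scores with zero fill", {
  tr <- signal_track("chrS", 10L, c(1, 2, 3))
  expect_equal(track_values(tr, "chrS", c(9, 10, 11, 12, 13)),
               c(0, 1, 2, 3, 0))
  expect_equal(track_values(tr, "chrX", 10:12), c(0, 0, 0))
})

test_that("promoter tables are validated on read", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chrS", start = 900, end = 1100, strand = "+",
                   center = 1000, tss_fwd = 1030, tss_rev = 970,
                   class = "ubiquitous")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_promoters(tsv)
  expect_equal(back$tss_fwd, 1030)

  bad <- df; bad$tss_rev <- 1050
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_promoters(tsv), "tss_rev < tss_fwd")
})
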