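test_that("read_peaks parses narrowPeak fields and skips headers", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "track name=peaks",
    "chr1\t1000\t1600\tp1\t100\t.\t5.2\t8.1\t6.3\t300",
    "chr2\t50\t250\tp2\t90\t.\t4.0\t7.0\t5.5\t100"), path)
  pk <- read_peaks(path)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$chrom, c("chr1", "chr2"))
  expect_equal(pk$start, c(1000L, 50L))
  expect_equal(pk$end, c(1600L, 250L))
  expect_equal(pk$neglog10_qval, c(6.3, 5.5))
  expect_equal(pk$summit_offset, c(300L, 100L))
})

test_that("read_peaks handles BED3 with absent optional fields", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t5\t100", path)
  pk <- read_peaks(path)
  expect_equal(pk$start, 5L)
  expect_true(is.na(pk$neglog10_qval))
  expect_true(is.na(pk$summit_offset))
})

test_that("read_peaks rejects malformed intervals naming the line", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t100", "chr1\t200\t200"), path)
  expect_error(read_peaks(path), "line 2")
  writeLines(c("track x", "chr1\t100\t50"), path)
  expect_error(read_peaks(path), "line 2")
})

test_that("fragments BED dialect: region filter, duplicates, variants", {
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "chrA\t100\t250\tBC1\t0\t110:G",
    "chrA\t300\t400\t.\t1\t.",
    "chrB\t100\t200\t.\t0\t."), path)
  f <- read_fragments(path)
  expect_equal(nrow(f), 2)            # duplicate dropped by default
  expect_equal(f$variants[1], "110:G")
  expect_equal(f$barcode[1], "BC1")
  f2 <- read_fragments(path, keep_duplicates = TRUE)
  expect_equal(nrow(f2), 3)
  expect_true(any(f2$is_duplicate))
  f3 <- read_fragments(path, region = list(chrom = "chrA", start = 0L,
                                           end = 260L))
  expect_equal(nrow(f3), 1)
})

test_that("BAM route: mate arithmetic, flag filters, mismatch recovery", {
  fx <- make_tiny_sam()
  f <- read_fragments(fx$sam, fasta = fx$fa$path)
  # only r1 survives (rdup duplicate, rsec secondary)
  expect_equal(nrow(f), 1)
  expect_equal(f$start, 100L)
  expect_equal(f$end, 250L)
  expect_equal(f$variants, paste0("110:", fx$alt))
  fk <- read_fragments(fx$sam, keep_duplicates = TRUE, fasta = fx$fa$path)
  expect_equal(nrow(fk), 2)
  expect_equal(sort(fk$start), c(100L, 120L))
})

test_that("BAM and fragments-BED routes agree", {
  fx <- make_tiny_sam()
  fb <- read_fragments(fx$sam, keep_duplicates = TRUE,
                       fasta = fx$fa$path)
  fd <- read_fragments(fx$bed, keep_duplicates = TRUE)
  cols <- c("chrom", "start", "end", "is_duplicate", "variants")
  expect_equal(fb[order(fb$start), cols], fd[order(fd$start), cols],
               ignore_attr = TRUE)
})

test_that("unpaired-only alignments advise the fragments-BED mode", {
  fa <- make_tiny_fasta()
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", fa$chrom, fa$len),
    sprintf("u1\t0\t%s\t101\t60\t50M\t*\t0\t0\t%s\t*", fa$chrom,
            substr(fa$seq, 101, 150))), sam)
  expect_error(read_fragments(sam), "fragments-BED")
})

test_that("reference windows are exact, N-padded, and uppercased", {
  fa <- make_tiny_fasta()
  s <- read_reference_window(fa$path, fa$chrom, 10L, 60L)
  expect_equal(s, substr(fa$seq, 11, 60))
  over <- read_reference_window(fa$path, fa$chrom, -10L, 40L)
  expect_equal(nchar(over), 50)
  expect_equal(substr(over, 1, 10), strrep("N", 10))
  expect_equal(substr(over, 11, 50), substr(fa$seq, 1, 40))
  tail <- read_reference_window(fa$path, fa$chrom, fa$len - 5L,
                                fa$len + 5L)
  expect_equal(substr(tail, 6, 10), strrep("N", 5))
  expect_error(read_reference_window(fa$path, "nope", 0L, 10L), "contig")
  # soft-masked input comes back uppercase
  lc <- tempfile(fileext = ".fa")
  writeLines(c(">m", "acgtacgtac"), lc)
  Rsamtools::indexFa(lc)
  expect_equal(read_reference_window(lc, "m", 0L, 4L), "ACGT")
})

test_that("segmentations are sorted and must not overlap", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t600\t800\t9_EnhA1", "chr1\t0\t600\t1_TssA"), path)
  seg <- read_segmentation(path)
  expect_equal(seg$start, c(0L, 600L))
  expect_equal(seg$state_label, c("1_TssA", "9_EnhA1"))
  writeLines(c("chr1\t0\t600\t1_TssA", "chr1\t500\t800\t9_EnhA1"), path)
  expect_error(read_segmentation(path), "overlap")
})

test_that("prediction TSV roundtrips and validates probabilities", {
  rec <- data.frame(chrom = "chr1", start = 0L, end = 600L, name = "p1",
                    prob_promoter = 1, prob_enhancer = 0,
                    prob_insulator = 0, prob_other = 0)
  path <- tempfile(fileext = ".tsv")
  write_predictions(rec, path)
  back <- read_predictions(path)
  expect_equal(back$label, "promoter")
  expect_equal(back$prob_promoter, 1)
  rec2 <- rec
  rec2$prob_promoter <- 0.5
  rec2$prob_enhancer <- 0.3   # sums to 0.8
  expect_error(write_predictions(rec2, path), "sum to 1")
  # roundtrip at print precision
  rec3 <- data.frame(chrom = "chr1", start = 10L, end = 610L, name = "x",
                     prob_promoter = 0.123456, prob_enhancer = 0.2,
                     prob_insulator = 0.3, prob_other = 0.376544)
  write_predictions(rec3, path)
  b3 <- read_predictions(path)
  expect_equal(b3$prob_promoter, 0.123456, tolerance = 1e-9)
  expect_equal(b3$start, 10L)
})

test_that("BED coordinates roundtrip without off-by-one", {
  set.seed(3)
  n <- 20
  peaks <- data.frame(chrom = "chr1",
                      start = sort(sample.int(10000, n)) * 3L)
  peaks$end <- peaks$start + sample(100:500, n)
  path <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tp%d", peaks$start, peaks$end,
                     seq_len(n)), path)
  back <- read_peaks(path)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
})
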