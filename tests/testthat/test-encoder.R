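test_that("peak_window centers by floor and has fixed length", {
  cfg <- encoder_config()
  w <- peak_window(list(chrom = "c", start = 1000L, end = 1600L), cfg)
  expect_equal(c(w$start, w$end), c(1000L, 1600L))
  w2 <- peak_window(list(chrom = "c", start = 1000L, end = 1601L), cfg)
  expect_equal(c(w2$start, w2$end), c(1000L, 1600L))
  for (s in c(0L, 37L, 999L)) {
    w3 <- peak_window(list(chrom = "c", start = s, end = s + 123L), cfg)
    expect_equal(w3$end - w3$start, 600L)
  }
})

test_that("encoder_config enforces its invariants", {
  expect_error(encoder_config(smooth_window = 14L))
  expect_error(encoder_config(smooth_polyorder = 15L))
  expect_error(encoder_config(window_len = 601L))
})

test_that("insert pileup equals brute-force span enumeration", {
  win <- list(chrom = "c", start = 1000L, end = 1600L)
  f1 <- frag_df("c", 1250L, 1350L)
  r <- insert_pileup_row(f1, win)
  expect_equal(sum(r), 100)
  expect_equal(which(r == 1), 251:350)
  # fragment entirely outside
  expect_equal(sum(insert_pileup_row(frag_df("c", 0L, 900L), win)), 0)
  # 200 random fragments vs O(n*L) oracle
  set.seed(42)
  fr <- frag_df("c", s <- sample(700:1700, 200, TRUE),
                s + sample(30:400, 200, TRUE))
  got <- insert_pileup_row(fr, win)
  oracle <- vapply(1000:1599, function(p)
    sum(fr$start <= p & p < fr$end), numeric(1))
  expect_equal(got, oracle)
})

test_that("cut rows: endpoint histograms, conservation, impulse support", {
  cfg <- encoder_config()
  win <- list(chrom = "c", start = 0L, end = 600L)
  set.seed(7)
  fr <- frag_df("c", s <- sample(-100:650, 300, TRUE),
                s + sample(30:300, 300, TRUE))
  raw <- cut_count_rows(fr, win, cfg, smooth = FALSE)
  # conservation: totals equal endpoint counts inside the window
  expect_equal(sum(raw["cut5", ]),
               sum(fr$start >= 0 & fr$start < 600))
  expect_equal(sum(raw["cut3", ]),
               sum(fr$end - 1 >= 0 & fr$end - 1 < 600))
  # direct histogram oracle
  h5 <- tabulate(fr$start[fr$start >= 0 & fr$start < 600] + 1L, 600)
  expect_equal(unname(raw["cut5", ]), as.numeric(h5))
  # all left ends at one position -> impulse; smoothing support is 15
  fi <- frag_df("c", rep(300L, 9), rep(300L, 9) + seq(40L, 120L, 10L))
  ri <- cut_count_rows(fi, win, cfg, smooth = FALSE)
  expect_equal(sum(ri["cut5", ] != 0), 1)
  si <- cut_count_rows(fi, win, cfg, smooth = TRUE)
  expect_equal(sum(abs(si["cut5", ]) > 1e-12), 15)
  # no fragments -> zeros
  z <- cut_count_rows(frag_df("z", 1L, 2L)[0, ], win, cfg)
  expect_true(all(z == 0))
})

test_that("fragment-length rows take per-site medians with zero fill", {
  cfg <- encoder_config()
  win <- list(chrom = "c", start = 0L, end = 600L)
  fr <- frag_df("c", rep(100L, 3), 100L + c(100L, 150L, 210L))
  raw <- fragment_length_rows(fr, win, cfg, smooth = FALSE)
  expect_equal(unname(raw["len5", 101]), 150)
  # single fragment: value L at both end positions
  f1 <- frag_df("c", 200L, 330L)
  r1 <- fragment_length_rows(f1, win, cfg, smooth = FALSE)
  expect_equal(unname(r1["len5", 201]), 130)
  expect_equal(unname(r1["len3", 330]), 130)
  expect_equal(sum(r1["len5", ] != 0), 1)
  # random fragments: grouped median equals stats::median oracle
  set.seed(8)
  fr2 <- frag_df("c", s <- sample(0:590, 400, TRUE),
                 s + sample(20:300, 400, TRUE))
  raw2 <- fragment_length_rows(fr2, win, cfg, smooth = FALSE)
  lens <- fr2$end - fr2$start
  oracle <- numeric(600)
  m <- tapply(lens, fr2$start, stats::median)
  oracle[as.integer(names(m)) + 1L] <- as.numeric(m)
  expect_equal(unname(raw2["len5", ]), oracle)
})

test_that("smoothing is Savitzky-Golay: constants, support, polyfit", {
  cfg <- encoder_config()
  expect_equal(smooth_track(rep(3, 100), cfg), rep(3, 100))
  imp <- numeric(101)
  imp[51] <- 1
  s <- smooth_track(imp, cfg)
  expect_equal(sum(abs(s) > 1e-12), 15)
  set.seed(5)
  x <- rnorm(80)
  got <- smooth_track(x, cfg)
  oracle <- sg_oracle_interior(x)
  keep <- !is.na(oracle)
  expect_lt(max(abs(got[keep] - oracle[keep])), 1e-9)
  expect_error(smooth_track(rnorm(10), cfg), "shorter")
})

test_that("sequence rows: pileup frequencies with reference fallback", {
  cfg <- encoder_config()
  fa <- make_tiny_fasta(len = 700L)
  win <- list(chrom = fa$chrom, start = 50L, end = 650L)
  refseq <- read_reference_window(fa$path, fa$chrom, 50L, 650L)
  # depth 20 at position 300 (0-based): 14 carry an A substitution, 6 a C
  ref_base <- substr(refseq, 251, 251)
  fr <- frag_df(fa$chrom, rep(250L, 20), rep(350L, 20),
                variants = c(rep("300:A", 14), rep("300:C", 6)))
  rows <- sequence_frequency_rows(fr, win, refseq, cfg)
  expect_equal(unname(rows[, 251]), c(0.7, 0.3, 0, 0))
  # all columns sum to 1 (no N reference here)
  expect_true(all(abs(colSums(rows) - 1) < 1e-12))
  # depth 9 < min_depth: one-hot of the reference base even if calls differ
  fr9 <- frag_df(fa$chrom, rep(250L, 9), rep(350L, 9),
                 variants = rep("300:G", 9))
  rows9 <- sequence_frequency_rows(fr9, win, refseq, cfg)
  onehot <- as.numeric(c("A", "C", "G", "T") == ref_base)
  expect_equal(unname(rows9[, 251]), onehot)
  # zero fragments: pure reference one-hot everywhere
  rows0 <- sequence_frequency_rows(fr[0, ], win, refseq, cfg)
  expect_true(all(colSums(rows0) == 1))
  expect_equal(unname(rows0[, 1]),
               as.numeric(c("A", "C", "G", "T") == substr(refseq, 1, 1)))
  # N reference with low depth: all-zero column
  refN <- paste0("N", substr(refseq, 2, 600))
  rowsN <- sequence_frequency_rows(fr[0, ], win, refN, cfg)
  expect_equal(sum(rowsN[, 1]), 0)
})

test_that("standardization: population moments, zero-variance, idempotence", {
  cfg <- encoder_config()
  # column {1, 3} over two peaks -> {-1, +1}
  tr <- array(0, c(5, 600, 2))
  tr[1, 1, ] <- c(1, 3)
  std <- standardize_dataset(tr, cfg)
  expect_equal(std$standardized[1, 1, ], c(-1, 1))
  # constant columns map to 0
  expect_true(all(std$standardized[2, , ] == 0))
  # non-degenerate columns: mean 0, population sd 1
  set.seed(12)
  tr2 <- array(rnorm(5 * 600 * 7), c(5, 600, 7))
  std2 <- standardize_dataset(tr2, cfg)
  z <- std2$standardized
  mu <- apply(z, c(1, 2), mean)
  sd_pop <- sqrt(apply(z, c(1, 2), function(v) mean((v - mean(v))^2)))
  expect_lt(max(abs(mu)), 1e-6)
  expect_lt(max(abs(sd_pop - 1)), 1e-6)
  # idempotence: re-applying fitted stats reproduces bit-for-bit
  again <- apply_encoding_stats(tr2, std2$stats, cfg)
  expect_identical(again, z)
})

test_that("peak indicator marks exactly the peak positions", {
  win <- list(chrom = "c", start = 0L, end = 600L)
  ind <- peak_indicator_row(list(start = 200L, end = 350L), win)
  expect_equal(sum(ind), 150)
  expect_true(all(ind %in% c(0, 1)))
  all1 <- peak_indicator_row(list(start = -10L, end = 700L), win)
  expect_equal(sum(all1), 600)
})

test_that("encode_dataset: shape, order invariance, empty fragments", {
  md <- get_micro_data()
  d <- md$d
  enc <- md$enc
  n <- nrow(d$peaks)
  expect_equal(dim(enc$encodings), c(10, 600, n))
  # shuffled peak order gives identical per-peak matrices
  set.seed(4)
  idx <- sample.int(n)
  enc2 <- encode_dataset(d$peaks[idx, ], d$fragments, d$fasta)
  expect_equal(enc2$encodings[, , order(idx)[1:5]],
               enc$encodings[, , 1:5], tolerance = 1e-12)
  # empty fragment source: signal rows all degenerate -> zero
  enc0 <- encode_dataset(d$peaks[1:3, ], d$fragments[0, ], d$fasta)
  expect_true(all(enc0$encodings[5:9, , ] == 0))
  expect_true(all(colSums(enc0$encodings[1:4, , 1]) == 1))
})

test_that("encoding from SAM and equivalent fragments-BED is identical", {
  fx <- make_tiny_sam()
  peak <- data.frame(chrom = fx$fa$chrom, start = 50L, end = 350L,
                     name = "p1", neglog10_qval = 5,
                     summit_offset = NA_integer_)
  fb <- read_fragments(fx$sam, keep_duplicates = TRUE,
                       fasta = fx$fa$path)
  fd <- read_fragments(fx$bed, keep_duplicates = TRUE)
  cfg <- encoder_config(min_depth = 1L)
  e1 <- encode_dataset(peak, fb, fx$fa$path, cfg)
  e2 <- encode_dataset(peak, fd, fx$fa$path, cfg)
  expect_equal(e1$encodings, e2$encodings, tolerance = 1e-12)
  # genotype awareness: at the planted SNP the encoded base is the read
  # allele, not the reference one-hot
  w <- peak_window(peak, cfg)
  col <- 110L - w$start + 1L
  alt_row <- match(fx$alt, c("A", "C", "G", "T"))
  ref_base <- substr(fx$fa$seq, 111, 111)
  ref_row <- match(ref_base, c("A", "C", "G", "T"))
  expect_equal(e1$encodings[alt_row, col, 1], 1)
  expect_equal(e1$encodings[ref_row, col, 1], 0)
})
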