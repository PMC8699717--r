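# Shared fixtures, all built in code.

# deterministic small reference written to a temp FASTA; returns
# list(path, seq) for one contig
make_tiny_fasta <- function(len = 400L, seed = 99L, chrom = "chrT") {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  path <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", chrom), gsub("(.{70})", "\\1\n", seq)), path)
  Rsamtools::indexFa(path)
  list(path = path, seq = seq, chrom = chrom, len = len)
}

# a coordinate-sorted SAM with:
#  - pair r1: fragment [100, 250), read1 carries a mismatch at 0-based
#    position 110 (alt base chosen to differ from the reference)
#  - pair rdup: duplicate-flagged fragment [120, 260)
#  - rsec: secondary alignment (must be ignored)
# plus the equivalent fragments-BED. Returns paths + the fasta info.
make_tiny_sam <- function(fa = make_tiny_fasta()) {
  sub0 <- function(s, e) substr(fa$seq, s + 1L, e)  # 0-based half-open
  ref110 <- substr(fa$seq, 111, 111)
  alt <- setdiff(c("A", "C", "G", "T"), ref110)[1]
  r1a <- sub0(100, 150)
  substr(r1a, 11, 11) <- alt  # genomic 0-based 110
  r1b <- sub0(200, 250)
  d1a <- sub0(120, 170)
  d1b <- sub0(210, 260)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", fa$chrom, fa$len),
    sprintf("r1\t99\t%s\t101\t60\t50M\t=\t201\t150\t%s\t*", fa$chrom, r1a),
    sprintf("rdup\t1123\t%s\t121\t60\t50M\t=\t211\t140\t%s\t*", fa$chrom,
            d1a),
    sprintf("rsec\t355\t%s\t131\t60\t50M\t=\t231\t150\t%s\t*", fa$chrom,
            sub0(130, 180)),
    sprintf("r1\t147\t%s\t201\t60\t50M\t=\t101\t-150\t%s\t*", fa$chrom,
            r1b),
    sprintf("rdup\t1171\t%s\t211\t60\t50M\t=\t121\t-140\t%s\t*", fa$chrom,
            d1b))
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    sprintf("%s\t100\t250\t.\t0\t110:%s", fa$chrom, alt),
    sprintf("%s\t120\t260\t.\t1\t.", fa$chrom)), bed)
  list(sam = sam, bed = bed, fa = fa, alt = alt)
}

# quick fragment data.frame constructor
frag_df <- function(chrom, start, end, variants = ".",
                    is_duplicate = FALSE, barcode = NA_character_) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), is_duplicate = is_duplicate,
             barcode = barcode, variants = variants)
}

# independent Savitzky-Golay oracle: local least-squares cubic fit per
# window, evaluated at the center (interior positions only)
sg_oracle_interior <- function(x, n = 15L, p = 3L) {
  h <- (n - 1L) %/% 2L
  out <- rep(NA_real_, length(x))
  for (i in (h + 1L):(length(x) - h)) {
    w <- (i - h):(i + h)
    fit <- stats::lm(x[w] ~ stats::poly(seq_len(n), degree = p,
                                        raw = TRUE))
    out[i] <- unname(stats::predict(fit)[h + 1L])
  }
  out
}

# brute-force IUPAC motif scan (both strands, overlapping, subject N
# never matches)
iupac_scan_oracle <- function(sequence, motif) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  rc <- function(m) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
              H = "D", V = "B", N = "N")
    paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
  }
  scan1 <- function(seq, m) {
    s <- strsplit(seq, "")[[1]]
    mm <- strsplit(m, "")[[1]]
    k <- length(mm)
    if (length(s) < k) return(0L)
    hits <- 0L
    for (i in 1:(length(s) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!(s[i + j - 1L] %in% tab[[mm[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  scan1(sequence, motif) + scan1(sequence, rc(motif))
}

# small cached 4-class dataset + encodings shared across test files
micro_env <- new.env()
get_micro_data <- function() {
  if (!is.null(micro_env$data)) return(micro_env$data)
  d <- gen_class_dataset(n_train = 80L, n_validation = 24L, n_test = 24L,
                         seed = 11L)
  enc <- encode_dataset(d$peaks, d$fragments, d$fasta)
  fm <- feature_matrix(d$peaks, d$fragments, d$fasta,
                       feature_config(tss = d$tss))
  micro_env$data <- list(d = d, enc = enc, fm = fm)
  micro_env$data
}

micro_model_config <- function(...) {
  model_config(conv_blocks = 1L, filters_per_block = 8L,
               branch_dense = 16L, joint_dense = 8L,
               branch_epochs = 3L, joint_epochs = 2L,
               early_stopping_patience = 3L, seed = 7L, ...)
}
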