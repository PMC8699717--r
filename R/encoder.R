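# Per-peak 10 x window encoding of ATAC-seq fragments + sequence.
#
# Rows 1-4: A/C/G/T base-call frequencies from the fragment pileup where
#           depth >= min_depth, else a one-hot of the reference base.
# Row 5:    insert (fragment-span) pileup counts.
# Rows 6-7: 5' / 3' Tn5 cut counts, Savitzky-Golay smoothed.
# Rows 8-9: median fragment length at each 5' / 3' cut site, smoothed.
# Row 10:   binary indicator of the original peak interval.
# Rows 5-9 are z-standardized per column across all peaks of a dataset
# (two-pass: raw tracks first, then dataset-level standardization).

SIGNAL_TRACKS <- c("insert", "cut5", "cut3", "len5", "len3")

#' Encoder configuration
#'
#' @param window_len Total encoded window in bp (default 600, i.e. 300 bp
#'   either side of the peak center).
#' @param min_depth Minimum number of A/C/G/T base calls at a position for
#'   the pileup frequency to be used; below it the reference one-hot is
#'   used (default 10).
#' @param smooth_window Savitzky-Golay window length in positions (odd,
#'   default 15).
#' @param smooth_polyorder Savitzky-Golay polynomial order (default 3).
#' @param tn5_shift Length-2 integer vector added to (5', 3') cut
#'   positions; the conventional +4/-5 transposase offset is not applied
#'   unless requested (default `c(0, 0)`).
#' @param zero_variance_value Value assigned to standardized columns whose
#'   dataset-wide standard deviation is zero (default 0).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(window_len = 600L, min_depth = 10L,
                           smooth_window = 15L, smooth_polyorder = 3L,
                           tn5_shift = c(0L, 0L),
                           zero_variance_value = 0) {
  window_len <- as.integer(window_len)
  stopifnot(window_len > 0, window_len %% 2 == 0,
            min_depth >= 1,
            smooth_window %% 2 == 1,
            smooth_polyorder < smooth_window,
            length(tn5_shift) == 2)
  structure(list(window_len = window_len,
                 half_window = window_len %/% 2L,
                 min_depth = as.integer(min_depth),
                 smooth_window = as.integer(smooth_window),
                 smooth_polyorder = as.integer(smooth_polyorder),
                 tn5_shift = as.integer(tn5_shift),
                 zero_variance_value = zero_variance_value),
            class = "encoder_config")
}

#' Encoding window centered on a peak
#'
#' The center is `floor((start + end) / 2)` and the window spans
#' `half_window` bp on each side, giving a fixed-length interval.
#'
#' @param peak List or one-row data.frame with `chrom`, `start`, `end`.
#' @param config An [encoder_config()].
#' @return `list(chrom, start, end)`, 0-based half-open.
#' @export
peak_window <- function(peak, config = encoder_config()) {
  center <- (peak$start + peak$end) %/% 2L
  list(chrom = peak$chrom,
       start = center - config$half_window,
       end = center + config$half_window)
}

#' Savitzky-Golay smoothing of a signal track
#'
#' Least-squares local polynomial smoothing (window `smooth_window`, order
#' `smooth_polyorder`); edge values come from evaluating the terminal
#' window's polynomial fit at the edge positions.
#'
#' @param track Numeric vector, length >= `smooth_window`.
#' @param config An [encoder_config()].
#' @export
smooth_track <- function(track, config = encoder_config()) {
  if (length(track) < config$smooth_window)
    stop("track shorter than the smoothing window", call. = FALSE)
  as.numeric(signal::sgolayfilt(track, p = config$smooth_polyorder,
                                n = config$smooth_window))
}

# fragments overlapping a window, as offsets (may extend outside [0, L))
.window_frags <- function(fragments, window) {
  f <- fragments[fragments$chrom == window$chrom &
                   fragments$start < window$end &
                   fragments$end > window$start, , drop = FALSE]
  f$off_start <- f$start - window$start
  f$off_end <- f$end - window$start
  f
}

#' Insert (fragment-span) pileup over a window
#'
#' Count at position p of fragments with `start <= p < end`.
#'
#' @param fragments Fragment data.frame (see [read_fragments()]).
#' @param window `list(chrom, start, end)` as from [peak_window()].
#' @return Integer-valued numeric vector of window length.
#' @export
insert_pileup_row <- function(fragments, window) {
  L <- window$end - window$start
  f <- .window_frags(fragments, window)
  d <- numeric(L + 1L)
  if (nrow(f) > 0) {
    s <- pmax(f$off_start, 0L) + 1L
    e <- pmin(f$off_end, L) + 1L
    for (i in seq_along(s)) {
      d[s[i]] <- d[s[i]] + 1
      d[e[i]] <- d[e[i]] - 1
    }
  }
  cumsum(d[seq_len(L)])
}

# histogram of cut positions (0-based offsets) over window length L
.cut_hist <- function(offsets, L) {
  h <- numeric(L)
  keep <- offsets >= 0L & offsets < L
  if (any(keep)) {
    t <- tabulate(offsets[keep] + 1L, nbins = L)
    h <- as.numeric(t)
  }
  h
}

#' Raw (pre-smoothing) 5' and 3' cut-count rows
#'
#' +1 at each fragment's left end (5' cut) and right-end base (3' cut),
#' after the configured Tn5 shift.
#'
#' @inheritParams insert_pileup_row
#' @param config An [encoder_config()].
#' @param smooth Apply Savitzky-Golay smoothing (the encoder does; set
#'   FALSE to inspect raw counts).
#' @return 2 x window_len matrix, rows `cut5`, `cut3`.
#' @export
cut_count_rows <- function(fragments, window, config = encoder_config(),
                           smooth = TRUE) {
  L <- window$end - window$start
  f <- .window_frags(fragments, window)
  cut5 <- .cut_hist(f$off_start + config$tn5_shift[1], L)
  cut3 <- .cut_hist(f$off_end - 1L + config$tn5_shift[2], L)
  if (smooth) {
    cut5 <- smooth_track(cut5, config)
    cut3 <- smooth_track(cut3, config)
  }
  rbind(cut5 = cut5, cut3 = cut3)
}

#' Median-fragment-length rows at 5' and 3' cut sites
#'
#' Raw value at p is the median insert length of fragments whose 5'
#' (resp. 3') cut falls at p, 0 where no fragment cuts; smoothed like the
#' cut-count rows.
#'
#' @inheritParams cut_count_rows
#' @return 2 x window_len matrix, rows `len5`, `len3`.
#' @export
fragment_length_rows <- function(fragments, window,
                                 config = encoder_config(),
                                 smooth = TRUE) {
  L <- window$end - window$start
  f <- .window_frags(fragments, window)
  lens <- f$off_end - f$off_start
  med_at <- function(offsets) {
    v <- numeric(L)
    keep <- offsets >= 0L & offsets < L
    if (any(keep)) {
      # grouped median via one sort (equivalent to per-group stats::median)
      o <- offsets[keep]
      ln <- lens[keep]
      ord <- order(o, ln)
      o <- o[ord]
      ln <- ln[ord]
      ends <- c(which(diff(o) != 0), length(o))
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      mid <- (starts + ends) / 2
      med <- (ln[floor(mid)] + ln[ceiling(mid)]) / 2
      v[o[starts] + 1L] <- med
    }
    v
  }
  len5 <- med_at(f$off_start + config$tn5_shift[1])
  len3 <- med_at(f$off_end - 1L + config$tn5_shift[2])
  if (smooth) {
    len5 <- smooth_track(len5, config)
    len3 <- smooth_track(len3, config)
  }
  rbind(len5 = len5, len3 = len3)
}

#' Base-call frequency rows (A, C, G, T)
#'
#' Each fragment contributes one base call per covered position: the
#' reference base, unless the fragment carries a recorded substitution
#' there (the genotype-aware part of the encoding). Where the number of
#' A/C/G/T calls reaches `min_depth` the row values are call frequencies;
#' below that the column falls back to a one-hot encoding of the reference
#' base (all-zero when the reference base is N).
#'
#' @inheritParams insert_pileup_row
#' @param refseq Uppercase reference sequence of exactly window length.
#' @param config An [encoder_config()].
#' @return 4 x window_len matrix with rows A, C, G, T.
#' @export
sequence_frequency_rows <- function(fragments, window, refseq,
                                    config = encoder_config()) {
  L <- window$end - window$start
  stopifnot(nchar(refseq) == L)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(toupper(refseq), "")[[1]]
  ref_idx <- match(ref, bases)           # NA for N etc.
  cov <- insert_pileup_row(fragments, window)
  cnt <- matrix(0, 4L, L, dimnames = list(bases, NULL))
  known <- which(!is.na(ref_idx) & cov > 0)
  if (length(known) > 0)
    cnt[cbind(ref_idx[known], known)] <- cov[known]
  f <- .window_frags(fragments, window)
  if (nrow(f) > 0 && any(f$variants != ".")) {
    for (i in which(f$variants != ".")) {
      v <- .parse_variants(f$variants[i])
      if (is.null(v)) next
      inside <- v$pos >= max(f$start[i], window$start) &
        v$pos < min(f$end[i], window$end)
      for (j in which(inside)) {
        p <- v$pos[j] - window$start + 1L
        alt <- match(v$base[j], bases)
        if (is.na(alt)) next
        if (!is.na(ref_idx[p])) cnt[ref_idx[p], p] <- cnt[ref_idx[p], p] - 1
        cnt[alt, p] <- cnt[alt, p] + 1
      }
    }
  }
  depth <- colSums(cnt)
  out <- matrix(0, 4L, L, dimnames = list(bases, NULL))
  deep <- depth >= config$min_depth
  if (any(deep))
    out[, deep] <- sweep(cnt[, deep, drop = FALSE], 2, depth[deep], "/")
  shallow <- which(!deep & !is.na(ref_idx))
  if (length(shallow) > 0)
    out[cbind(ref_idx[shallow], shallow)] <- 1
  out
}

#' Binary peak-indicator row
#'
#' 1 exactly at window positions inside the original peak interval.
#'
#' @param peak List/row with `start`, `end`.
#' @param window `list(chrom, start, end)`.
#' @export
peak_indicator_row <- function(peak, window) {
  p <- seq(window$start, window$end - 1L)
  as.numeric(p >= peak$start & p < peak$end)
}

# all raw tracks for one peak
.raw_peak_tracks <- function(peak, fragments, refseq, config) {
  window <- peak_window(peak, config)
  list(seq_freq = sequence_frequency_rows(fragments, window, refseq, config),
       signal = rbind(insert = insert_pileup_row(fragments, window),
                      cut_count_rows(fragments, window, config),
                      fragment_length_rows(fragments, window, config)),
       indicator = peak_indicator_row(peak, window))
}

#' Fit dataset-wide column standardization for the signal tracks
#'
#' Per signal track and per column offset, computes the mean and
#' population standard deviation across all peaks; `z = (x - mean) / std`,
#' with zero-variance columns mapped to the configured constant.
#'
#' @param tracks 3-D array `(5, window_len, n_peaks)` of raw signal tracks.
#' @param config An [encoder_config()].
#' @return `list(stats = list(mean, std), standardized)` where `mean` and
#'   `std` are 5 x window_len matrices.
#' @export
standardize_dataset <- function(tracks, config = encoder_config()) {
  stopifnot(length(dim(tracks)) == 3, dim(tracks)[1] == 5)
  n <- dim(tracks)[3]
  mu <- apply(tracks, c(1, 2), mean)
  sd_pop <- sqrt(pmax(apply(tracks, c(1, 2), function(x)
    mean((x - mean(x))^2)), 0))
  stats <- list(mean = mu, std = sd_pop)
  list(stats = stats,
       standardized = apply_encoding_stats(tracks, stats, config))
}

#' Apply previously fitted standardization statistics
#'
#' @param tracks 3-D array `(5, window_len, n_peaks)`.
#' @param stats `list(mean, std)` as fitted by [standardize_dataset()].
#' @param config An [encoder_config()].
#' @return Standardized array of the same shape.
#' @export
apply_encoding_stats <- function(tracks, stats, config = encoder_config()) {
  out <- tracks
  n <- dim(tracks)[3]
  zero <- stats$std == 0
  for (k in seq_len(n)) {
    z <- (tracks[, , k] - stats$mean) / stats$std
    z[zero] <- config$zero_variance_value
    out[, , k] <- z
  }
  out
}

#' Encode a peak set into 10 x window_len matrices
#'
#' Two passes: raw per-peak tracks, then dataset-level column
#' standardization of the five signal rows. Per-peak matrices depend only
#' on the peak, its fragments and the reference, so output order matches
#' input order and is invariant to shuffling.
#'
#' @param peaks Peak data.frame ([read_peaks()]).
#' @param fragments Fragment data.frame ([read_fragments()]), or a path
#'   accepted by [read_fragments()].
#' @param fasta Indexed reference FASTA (or a personalized consensus).
#' @param config An [encoder_config()].
#' @param stats Optional pre-fitted standardization statistics; when given
#'   they are applied instead of re-fitting (as at prediction time).
#' @return List of class `peak_encoding_set`: `encodings` (array
#'   `10 x window_len x n`), `stats`, `peaks`, `config`.
#' @export
encode_dataset <- function(peaks, fragments, fasta,
                           config = encoder_config(), stats = NULL) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  n <- nrow(peaks)
  stopifnot(n >= 1)
  L <- config$window_len
  seq_rows <- array(0, c(4, L, n))
  sig_rows <- array(0, c(5, L, n))
  ind_rows <- matrix(0, L, n)
  # index fragments by chromosome once; per-peak subsetting by start order
  by_chrom <- split(fragments, fragments$chrom)
  by_chrom <- lapply(by_chrom, function(f) f[order(f$start), , drop = FALSE])
  max_len <- if (nrow(fragments) > 0)
    max(fragments$end - fragments$start) else 0L
  fetch <- .reference_fetcher(fasta)
  for (k in seq_len(n)) {
    peak <- peaks[k, ]
    window <- peak_window(peak, config)
    f <- by_chrom[[peak$chrom]]
    if (is.null(f)) {
      f <- fragments[0, , drop = FALSE]
    } else {
      lo <- findInterval(window$start - max_len, f$start) + 1L
      hi <- findInterval(window$end - 1L, f$start)
      f <- if (hi >= lo) f[lo:hi, , drop = FALSE] else f[0, , drop = FALSE]
    }
    refseq <- fetch(window$chrom, window$start, window$end)
    raw <- .raw_peak_tracks(peak, f, refseq, config)
    seq_rows[, , k] <- raw$seq_freq
    sig_rows[, , k] <- raw$signal
    ind_rows[, k] <- raw$indicator
  }
  if (is.null(stats)) {
    std <- standardize_dataset(sig_rows, config)
    stats <- std$stats
    sig_std <- std$standardized
  } else {
    sig_std <- apply_encoding_stats(sig_rows, stats, config)
  }
  enc <- array(0, c(10, L, n))
  enc[1:4, , ] <- seq_rows
  enc[5:9, , ] <- sig_std
  enc[10, , ] <- ind_rows
  structure(list(encodings = enc, stats = stats, peaks = peaks,
                 config = config),
            class = "peak_encoding_set")
}

#' @export
print.peak_encoding_set <- function(x, ...) {
  d <- dim(x$encodings)
  cat(sprintf("peak_encoding_set: %d peaks, %d x %d matrices\n",
              d[3], d[1], d[2]))
  invisible(x)
}
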