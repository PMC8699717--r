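# The 19-element auxiliary feature vector fed to the second classifier
# branch. The vector length and its interface are fixed; the membership is
# a documented, configurable registry drawn from the feature families the
# method relies on (TSS distance, peak-caller FDR, CTCF and other motif
# counts, insert-size and cut-site statistics, GC/CpG content,
# conservation).

# CTCF core consensus (IUPAC), configurable; reproducible without a motif
# database.
DEFAULT_CTCF_MOTIF <- "CCGCGNGGNGGCAG"

DEFAULT_EXTRA_MOTIFS <- c(tata = "TATAAA", caat = "CCAAT",
                          gcbox = "GGGCGG", ap1 = "TGASTCA")

#' Feature-extraction configuration
#'
#' @param tss Optional data.frame of TSS positions with columns `chrom`,
#'   `pos` (0-based). When absent the TSS-distance feature takes the
#'   neutral distal value `1e6`.
#' @param ctcf_motif IUPAC consensus used for the CTCF motif count.
#' @param extra_motifs Named character vector of exactly 4 additional
#'   IUPAC motifs.
#' @param conservation Optional function `(chrom, start, end) ->` numeric
#'   per-base scores; the mean-conservation feature is 0 when absent.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(tss = NULL, ctcf_motif = DEFAULT_CTCF_MOTIF,
                           extra_motifs = DEFAULT_EXTRA_MOTIFS,
                           conservation = NULL) {
  stopifnot(nzchar(ctcf_motif), length(extra_motifs) == 4,
            !is.null(names(extra_motifs)))
  structure(list(tss = tss, ctcf_motif = ctcf_motif,
                 extra_motifs = extra_motifs, conservation = conservation),
            class = "feature_config")
}

#' Count motif occurrences on both strands
#'
#' Matches the IUPAC `motif` against the forward sequence and against the
#' reverse complement of the motif (i.e. both strands of the subject);
#' overlapping matches are counted and subject `N` bases never match.
#'
#' @param sequence Character string over A/C/G/T/N.
#' @param motif IUPAC motif string.
#' @return Integer count.
#' @export
count_motif_occurrences <- function(sequence, motif) {
  if (nchar(sequence) < nchar(motif)) return(0L)
  subj <- Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::countPattern(pat, subj, fixed = "subject")
  rev <- Biostrings::countPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = "subject")
  as.integer(fwd + rev)
}

#' Names of the 19 registry features, in order
#' @export
feature_names <- function(config = feature_config()) {
  c("tss_distance", "peak_length", "neglog10_qval", "fragment_count",
    "mean_insert", "sd_insert", "frac_subnucleosomal",
    "frac_mononucleosomal", "cut_asymmetry", "gc_fraction", "cpg_count",
    "ctcf_motifs", paste0("motif_", names(config$extra_motifs)),
    "mean_conservation", "summit_offset_frac", "duplicate_fraction")
}

#' Extract the 19-element auxiliary feature vector for one peak
#'
#' Deterministic function of (peak, fragments, reference window, config).
#' Missing optional annotations map to documented neutral values (TSS
#' distance 1e6, conservation 0, q-value 0, summit fraction 0.5) so the
#' vector always has length 19.
#'
#' @param peak One-row peak data.frame ([read_peaks()]).
#' @param fragments Fragment data.frame.
#' @param refseq Uppercase reference sequence of the encoding window.
#' @param config A [feature_config()].
#' @param window The encoding window; defaults to [peak_window()] of the
#'   peak with the default encoder configuration.
#' @param .skip_seq Internal: leave sequence-derived features at 0 (the
#'   batch path fills them vectorized).
#' @return Named numeric vector of length 19.
#' @export
extract_features <- function(peak, fragments, refseq,
                             config = feature_config(),
                             window = peak_window(peak),
                             .skip_seq = FALSE) {
  f <- .window_frags(fragments, window)
  center <- (peak$start + peak$end) %/% 2L
  tss_dist <- 1e6
  if (!is.null(config$tss)) {
    tt <- config$tss[config$tss$chrom == peak$chrom, , drop = FALSE]
    if (nrow(tt) > 0) {
      d <- tt$pos - center
      tss_dist <- d[which.min(abs(d))]
    }
  }
  lens <- f$end - f$start
  nfrag <- nrow(f)
  L <- window$end - window$start
  n5 <- sum(f$off_start >= 0 & f$off_start < L)
  n3 <- sum(f$off_end - 1 >= 0 & f$off_end - 1 < L)
  if (.skip_seq) {
    gc <- 0
    cpg <- 0
    ctcf <- 0
    extra <- numeric(length(config$extra_motifs))
  } else {
    bases <- strsplit(toupper(refseq), "")[[1]]
    acgt <- sum(bases %in% c("A", "C", "G", "T"))
    gc <- if (acgt > 0) sum(bases %in% c("C", "G")) / acgt else 0
    cpg <- Biostrings::countPattern("CG",
                                    Biostrings::DNAString(toupper(refseq)))
    ctcf <- count_motif_occurrences(refseq, config$ctcf_motif)
    extra <- vapply(config$extra_motifs, function(m)
      as.numeric(count_motif_occurrences(refseq, m)), numeric(1))
  }
  cons <- 0
  if (!is.null(config$conservation))
    cons <- mean(config$conservation(window$chrom, window$start,
                                     window$end))
  vals <- c(
    tss_dist,
    peak$end - peak$start,
    if (is.na(peak$neglog10_qval)) 0 else peak$neglog10_qval,
    nfrag,
    if (nfrag > 0) mean(lens) else 0,
    if (nfrag > 1) stats::sd(lens) else 0,
    if (nfrag > 0) mean(lens < 147) else 0,
    if (nfrag > 0) mean(lens >= 147 & lens < 295) else 0,
    if (n5 + n3 > 0) (n5 - n3) / (n5 + n3) else 0,
    gc,
    # CpG dinucleotides, forward strand only (the dinucleotide is its own
    # reverse complement as a site)
    cpg,
    ctcf,
    extra,
    cons,
    if (is.na(peak$summit_offset)) 0.5
    else peak$summit_offset / (peak$end - peak$start),
    if (nfrag > 0) mean(f$is_duplicate) else 0
  )
  stats::setNames(as.numeric(vals), feature_names(config))
}

#' Feature matrix for a peak set
#'
#' @param peaks Peak data.frame.
#' @param fragments Fragment data.frame or path.
#' @param fasta Indexed reference FASTA.
#' @param config A [feature_config()].
#' @param encoder_cfg [encoder_config()] defining the window.
#' @return n x 19 numeric matrix with feature names as columns.
#' @export
feature_matrix <- function(peaks, fragments, fasta,
                           config = feature_config(),
                           encoder_cfg = encoder_config()) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  n <- nrow(peaks)
  out <- matrix(0, n, 19,
                dimnames = list(peaks$name, feature_names(config)))
  fetch <- .reference_fetcher(fasta)
  windows <- lapply(seq_len(n), function(k)
    peak_window(peaks[k, ], encoder_cfg))
  refseqs <- vapply(windows, function(w)
    fetch(w$chrom, w$start, w$end), character(1))
  for (k in seq_len(n))
    out[k, ] <- extract_features(peaks[k, ], fragments, refseqs[k],
                                 config, windows[[k]], .skip_seq = TRUE)
  # sequence-derived features in one vectorized pass (identical values to
  # the per-peak path)
  ss <- Biostrings::DNAStringSet(refseqs)
  counts2 <- function(motif) {
    pat <- Biostrings::DNAString(toupper(motif))
    Biostrings::vcountPattern(pat, ss, fixed = "subject") +
      Biostrings::vcountPattern(Biostrings::reverseComplement(pat), ss,
                                fixed = "subject")
  }
  lf <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
  acgt <- rowSums(lf)
  gc <- ifelse(acgt > 0, (lf[, "C"] + lf[, "G"]) / acgt, 0)
  out[, "gc_fraction"] <- gc
  out[, "cpg_count"] <- Biostrings::vcountPattern("CG", ss)
  out[, "ctcf_motifs"] <- counts2(config$ctcf_motif)
  for (m in names(config$extra_motifs))
    out[, paste0("motif_", m)] <- counts2(config$extra_motifs[[m]])
  out
}

#' Fit per-feature standardization (population z-scores)
#'
#' @param x n x p feature matrix.
#' @return `list(stats = list(mean, std), standardized)`; zero-variance
#'   features standardize to 0. The stats are reused at prediction time.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  stats <- list(mean = mu, std = sd_pop)
  list(stats = stats, standardized = apply_feature_stats(x, stats))
}

#' Apply fitted feature standardization statistics
#' @param x n x p feature matrix.
#' @param stats As returned by [standardize_features()].
#' @export
apply_feature_stats <- function(x, stats) {
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2, stats$mean), 2,
             ifelse(stats$std == 0, 1, stats$std), "/")
  z[, stats$std == 0] <- 0
  z
}
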