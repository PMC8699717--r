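# Ground-truth construction: ChromHMM-style state labels are merged into 4
# functional classes, peaks are kept only when >= 90% of their length is
# covered by a single class (the unanimity filter), chromosomes are
# partitioned into fixed train/validation/test splits, and the "other"
# class can be augmented with non-peak consensus regions.

# 18-state Roadmap mapping. States 3,4,14,15 are deliberately unmapped
# (flanking/bivalent states are ambiguous); this scheme has no insulator
# state, a documented labeling limitation.
ROADMAP18_MAP <- c(
  "1_TssA" = "promoter", "2_TssFlnk" = "promoter",
  "7_EnhG1" = "enhancer", "8_EnhG2" = "enhancer", "9_EnhA1" = "enhancer",
  "10_EnhA2" = "enhancer", "11_EnhWk" = "enhancer",
  "5_Tx" = "other", "6_TxWk" = "other", "12_ZNF/Rpts" = "other",
  "13_Het" = "other", "16_ReprPC" = "other", "17_ReprPCW" = "other",
  "18_Quies" = "other")

# EndoC beta-cell scheme (study-specific state names); no insulator state.
ENDOC_MAP <- c(
  "1_Active_TSS" = "promoter", "2_Weak_TSS" = "promoter",
  "14_Bivalent_poised_TSS" = "promoter",
  "8_Genic_enhancer" = "enhancer", "9_Active_enhancer_1" = "enhancer",
  "10_Active_enhancer_2" = "enhancer", "11_Weak_enhancer" = "enhancer",
  "5_Strong_transcription" = "other", "6_Weak_transcription" = "other",
  "16_Repressed_polycomb" = "other", "17_Weak_repressed_polycomb" = "other",
  "18_Quiescent_low_signal" = "other")

#' The four functional classes
#' @export
functional_classes <- function() CLASS_LEVELS

#' Build a label scheme (state label -> functional class)
#'
#' Built-in schemes: `roadmap18` (18-state Roadmap) and `endoc`; `custom`
#' takes an explicit named vector mapping state labels to one of the four
#' classes. States absent from the map are excluded rather than guessed.
#'
#' @param name `"roadmap18"`, `"endoc"`, or `"custom"`.
#' @param map For `custom`: named character vector of classes.
#' @return List of class `label_scheme`.
#' @export
label_scheme <- function(name = c("roadmap18", "endoc", "custom"),
                         map = NULL) {
  name <- match.arg(name)
  map <- switch(name, roadmap18 = ROADMAP18_MAP, endoc = ENDOC_MAP,
                custom = map)
  if (is.null(map) || is.null(names(map)))
    stop("custom scheme requires a named state -> class map", call. = FALSE)
  if (!all(map %in% CLASS_LEVELS))
    stop("classes must be one of: ", paste(CLASS_LEVELS, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, map = map), class = "label_scheme")
}

#' Map a ChromHMM state label to a functional class
#'
#' @param state_label Character vector of state labels.
#' @param scheme A [label_scheme()] or a built-in scheme name.
#' @return Character vector of classes, `NA` for unmapped (excluded)
#'   states.
#' @export
relabel_state <- function(state_label, scheme = "roadmap18") {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  stopifnot(inherits(scheme, "label_scheme"))
  unname(scheme$map[state_label])
}

#' Label one peak by unanimous segmentation coverage
#'
#' The segmentation's states are merged into classes first; the peak is
#' labeled with the class whose states cover at least `threshold` of the
#' peak's length (exact interval-intersection bp sums, denominated by peak
#' length), otherwise excluded. The boundary is inclusive: coverage
#' exactly at the threshold is retained.
#'
#' @param peak One-row peak data.frame.
#' @param segmentation Segmentation data.frame ([read_segmentation()]).
#' @param scheme [label_scheme()] or name.
#' @param threshold Unanimity threshold (default 0.9).
#' @return `list(label, overlap_fraction)` or `NULL` when excluded.
#' @export
annotate_peak <- function(peak, segmentation, scheme = "roadmap18",
                          threshold = 0.9) {
  cls <- relabel_state(segmentation$state_label, scheme)
  keep <- !is.na(cls) & segmentation$chrom == peak$chrom
  seg <- segmentation[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(seg) == 0) return(NULL)
  ov <- pmin(seg$end, peak$end) - pmax(seg$start, peak$start)
  pos <- ov > 0
  if (!any(pos)) return(NULL)
  cov <- tapply(ov[pos], cls[pos], sum)
  frac <- cov / (peak$end - peak$start)
  best <- which.max(frac)
  if (frac[best] >= threshold)
    list(label = names(frac)[best], overlap_fraction = unname(frac[best]))
  else NULL
}

# fixed autosome partition used for all models
SPLIT_TRAIN <- c(1, 4, 5, 6, 7, 8, 9, 12, 13, 14, 15, 16, 17, 18, 19, 20,
                 21, 22)
SPLIT_VALIDATION <- c(2, 10)
SPLIT_TEST <- c(3, 11)

#' Chromosome-level split assignment
#'
#' Validation: chromosomes 2 and 10; test: 3 and 11; training: the other
#' 18 autosomes. Non-autosomes (X, Y, M) are excluded (`NA`). `"chr3"` and
#' `"3"` are equivalent.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector: `"train"`, `"validation"`, `"test"`, or `NA`.
#' @export
assign_split <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  out <- rep(NA_character_, length(chrom))
  out[num %in% SPLIT_TRAIN] <- "train"
  out[num %in% SPLIT_VALIDATION] <- "validation"
  out[num %in% SPLIT_TEST] <- "test"
  out
}

#' Label a peak set against a segmentation and assign splits
#'
#' Convenience wrapper over [annotate_peak()] and [assign_split()];
#' excluded peaks (ambiguous label or non-autosomal) are dropped.
#'
#' @inheritParams annotate_peak
#' @param peaks Peak data.frame.
#' @return Labeled-peak data.frame: peak columns plus `label`,
#'   `overlap_fraction`, `split`, `is_nonpeak_augmented`.
#' @export
label_peaks <- function(peaks, segmentation, scheme = "roadmap18",
                        threshold = 0.9) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  rows <- vector("list", nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    ann <- annotate_peak(peaks[k, ], segmentation, scheme, threshold)
    if (is.null(ann)) next
    row <- peaks[k, , drop = FALSE]
    row$label <- ann$label
    row$overlap_fraction <- ann$overlap_fraction
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(NULL)
  out$split <- assign_split(out$chrom)
  out <- out[!is.na(out$split), , drop = FALSE]
  out$is_nonpeak_augmented <- FALSE
  rownames(out) <- NULL
  out
}

#' Augment "other" examples with non-peak consensus regions
#'
#' Candidates are consensus peaks not called as a peak in the sample
#' (no interval overlap with the sample's own calls). A seeded uniform
#' subsample is drawn so that augmented examples are at most `cap` of all
#' "other" examples: n <= floor(P * cap / (1 - cap)) for P peak-derived
#' others. Augmented regions are always labeled "other".
#'
#' @param n_sample_other Number of peak-derived "other" examples in the
#'   sample (P above).
#' @param consensus_peaks Consensus peak data.frame.
#' @param sample_peaks The sample's own peak calls.
#' @param cap Maximum augmented fraction of all "other" examples, in
#'   (0, 1] (default 0.25).
#' @param seed Integer seed for the subsample.
#' @return Data.frame of augmented regions with `label = "other"` and
#'   `is_nonpeak_augmented = TRUE` (zero rows when no candidates).
#' @export
augment_nonpeak_other <- function(n_sample_other, consensus_peaks,
                                  sample_peaks, cap = 0.25, seed = 1L) {
  if (!(cap > 0 && cap <= 1))
    stop("cap must be in (0, 1]", call. = FALSE)
  overlaps_sample <- vapply(seq_len(nrow(consensus_peaks)), function(i) {
    p <- consensus_peaks[i, ]
    any(sample_peaks$chrom == p$chrom & sample_peaks$start < p$end &
          sample_peaks$end > p$start)
  }, logical(1))
  cand <- consensus_peaks[!overlaps_sample, , drop = FALSE]
  n_max <- floor(n_sample_other * cap / (1 - cap))
  n_take <- min(nrow(cand), n_max)
  if (n_take <= 0) {
    cand <- cand[0, , drop = FALSE]
  } else {
    set.seed(seed)
    cand <- cand[sort(sample.int(nrow(cand), n_take)), , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    cand$label <- "other"
    cand$overlap_fraction <- NA_real_
    cand$split <- assign_split(cand$chrom)
    cand$is_nonpeak_augmented <- TRUE
  }
  rownames(cand) <- NULL
  cand
}
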