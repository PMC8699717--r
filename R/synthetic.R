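# Synthetic fixtures: seeded reference sequences, class-archetype ATAC-seq
# fragment sets, consistent ChromHMM-like segmentations, and genotyped
# cohorts with planted gain/loss effects. Everything here is a pure
# function of (config, seed), so the whole pipeline is testable without
# downloads.
#
# The archetypes emulate the qualitative structure of real data: each
# class differs in accessibility amplitude, nucleosome-free-region width,
# and sub- vs mono-nucleosomal fragment-size mixture; the insulator
# archetype plants a CTCF consensus at the locus center and the promoter
# archetype registers a TSS there. They do not model GC bias, mappability
# or chimeric fragments.

# concrete instantiation of the CTCF IUPAC consensus planted in insulator
# reference sequence
CTCF_PLANT <- "CCGCGAGGTGGCAG"

#' Class-archetype fragment model parameters
#'
#' Fragment centers are normal around the locus center with spread
#' `pos_sd` (the nucleosome-free-region width); insert sizes come from a
#' two-component lognormal mixture (sub-nucleosomal mode < 147 bp,
#' mono-nucleosomal mode around 200 bp) with class-specific weights;
#' `depth` scales the expected fragment count; `qval_range` is the
#' -log10 q-value range the peak caller would report.
#'
#' @param class One of the four functional classes.
#' @export
archetype_config <- function(class = CLASS_LEVELS) {
  class <- match.arg(class)
  defaults <- list(
    promoter = list(depth = 400L, pos_sd = 80, sub_weight = 0.80,
                    sub_meanlog = log(80), sub_sdlog = 0.30,
                    mono_meanlog = log(200), mono_sdlog = 0.15,
                    qval_range = c(20, 50)),
    enhancer = list(depth = 250L, pos_sd = 60, sub_weight = 0.60,
                    sub_meanlog = log(90), sub_sdlog = 0.30,
                    mono_meanlog = log(200), mono_sdlog = 0.15,
                    qval_range = c(10, 30)),
    insulator = list(depth = 200L, pos_sd = 30, sub_weight = 0.75,
                     sub_meanlog = log(70), sub_sdlog = 0.25,
                     mono_meanlog = log(210), mono_sdlog = 0.15,
                     qval_range = c(8, 20)),
    other = list(depth = 80L, pos_sd = 150, sub_weight = 0.30,
                 sub_meanlog = log(100), sub_sdlog = 0.35,
                 mono_meanlog = log(210), mono_sdlog = 0.20,
                 qval_range = c(2, 6)))
  structure(c(list(class = class), defaults[[class]]),
            class = "archetype_config")
}

#' Generate a seeded random reference FASTA
#'
#' i.i.d. bases at a target GC content; deterministic per seed. The file
#' is indexed on write.
#'
#' @param seed Integer seed.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gc Target GC fraction in (0, 1).
#' @param path Output FASTA path.
#' @return The FASTA path, invisibly.
#' @export
gen_reference <- function(seed, contig_lengths, gc = 0.41,
                          path = tempfile(fileext = ".fa")) {
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)", call. = FALSE)
  stopifnot(all(contig_lengths >= 1), !is.null(names(contig_lengths)))
  set.seed(seed)
  seqs <- vapply(contig_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  .write_fasta(seqs, path)
  invisible(path)
}

.write_fasta <- function(named_seqs, path) {
  ss <- Biostrings::DNAStringSet(named_seqs)
  names(ss) <- names(named_seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  if (file.exists(paste0(path, ".fai"))) file.remove(paste0(path, ".fai"))
  Rsamtools::indexFa(path)
  path
}

# sample n insert lengths from an archetype's mixture
.sample_lengths <- function(arch, n) {
  sub <- stats::runif(n) < arch$sub_weight
  len <- numeric(n)
  len[sub] <- stats::rlnorm(sum(sub), arch$sub_meanlog, arch$sub_sdlog)
  len[!sub] <- stats::rlnorm(sum(!sub), arch$mono_meanlog,
                             arch$mono_sdlog)
  pmax(20L, as.integer(round(len)))
}

#' Generate fragments (and the peak call) for one archetype locus
#'
#' Samples `n_fragments` fragments with archetype positional and
#' insert-size distributions around the locus center. The returned peak
#' spans the central `peak_halfwidth * 2` bp with a class-typical
#' -log10 q-value.
#'
#' @param archetype An [archetype_config()] or class name.
#' @param chrom Contig name.
#' @param center Locus center (0-based).
#' @param n_fragments Number of fragments (default: archetype depth).
#' @param seed Optional seed (omit when already inside a seeded stream).
#' @param peak_halfwidth Half-width of the peak call (default 200).
#' @param name Peak name.
#' @return `list(fragments, peak)`.
#' @export
gen_peak_fragments <- function(archetype, chrom, center,
                               n_fragments = NULL, seed = NULL,
                               peak_halfwidth = 200L,
                               name = sprintf("%s_%d", chrom, center)) {
  if (is.character(archetype)) archetype <- archetype_config(archetype)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_fragments)) n_fragments <- archetype$depth
  mid <- round(stats::rnorm(n_fragments, center, archetype$pos_sd))
  len <- .sample_lengths(archetype, n_fragments)
  start <- pmax(0L, as.integer(mid - len %/% 2L))
  frags <- data.frame(chrom = chrom, start = start,
                      end = start + len,
                      is_duplicate = FALSE, barcode = NA_character_,
                      variants = ".")
  qv <- stats::runif(1, archetype$qval_range[1], archetype$qval_range[2])
  peak <- data.frame(chrom = chrom, start = center - peak_halfwidth,
                     end = center + peak_halfwidth, name = name,
                     neglog10_qval = qv,
                     summit_offset = as.integer(peak_halfwidth))
  list(fragments = frags, peak = peak)
}

# the scheme used by generated 4-class segmentations: the Roadmap-style
# states plus a CTCF insulator state (the public 18-state scheme carries
# no insulator)
#' Label scheme used by the synthetic segmentation generator
#' @export
synthetic_scheme <- function() {
  label_scheme("custom", map = c(ROADMAP18_MAP, "7_Ins" = "insulator"))
}

# state emitted for each planted class
.state_for_class <- function(scheme, class) {
  hits <- names(scheme$map)[scheme$map == class]
  if (length(hits) == 0)
    stop("scheme has no state mapping to class ", class, call. = FALSE)
  hits[1]
}

#' Generate a segmentation consistent with planted labels
#'
#' Each locus is fully covered by a state mapping to its planted class
#' (with `margin` bp of slack on each side); gaps are filled with the
#' scheme's quiescent-mapped ("other") state. Output is sorted and
#' non-overlapping.
#'
#' @param loci data.frame `chrom`, `start`, `end`, `class`
#'   (non-overlapping).
#' @param scheme A [label_scheme()]; default [synthetic_scheme()].
#' @param contig_lengths Named lengths used to close the final background
#'   segment.
#' @param margin Extra covered bp on each side of a locus (default 50).
#' @return Segmentation data.frame as from [read_segmentation()].
#' @export
gen_segmentation <- function(loci, scheme = synthetic_scheme(),
                             contig_lengths, margin = 50L) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  bg <- .state_for_class(scheme, "other")
  rows <- list()
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    s <- pmax(0L, sub$start - margin)
    e <- pmin(contig_lengths[[ch]], sub$end + margin)
    if (nrow(sub) > 1 && any(s[-1] < e[-nrow(sub)]))
      stop("overlapping loci on ", ch, call. = FALSE)
    pos <- 0L
    for (i in seq_len(nrow(sub))) {
      if (s[i] > pos)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = s[i], state_label = bg)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s[i], end = e[i],
        state_label = .state_for_class(scheme, sub$class[i]))
      pos <- e[i]
    }
    if (pos < contig_lengths[[ch]])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = contig_lengths[[ch]],
        state_label = bg)
  }
  out <- do.call(rbind, rows)
  out$scheme <- scheme$name
  rownames(out) <- NULL
  out
}

#' Generate a complete 4-class synthetic dataset
#'
#' Builds one contig per split (chr1 train, chr2 validation, chr3 test),
#' plants loci of the four classes at regular spacing (CTCF consensus in
#' the reference at insulator loci, a TSS registered at promoter loci),
#' samples archetype fragments, and emits the matching segmentation.
#'
#' @param n_train,n_validation,n_test Loci per split.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param spacing Distance between locus centers in bp (default 2000).
#' @param dir Output directory for the FASTA.
#' @param class_weights Sampling weights of the four classes.
#' @return List: `fasta`, `peaks` (with planted `label` and `split`),
#'   `fragments`, `segmentation`, `tss`, `contig_lengths`, `scheme`.
#' @export
gen_class_dataset <- function(n_train = 2000L, n_validation = 400L,
                              n_test = 400L, seed = 17L, spacing = 2000L,
                              dir = tempfile("synthdata"),
                              class_weights = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- c(train = n_train, validation = n_validation, test = n_test)
  contigs <- c(train = "chr1", validation = "chr2", test = "chr3")
  contig_lengths <- stats::setNames(
    as.integer(counts * spacing + spacing), unname(contigs))
  # reference bases first, then overwrite motif plants
  seqs <- vapply(contig_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.295, 0.205, 0.205, 0.295)), collapse = ""),
    character(1))
  peaks <- list()
  frags <- list()
  tss <- list()
  loci <- list()
  for (sp in names(counts)) {
    ch <- contigs[[sp]]
    n <- counts[[sp]]
    if (n == 0) next
    centers <- as.integer(spacing * seq_len(n) - spacing %/% 2L)
    classes <- sample(CLASS_LEVELS, n, replace = TRUE,
                      prob = class_weights)
    for (i in seq_len(n)) {
      cls <- classes[i]
      if (cls == "insulator") {
        at <- centers[i] - nchar(CTCF_PLANT) %/% 2L
        substr(seqs[[ch]], at + 1L, at + nchar(CTCF_PLANT)) <- CTCF_PLANT
      }
      if (cls == "promoter")
        tss[[length(tss) + 1L]] <- data.frame(chrom = ch,
                                              pos = centers[i])
      g <- gen_peak_fragments(cls, ch, centers[i],
                              name = sprintf("%s_%s_%d", sp, cls, i))
      g$peak$label <- cls
      g$peak$split <- sp
      peaks[[length(peaks) + 1L]] <- g$peak
      frags[[length(frags) + 1L]] <- g$fragments
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = g$peak$start, end = g$peak$end, class = cls)
    }
  }
  fasta <- file.path(dir, "reference.fa")
  .write_fasta(seqs, fasta)
  peaks <- do.call(rbind, peaks)
  fragments <- do.call(rbind, frags)
  fragments <- fragments[order(fragments$chrom, fragments$start), ]
  rownames(peaks) <- rownames(fragments) <- NULL
  loci <- do.call(rbind, loci)
  segmentation <- gen_segmentation(loci, synthetic_scheme(),
                                   contig_lengths)
  tss <- if (length(tss) > 0) do.call(rbind, tss)
  else data.frame(chrom = character(), pos = integer())
  list(fasta = fasta, peaks = peaks, fragments = fragments,
       segmentation = segmentation, tss = tss,
       contig_lengths = contig_lengths, scheme = synthetic_scheme())
}

#' Cohort configuration for genotype-effect simulations
#'
#' @param n_samples Cohort size (default 19, a typical islet cohort).
#' @param allele_freq Alternative-allele frequency.
#' @param effect_size Accessibility shift per alt allele, in population
#'   standard deviations of the per-locus fragment count.
#' @param base_depth Expected fragment count at a locus for genotype
#'   ref/ref.
#' @param seed Integer seed.
#' @export
cohort_config <- function(n_samples = 19L, allele_freq = 0.3,
                          effect_size = 1, base_depth = 200L,
                          seed = 1L) {
  stopifnot(n_samples >= 2, is.finite(effect_size),
            allele_freq > 0, allele_freq < 1, base_depth >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 allele_freq = allele_freq, effect_size = effect_size,
                 base_depth = as.integer(base_depth),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a genotyped cohort with planted gain/loss effects
#'
#' For each locus, each sample draws a genotype from the allele frequency;
#' its fragment count is Poisson with mean shifted by
#' `direction * effect_size * sqrt(base_depth)` per alt allele (so
#' `effect_size` is in population SDs of the null Poisson count), and the
#' alternative base is substituted into fragments covering the SNP with
#' probability dosage/2. Planted directions alternate gain/loss. A
#' reporter-assay (MPRA-style) log fold change concordant with the
#' planted direction is also drawn per locus.
#'
#' @param config A [cohort_config()].
#' @param loci data.frame `chrom`, `center` (SNP at the center); or an
#'   integer number of loci to place on one contig.
#' @param archetype Fragment archetype for all loci (default enhancer).
#' @return List: `scores` (locus, sample, genotype, dosage, score),
#'   `fragments` (per sample-locus fragment sets with variants),
#'   `genotypes` (locus x sample TSV-shaped table), `truth` (locus,
#'   direction, mpra_logfc), `config`.
#' @export
gen_genotyped_cohort <- function(config = cohort_config(), loci = 100L,
                                 archetype = "enhancer") {
  if (is.character(archetype)) archetype <- archetype_config(archetype)
  set.seed(config$seed)
  if (is.numeric(loci) && length(loci) == 1)
    loci <- data.frame(chrom = "chr1",
                       center = as.integer(2000L * seq_len(loci)))
  n_loci <- nrow(loci)
  loci$locus <- sprintf("locus_%03d", seq_len(n_loci))
  loci$direction <- rep(c("gain", "loss"), length.out = n_loci)
  dir_sign <- ifelse(loci$direction == "gain", 1, -1)
  loci$mpra_logfc <- stats::rnorm(n_loci, mean = 0.8 * dir_sign, sd = 0.4)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  shift <- config$effect_size * sqrt(config$base_depth)
  scores <- list()
  frag_rows <- list()
  geno <- matrix(NA_character_, n_loci, config$n_samples,
                 dimnames = list(loci$locus, samples))
  for (j in seq_len(n_loci)) {
    dosage <- stats::rbinom(config$n_samples, 2, config$allele_freq)
    geno[j, ] <- GENOTYPE_LEVELS[dosage + 1L]
    lam <- pmax(5, config$base_depth + dir_sign[j] * shift * dosage)
    for (s in seq_len(config$n_samples)) {
      nf <- stats::rpois(1, lam[s])
      g <- gen_peak_fragments(archetype, loci$chrom[j], loci$center[j],
                              n_fragments = nf)
      f <- g$fragments
      if (dosage[s] > 0 && nf > 0) {
        covers <- f$start <= loci$center[j] & f$end > loci$center[j]
        alt <- covers & stats::runif(nf) < dosage[s] / 2
        f$variants[alt] <- sprintf("%d:T", loci$center[j])
      }
      f$sample <- samples[s]
      f$locus <- loci$locus[j]
      frag_rows[[length(frag_rows) + 1L]] <- f
      scores[[length(scores) + 1L]] <- data.frame(
        locus = loci$locus[j], sample = samples[s],
        genotype = GENOTYPE_LEVELS[dosage[s] + 1L], dosage = dosage[s],
        score = nf / config$base_depth)
    }
  }
  list(scores = do.call(rbind, scores),
       fragments = do.call(rbind, frag_rows),
       genotypes = geno,
       truth = loci,
       config = config)
}
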