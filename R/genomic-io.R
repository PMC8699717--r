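# I/O for the standard formats the pipeline touches.
#
# Every coordinate inside the package is 0-based half-open (BED convention).
# 1-based formats (SAM POS, FASTA windows) are converted at the boundary and
# nowhere else.

CLASS_LEVELS <- c("promoter", "enhancer", "insulator", "other")

.stop_line <- function(path, i, msg) {
  stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
}

.check_intervals <- function(start, end, path, lines) {
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad) > 0)
    .stop_line(path, lines[bad[1]],
               "invalid interval (need 0 <= start < end)")
  invisible(NULL)
}

#' Read peak calls from narrowPeak or BED
#'
#' Reads MACS2-style narrowPeak (10 columns; column 9 is the -log10 FDR
#' q-value, column 10 the summit offset) or plain BED with at least 3
#' columns. `track`/`browser`/`#` header lines are skipped. Coordinates are
#' returned 0-based half-open, as stored in the file.
#'
#' @param path Path to the peak file.
#' @param dialect `"auto"` (by column count), `"narrowPeak"`, or `"bed3+"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `neglog10_qval` (NA when absent), `summit_offset` (NA when absent).
#' @export
read_peaks <- function(path, dialect = c("auto", "narrowPeak", "bed3+")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), neglog10_qval = numeric(),
                      summit_offset = integer()))
  }
  fields <- strsplit(raw, "[ \t]+")
  ncols <- lengths(fields)
  if (dialect == "auto")
    dialect <- if (all(ncols >= 10)) "narrowPeak" else "bed3+"
  need <- if (dialect == "narrowPeak") 10L else 3L
  short <- which(ncols < need)
  if (length(short) > 0)
    .stop_line(path, lines[short[1]],
               sprintf("expected >= %d fields for %s, found %d",
                       need, dialect, ncols[short[1]]))
  col <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- col(1)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  .check_intervals(start, end, path, lines)
  name <- if (all(ncols >= 4)) col(4) else sprintf("peak_%d", seq_along(chrom))
  if (dialect == "narrowPeak") {
    qval <- suppressWarnings(as.numeric(col(9)))
    bad <- which(is.na(qval) | qval < 0)
    if (length(bad) > 0)
      .stop_line(path, lines[bad[1]], "column 9 is not a -log10 q-value >= 0")
    summit <- suppressWarnings(as.integer(col(10)))
  } else {
    qval <- rep(NA_real_, length(chrom))
    summit <- rep(NA_integer_, length(chrom))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             neglog10_qval = qval, summit_offset = summit)
}

# parse "pos:base;pos:base" variant annotations (0-based positions)
.parse_variants <- function(x) {
  if (is.na(x) || x == "." || !nzchar(x)) return(NULL)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  pos <- vapply(kv, function(p) as.integer(p[1]), integer(1))
  base <- vapply(kv, function(p) toupper(p[2]), character(1))
  data.frame(pos = pos, base = base)
}

.format_variants <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(".")
  paste(sprintf("%d:%s", df$pos, df$base), collapse = ";")
}

.read_fragments_bed <- function(path, region, keep_duplicates) {
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  raw <- raw[keep]
  fields <- strsplit(raw, "[ \t]+")
  ncols <- lengths(fields)
  if (length(raw) > 0 && any(ncols < 3))
    .stop_line(path, lines[which(ncols < 3)[1]], "expected >= 3 fields")
  col <- function(i, default) {
    vapply(seq_along(fields), function(j) {
      if (ncols[j] >= i) fields[[j]][i] else default
    }, character(1))
  }
  chrom <- col(1, NA_character_)
  start <- suppressWarnings(as.integer(col(2, NA_character_)))
  end <- suppressWarnings(as.integer(col(3, NA_character_)))
  if (length(raw) > 0) .check_intervals(start, end, path, lines)
  barcode <- col(4, NA_character_)
  barcode[barcode == "."] <- NA_character_
  dup <- col(5, "0") %in% c("1", "T", "TRUE")
  variants <- col(6, ".")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    is_duplicate = dup, barcode = barcode,
                    variants = variants)
  if (!is.null(region))
    out <- out[out$chrom == region$chrom &
                 out$start < region$end & out$end > region$start, ,
               drop = FALSE]
  if (!keep_duplicates) out <- out[!out$is_duplicate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# expand a cigar string into per-op (op, len)
.parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

# mismatching base calls of one read against the reference.
# pos1: 1-based leftmost aligned position; returns 0-based genomic positions.
.read_mismatches <- function(pos1, cigar, seq, refseq) {
  cg <- .parse_cigar(cigar)
  rpos <- pos1
  qpos <- 1L
  out_pos <- integer(0)
  out_base <- character(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      qs <- substring(seq, qpos, qpos + len - 1L)
      rs <- substring(refseq, rpos - pos1 + 1L, rpos - pos1 + len)
      qb <- strsplit(qs, "")[[1]]
      rb <- strsplit(toupper(rs), "")[[1]]
      mm <- which(qb != rb & qb %in% c("A", "C", "G", "T"))
      if (length(mm) > 0) {
        out_pos <- c(out_pos, rpos - 1L + mm - 1L)  # to 0-based
        out_base <- c(out_base, qb[mm])
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
  }
  if (length(out_pos) == 0) return(NULL)
  data.frame(pos = out_pos, base = out_base)
}

.read_fragments_bam <- function(path, region, keep_duplicates, fasta) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "isize", "cigar", "seq")
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  if (!is.null(region)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index (.bai) required for region queries: ", path,
           call. = FALSE)
    which <- IRanges::IRangesList(
      IRanges::IRanges(region$start + 1L, region$end))
    names(which) <- region$chrom
    param <- Rsamtools::ScanBamParam(what = what, flag = flag, which = which)
    r <- Rsamtools::scanBam(bam, param = param)[[1]]
  } else {
    param <- Rsamtools::ScanBamParam(what = what, flag = flag)
    r <- Rsamtools::scanBam(bam, param = param)[[1]]
  }
  if (length(r$qname) == 0) {
    n_any <- Rsamtools::countBam(bam)$records
    if (is.null(region) && n_any > 0)
      stop("no properly-paired reads in ", path,
           "; for unpaired or pre-computed fragments use the fragments-BED ",
           "input instead", call. = FALSE)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), is_duplicate = logical(),
                      barcode = character(), variants = character()))
  }
  dup_read <- bitwAnd(r$flag, 1024L) > 0L
  # fragment = leftmost mate (isize > 0): [pos-1, pos-1+isize)
  left <- which(r$isize > 0L)
  frag <- data.frame(qname = r$qname[left],
                     chrom = as.character(r$rname[left]),
                     start = r$pos[left] - 1L,
                     end = r$pos[left] - 1L + r$isize[left])
  # duplicate if either mate flagged
  dup_by_qname <- tapply(dup_read, r$qname, any)
  frag$is_duplicate <- as.logical(dup_by_qname[frag$qname])
  frag$barcode <- NA_character_
  # genotype-aware calls: recover per-fragment substitutions from mismatches
  if (!is.null(fasta)) {
    seqs <- as.character(r$seq)
    ref_ends <- vapply(seq_along(r$pos), function(i) {
      cg <- .parse_cigar(r$cigar[i])
      r$pos[i] + sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")]) - 1L
    }, integer(1))
    mm_by_qname <- new.env(parent = emptyenv())
    for (i in seq_along(r$pos)) {
      refseq <- read_reference_window(fasta, as.character(r$rname[i]),
                                      r$pos[i] - 1L, ref_ends[i])
      mm <- .read_mismatches(r$pos[i], r$cigar[i], seqs[i], refseq)
      if (!is.null(mm)) {
        prev <- mm_by_qname[[r$qname[i]]]
        mm_by_qname[[r$qname[i]]] <- rbind(prev, mm)
      }
    }
    frag$variants <- vapply(frag$qname, function(q) {
      mm <- mm_by_qname[[q]]
      if (is.null(mm)) "." else .format_variants(unique(mm))
    }, character(1))
  } else {
    frag$variants <- "."
  }
  frag$qname <- NULL
  if (!is.null(region))
    frag <- frag[frag$chrom == region$chrom &
                   frag$start < region$end & frag$end > region$start, ,
                 drop = FALSE]
  if (!keep_duplicates) frag <- frag[!frag$is_duplicate, , drop = FALSE]
  frag <- frag[order(frag$chrom, frag$start, frag$end), , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

#' Read paired-end fragments from BAM/SAM or a fragments BED
#'
#' From alignments, one fragment per properly-paired read pair spanning the
#' full insert (leftmost mate start to leftmost start + template length);
#' secondary, supplementary and unmapped records are excluded, and
#' duplicate-flagged pairs are dropped unless `keep_duplicates`. As an
#' alternative, a plain fragments BED dialect is accepted with columns
#' `chrom start end [barcode] [dup01] [variants]`, where `variants` lists
#' per-fragment base substitutions as `pos:base;...` (0-based positions,
#' `"."` for none) — this is how genotype-aware base calls travel without a
#' BAM file.
#'
#' @param path BAM, SAM, or fragments-BED file.
#' @param region Optional `list(chrom=, start=, end=)` (0-based half-open);
#'   fragments overlapping the region are returned. BAM region queries
#'   require a `.bai` index.
#' @param keep_duplicates Keep duplicate-flagged fragments (as done for
#'   aggregated single-nucleus data); default drops them.
#' @param fasta Optional indexed FASTA; in BAM mode, read-vs-reference
#'   mismatches are recorded as per-fragment substitutions.
#' @return data.frame `chrom`, `start`, `end`, `is_duplicate`, `barcode`,
#'   `variants`.
#' @export
read_fragments <- function(path, region = NULL, keep_duplicates = FALSE,
                           fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(bam|sam)$", path, ignore.case = TRUE))
    .read_fragments_bam(path, region, keep_duplicates, fasta)
  else
    .read_fragments_bed(path, region, keep_duplicates)
}

#' Fetch an uppercase reference window, N-padded at contig edges
#'
#' @param fasta Path to an indexed FASTA (a `.fai` is created if missing).
#' @param chrom Contig name (must exist in the FASTA).
#' @param start,end 0-based half-open window; positions outside the contig
#'   are returned as `N`.
#' @return Character string of length `end - start`.
#' @export
read_reference_window <- function(fasta, chrom, start, end) {
  stopifnot(end > start)
  lens <- .contig_lengths(fasta)
  if (!chrom %in% names(lens))
    stop("contig not in reference: ", chrom, call. = FALSE)
  clen <- lens[[chrom]]
  s <- max(start, 0L)
  e <- min(end, clen)
  core <- ""
  if (e > s) {
    fa <- Rsamtools::FaFile(fasta)
    param <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e))
    core <- toupper(as.character(Rsamtools::scanFa(fa, param = param)[[1]]))
  }
  paste0(strrep("N", s - start), core, strrep("N", end - e))
}

# closure that fetches windows from whole contigs loaded once (bulk
# encoders touch thousands of windows; per-window FASTA queries dominate
# otherwise). Same N-padding/uppercasing semantics as
# read_reference_window.
.reference_fetcher <- function(fasta) {
  lens <- .contig_lengths(fasta)
  seqs <- new.env(parent = emptyenv())
  function(chrom, start, end) {
    if (!chrom %in% names(lens))
      stop("contig not in reference: ", chrom, call. = FALSE)
    if (is.null(seqs[[chrom]])) {
      fa <- Rsamtools::FaFile(fasta)
      param <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(1L, lens[[chrom]]))
      seqs[[chrom]] <- toupper(as.character(
        Rsamtools::scanFa(fa, param = param)[[1]]))
    }
    clen <- lens[[chrom]]
    s <- max(start, 0L)
    e <- min(end, clen)
    core <- if (e > s) substring(seqs[[chrom]], s + 1L, e) else ""
    paste0(strrep("N", s - start), core, strrep("N", end - e))
  }
}

.fai_cache <- new.env(parent = emptyenv())

.contig_lengths <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  key <- paste0(normalizePath(fasta), "#",
                file.mtime(paste0(fasta, ".fai")))
  if (!is.null(.fai_cache[[key]])) return(.fai_cache[[key]])
  fai <- utils::read.table(paste0(fasta, ".fai"), sep = "\t",
                           stringsAsFactors = FALSE)
  lens <- stats::setNames(fai[[2]], fai[[1]])
  .fai_cache[[key]] <- lens
  lens
}

#' Read a ChromHMM-style segmentation (BED4+)
#'
#' Records are sorted by (chrom, start); overlapping records within a
#' chromosome are an error, since a segmentation assigns one state per
#' interval.
#'
#' @param path BED file with the state label in column 4.
#' @param scheme Optional label-scheme identifier carried along.
#' @return data.frame `chrom`, `start`, `end`, `state_label`, `scheme`.
#' @export
read_segmentation <- function(path, scheme = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  raw <- raw[keep]
  fields <- strsplit(raw, "[ \t]+")
  ncols <- lengths(fields)
  if (length(raw) > 0 && any(ncols < 4))
    .stop_line(path, lines[which(ncols < 4)[1]], "expected >= 4 fields")
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  state <- vapply(fields, `[`, character(1), 4)
  if (length(raw) > 0) .check_intervals(start, end, path, lines)
  if (any(!nzchar(state)))
    .stop_line(path, lines[which(!nzchar(state))[1]], "empty state label")
  o <- order(chrom, start)
  out <- data.frame(chrom = chrom[o], start = start[o], end = end[o],
                    state_label = state[o], scheme = scheme)
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop(path, ": overlapping segmentation records on ", ch, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write per-peak class probabilities as TSV
#'
#' Columns: chrom, start, end, name, prob_promoter, prob_enhancer,
#' prob_insulator, prob_other, label (argmax class); probabilities with 6
#' decimals. Rows whose probabilities do not sum to 1 within 1e-6 are
#' rejected.
#'
#' @param records data.frame with `chrom`, `start`, `end`, `name` and the
#'   four `prob_*` columns (a `label` column, if present, is recomputed).
#' @param path Output path.
#' @export
write_predictions <- function(records, path) {
  pcols <- paste0("prob_", CLASS_LEVELS)
  stopifnot(all(c("chrom", "start", "end", "name", pcols) %in%
                  names(records)))
  probs <- as.matrix(records[, pcols])
  if (any(probs < 0 | probs > 1) ||
      any(abs(rowSums(probs) - 1) > 1e-6))
    stop("class probabilities must lie in [0,1] and sum to 1 within 1e-6",
         call. = FALSE)
  label <- CLASS_LEVELS[max.col(probs, ties.method = "first")]
  out <- data.frame(chrom = records$chrom, start = records$start,
                    end = records$end, name = records$name)
  for (j in seq_along(pcols)) out[[pcols[j]]] <- sprintf("%.6f", probs[, j])
  out$label <- label
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#' @param path Predictions TSV.
#' @return data.frame with numeric probability columns and `label`.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
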