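# Genotype-modulated gain/loss of cis-regulatory activity: a per-locus
# point-biserial screen over per-sample activity scores, plus concordance
# tests against reporter-assay (MPRA) log fold changes.

GENOTYPE_LEVELS <- c("ref/ref", "ref/alt", "alt/alt")

#' Regulatory activity score of a prediction
#'
#' The sum of the promoter and enhancer probabilities.
#'
#' @param probs Length-4 probability vector, or an n x 4 matrix with
#'   columns ordered promoter, enhancer, insulator, other.
#' @export
activity_score <- function(probs) {
  if (is.matrix(probs)) probs[, 1] + probs[, 2]
  else probs[1] + probs[2]
}

#' Point-biserial correlation with a one-tailed p-value
#'
#' Pearson correlation of scores against the 0/1 group coding, with
#' `t = r * sqrt((n - 2) / (1 - r^2))` and the upper-tail p-value for the
#' alternative that group 1 scores higher. Swapping the coding flips the
#' sign of r and mirrors p to 1 - p. Constant scores give r = 0, p = 0.5.
#'
#' @param group 0/1 (or logical) group coding; both groups non-empty.
#' @param scores Numeric scores, same length, n >= 3.
#' @return `list(r, p, n)`.
#' @export
point_biserial <- function(group, scores) {
  group <- as.numeric(group)
  stopifnot(length(group) == length(scores), all(group %in% c(0, 1)))
  n <- length(group)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(group)) < 2)
    stop("both groups must be non-empty", call. = FALSE)
  if (stats::sd(scores) == 0) return(list(r = 0, p = 0.5, n = n))
  r <- stats::cor(scores, group)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- stats::pt(t, df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Strongest genotype-pair correlation at a locus
#'
#' Evaluates the point-biserial correlation for every pair of genotype
#' groups present (the higher-alt-dosage group coded 1) and returns the
#' pairing attaining the maximum |r|; ties go to the pairing with the
#' larger combined n. The reported p is one-tailed in the direction of the
#' observed correlation (min of the two orientations).
#'
#' @param genotype Character vector in `ref/ref`, `ref/alt`, `alt/alt`
#'   (or dosages 0/1/2).
#' @param scores Per-sample activity scores.
#' @return `list(r, p, pairing, n)`.
#' @export
max_genotype_correlation <- function(genotype, scores) {
  if (is.numeric(genotype)) genotype <- GENOTYPE_LEVELS[genotype + 1L]
  stopifnot(all(genotype %in% GENOTYPE_LEVELS),
            length(genotype) == length(scores))
  present <- GENOTYPE_LEVELS[GENOTYPE_LEVELS %in% genotype]
  if (length(present) < 2)
    stop("need at least 2 genotype groups", call. = FALSE)
  pairs <- utils::combn(present, 2, simplify = FALSE)
  best <- NULL
  for (pr in pairs) {
    keep <- genotype %in% pr
    if (sum(keep) < 3) next
    # pr is ordered by increasing alt dosage; code the higher-dosage group 1
    g <- as.numeric(genotype[keep] == pr[2])
    pb <- point_biserial(g, scores[keep])
    cand <- list(r = pb$r, p = min(pb$p, 1 - pb$p),
                 pairing = paste(pr, collapse = " vs "), n = pb$n)
    if (is.null(best) || abs(cand$r) > abs(best$r) ||
        (abs(cand$r) == abs(best$r) && cand$n > best$n))
      best <- cand
  }
  if (is.null(best))
    stop("no genotype pairing with at least 3 samples", call. = FALSE)
  best
}

#' Gain/loss call from a correlation and its p-value
#'
#' `loss` for significant negative correlations (alt allele lowers
#' activity), `gain` for significant positive ones, `none` otherwise.
#'
#' @param r Correlation in [-1, 1].
#' @param p One-tailed p-value.
#' @param alpha Significance threshold (default 0.01).
#' @return `"loss"`, `"gain"`, or `"none"` (vectorized).
#' @export
classify_gain_loss <- function(r, p, alpha = 0.01) {
  out <- rep("none", length(r))
  out[p < alpha & r < 0] <- "loss"
  out[p < alpha & r > 0] <- "gain"
  out
}

#' Screen many loci for genotype-modulated activity
#'
#' @param data data.frame with columns `locus`, `genotype`, `score` (one
#'   row per sample per locus).
#' @param alpha Significance threshold for the direction call.
#' @return data.frame: `locus`, `r`, `p`, `pairing`, `n`, `direction`.
#' @export
screen_effects <- function(data, alpha = 0.01) {
  stopifnot(all(c("locus", "genotype", "score") %in% names(data)))
  loci <- unique(data$locus)
  rows <- lapply(loci, function(l) {
    d <- data[data$locus == l, ]
    res <- tryCatch(max_genotype_correlation(d$genotype, d$score),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(locus = l, r = res$r, p = res$p, pairing = res$pairing,
               n = res$n,
               direction = classify_gain_loss(res$r, res$p, alpha))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' MPRA concordance tests for predicted loss/gain groups
#'
#' One-sided one-sample t-tests per group (loss: mean log fold change
#' below 0; gain: above 0) and a two-sided Mann-Whitney U test between the
#' two groups. Tests with too few observations are reported as `NA`.
#'
#' @param loss_logfc MPRA log fold changes of loci called `loss`.
#' @param gain_logfc MPRA log fold changes of loci called `gain`.
#' @return `list(p_loss, p_gain, p_between)`.
#' @export
mpra_concordance <- function(loss_logfc, gain_logfc) {
  safe_t <- function(x, alternative) {
    if (length(x) < 2) return(NA_real_)
    tryCatch(stats::t.test(x, mu = 0,
                           alternative = alternative)$p.value,
             error = function(e) NA_real_)  # degenerate (constant) group
  }
  p_loss <- safe_t(loss_logfc, "less")
  p_gain <- safe_t(gain_logfc, "greater")
  p_between <- if (length(loss_logfc) >= 1 && length(gain_logfc) >= 1)
    stats::wilcox.test(loss_logfc, gain_logfc)$p.value
  else NA_real_
  list(p_loss = p_loss, p_gain = p_gain, p_between = p_between)
}
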