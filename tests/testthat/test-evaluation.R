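# independent average-precision oracle: direct set counting per distinct
# threshold, step-integrated over recall
ap_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    p <- sum(labels[sel]) / sum(sel)
    r <- sum(labels[sel]) / pos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

classes4 <- functional_classes()

test_that("perfect predictions score 1 on every summary metric", {
  set.seed(2)
  truth <- sample(classes4, 50, TRUE)
  probs <- outer(truth, classes4, `==`) * 1
  m <- compute_metrics(truth, probs)
  expect_equal(m$accuracy, 1)
  expect_equal(m$micro_f1, 1)
  expect_equal(m$micro_average_precision, 1)
  expect_equal(m$mcc, 1)
  expect_equal(sum(m$confusion), 50)
})

test_that("multiclass MCC reduces to the binary closed form", {
  # binary toy confusion TP=8, FP=2, FN=1, TN=9 embedded in two classes
  truth <- c(rep("enhancer", 9), rep("other", 11))
  pred <- c(rep("enhancer", 8), "other",            # 8 TP, 1 FN
            rep("enhancer", 2), rep("other", 9))    # 2 FP, 9 TN
  probs <- outer(pred, classes4, `==`) * 1
  m <- compute_metrics(truth, probs)
  tp <- 8; fp <- 2; fn <- 1; tn <- 9
  closed <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(m$mcc, closed, tolerance = 1e-12)
})

test_that("average precision matches enumeration and null prevalence", {
  set.seed(31)
  labels <- rbinom(300, 1, 0.3)
  scores <- round(runif(300), 2)  # forces ties
  expect_equal(atacre:::.average_precision(labels, scores),
               ap_oracle(labels, scores), tolerance = 1e-12)
  # uniform random scores: micro-AP close to prevalence
  n <- 10000
  truth <- sample(classes4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  probs <- matrix(runif(n * 4), n)
  probs <- probs / rowSums(probs)
  m <- compute_metrics(truth, probs)
  expect_lt(abs(m$micro_average_precision - 0.25), 0.02)
})

test_that("micro-F1 equals accuracy for single-label multiclass", {
  set.seed(13)
  for (i in 1:5) {
    truth <- sample(classes4, 200, TRUE)
    probs <- matrix(runif(800), 200)
    probs <- probs / rowSums(probs)
    m <- compute_metrics(truth, probs)
    expect_equal(m$micro_f1, m$accuracy, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to example order; degenerate AUC is NA", {
  set.seed(14)
  truth <- sample(classes4[1:3], 100, TRUE)  # "other" absent
  probs <- matrix(runif(400), 100)
  probs <- probs / rowSums(probs)
  m1 <- compute_metrics(truth, probs)
  o <- sample.int(100)
  m2 <- compute_metrics(truth[o], probs[o, ])
  expect_equal(m1$confusion, m2$confusion)
  expect_equal(m1$micro_average_precision, m2$micro_average_precision)
  expect_equal(m1$mcc, m2$mcc)
  expect_true(is.na(m1$per_class$roc_auc[4]))
  expect_false(anyNA(m1$per_class$roc_auc[-4]))
})

test_that("ROC AUC matches the pairwise-comparison definition", {
  set.seed(15)
  lab <- rbinom(60, 1, 0.4)
  sc <- round(rnorm(60), 1)
  pos <- sc[lab == 1]
  neg <- sc[lab == 0]
  pairs <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(atacre:::.roc_auc(lab, sc), mean(pairs),
               tolerance = 1e-12)
})

test_that("naive baseline applies thresholds with promoter priority", {
  th <- naive_thresholds()  # 2kb, 0.001, >0
  expect_equal(naive_classify(1500, 1e-6, 3, th)$label, "promoter")
  expect_equal(naive_classify(10000, 1e-6, 1, th)$label, "insulator")
  expect_equal(naive_classify(10000, 1e-4, 0, th)$label, "enhancer")
  # qval above threshold -> other
  th2 <- naive_thresholds(qval_threshold = 0.001)
  expect_equal(naive_classify(10000, 0.01, 0, th2)$label, "other")
  # -log10 input accepted with the flag
  expect_equal(naive_classify(10000, 4, 0, th, qval_is_neglog10 = TRUE)$label,
               "enhancer")
  # probabilities are hard 0/1 and rows sum to 1
  r <- naive_classify(c(100, 9000), c(1e-5, 0.5), c(0, 2), th)
  expect_true(all(r$probs %in% c(0, 1)))
  expect_equal(rowSums(r$probs), c(1, 1))
  # priority is total: promoter rule wins regardless of other inputs
  set.seed(16)
  d <- runif(50, 0, 2000)
  r2 <- naive_classify(d, runif(50), sample(0:6, 50, TRUE), th)
  expect_true(all(r2$label == "promoter"))
  expect_error(naive_classify(10000, NA, 0, th), "q-value")
})

test_that("fisher_overlap equals hypergeometric enumeration", {
  bg <- sprintf("p%d", 1:20)
  pred <- bg[1:10]
  ref <- bg[1:10]
  res <- fisher_overlap(pred, ref, bg)
  # exhaustive hypergeometric two-sided p for table [[10,0],[0,10]]
  enum_p <- function(a, m, n, k) {
    probs <- dhyper(0:min(m, k), m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(res$p_value, enum_p(10, 10, 10, 10), tolerance = 1e-10)
  # random tables against the enumeration oracle
  set.seed(18)
  for (i in 1:5) {
    bg2 <- sprintf("q%d", 1:40)
    p2 <- sample(bg2, 15)
    r2 <- sample(bg2, 12)
    a <- length(intersect(p2, r2))
    got <- fisher_overlap(p2, r2, bg2)
    expect_equal(got$p_value, enum_p(a, 12, 28, 15), tolerance = 1e-10)
  }
  # proportional margins: odds ratio 1, no association
  bg3 <- sprintf("r%d", 1:100)
  p3 <- bg3[1:50]
  r3 <- bg3[c(1:25, 51:75)]
  res3 <- fisher_overlap(p3, r3, bg3)
  expect_equal(res3$odds_ratio, 1)
  expect_error(fisher_overlap("a", "a", character(0)), "background")
})
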