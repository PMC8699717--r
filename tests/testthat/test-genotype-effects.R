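test_that("activity score is the promoter + enhancer probability mass", {
  expect_equal(activity_score(c(0.6, 0.3, 0.05, 0.05)), 0.9)
  expect_equal(activity_score(c(0, 0, 0.5, 0.5)), 0)
  m <- matrix(c(0.25, 0.25, 0.25, 0.25,
                0.1, 0.2, 0.3, 0.4), 2, byrow = TRUE)
  expect_equal(activity_score(m), c(0.5, 0.3))
  set.seed(3)
  p <- matrix(runif(40), 10)
  p <- p / rowSums(p)
  expect_true(all(activity_score(p) >= 0 & activity_score(p) <= 1))
})

test_that("point-biserial equals dummy-coded Pearson with t-tail p", {
  # identical scores in both groups: r = 0, p = 0.5
  expect_equal(point_biserial(c(0, 0, 1, 1), c(2, 2, 2, 2)),
               list(r = 0, p = 0.5, n = 4))
  # perfectly separated groups
  pb <- point_biserial(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_equal(abs(pb$r), 1)
  expect_equal(pb$p, 0)
  # random vectors against the cor + pt oracle
  set.seed(23)
  for (i in 1:10) {
    g <- c(rep(0, 7), rep(1, 8))[sample.int(15)]
    s <- rnorm(15)
    pb <- point_biserial(g, s)
    r <- cor(s, g)
    t <- r * sqrt(13 / (1 - r^2))
    expect_equal(pb$r, r, tolerance = 1e-12)
    expect_equal(pb$p, pt(t, 13, lower.tail = FALSE), tolerance = 1e-10)
    # affine transforms of scores leave |r| and p unchanged
    pb2 <- point_biserial(g, 3 * s + 7)
    expect_equal(pb2$r, pb$r, tolerance = 1e-12)
    expect_equal(pb2$p, pb$p, tolerance = 1e-12)
    # swapping the coding flips r and mirrors p
    pb3 <- point_biserial(1 - g, s)
    expect_equal(pb3$r, -pb$r, tolerance = 1e-12)
    expect_equal(pb3$p, 1 - pb$p, tolerance = 1e-10)
  }
  expect_error(point_biserial(c(0, 0, 0), c(1, 2, 3)), "non-empty")
})

test_that("max_genotype_correlation scans genotype pairings", {
  # only two groups present: exactly that pairing
  g2 <- c("ref/ref", "ref/ref", "ref/ref", "alt/alt", "alt/alt",
          "alt/alt")
  s2 <- c(1, 2, 1.5, 5, 6, 5.5)
  r2 <- max_genotype_correlation(g2, s2)
  expect_equal(r2$pairing, "ref/ref vs alt/alt")
  expect_gt(r2$r, 0.9)
  # monotone dosage effect: the extreme pairing attains max |r|
  # (enumeration over the three pairings confirms below)
  set.seed(24)
  dos <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  sc <- dos + rnorm(9, sd = 0.2)
  r3 <- max_genotype_correlation(dos, sc)
  expect_equal(r3$pairing, "ref/ref vs alt/alt")
  expect_gt(r3$r, 0.9)
  # three groups: the best of the three pairings is returned
  set.seed(25)
  g <- rep(c("ref/ref", "ref/alt", "alt/alt"), each = 6)
  s <- rnorm(18) + rep(c(0, 1, 2), each = 6)
  best <- max_genotype_correlation(g, s)
  all_r <- sapply(list(c("ref/ref", "ref/alt"), c("ref/ref", "alt/alt"),
                       c("ref/alt", "alt/alt")), function(pr) {
    keep <- g %in% pr
    cor(s[keep], as.numeric(g[keep] == pr[2]))
  })
  expect_equal(abs(best$r), max(abs(all_r)), tolerance = 1e-12)
  expect_error(max_genotype_correlation(rep("ref/ref", 5), rnorm(5)),
               "2 genotype groups")
})

test_that("gain/loss classification applies sign and alpha", {
  expect_equal(classify_gain_loss(-0.8, 0.005), "loss")
  expect_equal(classify_gain_loss(0.9, 0.02), "none")
  expect_equal(classify_gain_loss(0.7, 0.001), "gain")
  expect_equal(classify_gain_loss(c(-0.5, 0.5, 0.1),
                                  c(0.001, 0.001, 0.5)),
               c("loss", "gain", "none"))
})

test_that("MPRA concordance matches hand-computed test statistics", {
  loss <- c(-1.2, -0.4, -0.9, -0.25, -1.5, 0.1, -0.6)
  gain <- c(0.8, 1.1, 0.3, 0.9, 1.4, -0.2, 0.7, 0.5)
  res <- mpra_concordance(loss, gain)
  # hand-rolled one-sample t, lower tail
  t_loss <- mean(loss) / (sd(loss) / sqrt(length(loss)))
  expect_equal(res$p_loss, pt(t_loss, length(loss) - 1),
               tolerance = 1e-10)
  t_gain <- mean(gain) / (sd(gain) / sqrt(length(gain)))
  expect_equal(res$p_gain, pt(t_gain, length(gain) - 1,
                              lower.tail = FALSE), tolerance = 1e-10)
  # hand-rolled exact Mann-Whitney U (no ties here)
  U <- sum(outer(loss, gain, `>`))
  n1 <- length(loss)
  n2 <- length(gain)
  p_exact <- 2 * min(pwilcox(U, n1, n2),
                     pwilcox(U - 1, n1, n2, lower.tail = FALSE))
  expect_equal(res$p_between, min(1, p_exact), tolerance = 1e-10)
  # extreme case: all-positive gain group rejects
  set.seed(41)
  allpos <- runif(10, 0.2, 1)
  expect_lt(mpra_concordance(numeric(0), allpos)$p_gain, 0.05)
  expect_true(is.na(mpra_concordance(numeric(0), allpos)$p_loss))
})

test_that("identically distributed groups rarely reject (null behavior)", {
  rejections <- 0L
  n_rep <- 100L
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    a <- rnorm(20)
    b <- rnorm(20)
    if (mpra_concordance(a, b)$p_between <= 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, n_rep / 10)  # null retained >= 90% of the time
})

test_that("screen_effects produces one direction call per locus", {
  set.seed(33)
  co <- gen_genotyped_cohort(cohort_config(n_samples = 19, seed = 4),
                             loci = 12)
  res <- screen_effects(co$scores)
  expect_equal(sort(res$locus), sort(unique(co$scores$locus)))
  expect_true(all(res$direction %in% c("gain", "loss", "none")))
  expect_true(all(res$p >= 0 & res$p <= 0.5 + 1e-12))
})
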