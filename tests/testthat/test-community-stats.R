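test_that("wisconsin double standardization matches step-by-step arithmetic", {
  expect_equal(wisconsin(matrix(5)), matrix(1))
  x <- metawax:::with_seed(71, matrix(runif(12, 0, 10), 3, 4,
    dimnames = list(paste0("s", 1:3), paste0("o", 1:4))))
  w <- wisconsin(x)
  # oracle arithmetic, spelled out
  step1 <- x
  for (j in 1:4) step1[, j] <- x[, j] / max(x[, j])
  step2 <- step1
  for (i in 1:3) step2[i, ] <- step1[i, ] / sum(step1[i, ])
  expect_equal(w, step2)
  expect_equal(unname(rowSums(w)), rep(1, 3))
  expect_equal(unname(apply(step1, 2, max)), rep(1, 4))
  bad <- x
  bad[, 2] <- 0
  expect_error(wisconsin(bad), "o2")
  # cross-check against the reference implementation
  expect_equal(unclass(w), unclass(vegan::wisconsin(x)), ignore_attr = TRUE)
})

test_that("bray_curtis follows its formula and bounds", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)
  disj <- rbind(a = c(1, 0), b = c(0, 2))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  y <- metawax:::with_seed(72, matrix(runif(40), 5, 8))
  expect_equal(lowerv <- bray_curtis(y)[lower.tri(diag(5))],
               as.vector(vegan::vegdist(y, "bray")))
})

test_that("nmds embeds exact configurations at ~zero stress with a monotone trace", {
  # 4 points with exactly planar Euclidean dissimilarities
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  d <- as.matrix(stats::dist(pts))
  fit <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_lte(fit$stress, 1e-3)
  expect_true(all(diff(fit$stress_trace) <= 1e-12))
  expect_equal(unname(colMeans(fit$points)), c(0, 0))  # centered
  # k = n - 1 embeds any metric input
  y <- metawax:::with_seed(73, matrix(runif(30), 6, 5))
  d6 <- as.matrix(stats::dist(y))
  fit6 <- nmds(d6, k = 5, n_starts = 5, seed = 3)
  expect_lte(fit6$stress, 1e-3)
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("nmds separates planted groups and vegan finds no better stress", {
  centers <- rbind(c(0, 0), c(10, 10))
  pts <- metawax:::with_seed(74, {
    rbind(centers[rep(1, 6), ] + matrix(rnorm(12, sd = 0.4), 6),
          centers[rep(2, 6), ] + matrix(rnorm(12, sd = 0.4), 6))
  })
  rownames(pts) <- paste0("s", 1:12)
  d <- as.matrix(stats::dist(pts))
  fit <- nmds(d, k = 2, n_starts = 10, seed = 4)
  expect_lt(fit$stress, 0.05)
  grp <- rep(c("A", "B"), each = 6)
  within_spread <- max(stats::dist(fit$points[grp == "A", ])) +
    max(stats::dist(fit$points[grp == "B", ]))
  between <- sqrt(sum((colMeans(fit$points[grp == "A", ]) -
                         colMeans(fit$points[grp == "B", ]))^2))
  expect_gt(between, within_spread)
  ref <- vegan::monoMDS(stats::as.dist(d), k = 2)
  expect_lt(fit$stress, ref$stress + 0.02)
})

test_that("anosim attains R = 1 on complete separation and matches enumeration", {
  centers <- rbind(c(0, 0), c(10, 10))
  pts <- metawax:::with_seed(75, rbind(
    centers[rep(1, 3), ] + matrix(rnorm(6, sd = 0.3), 3),
    centers[rep(2, 3), ] + matrix(rnorm(6, sd = 0.3), 3)))
  d <- as.matrix(stats::dist(pts))
  grp <- rep(c("A", "B"), each = 3)
  res <- anosim(d, grp, exact = TRUE)
  expect_equal(unname(res$statistic), 1)
  orc <- anosim_enumeration_oracle(d, grp)
  expect_equal(unname(res$statistic), orc$R)
  expect_equal(res$p.value, orc$p)
  # the complement labelling reproduces the same partition, hence 2/20
  expect_equal(res$p.value, 0.1)
  # statistic agrees with the reference implementation
  ref <- vegan::anosim(stats::as.dist(d), grp, permutations = 0)
  expect_equal(unname(res$statistic), unname(ref$statistic))
  # near-zero R for exchangeable data, permutation p reproducible under seed
  d2 <- metawax:::with_seed(76, as.matrix(stats::dist(matrix(rnorm(16), 8))))
  g2 <- rep(c("A", "B"), 4)
  r1 <- anosim(d2, g2, n_perm = 199, seed = 5)
  r2 <- anosim(d2, g2, n_perm = 199, seed = 5)
  expect_equal(r1$p.value, r2$p.value)
  expect_gte(r1$p.value, 1 / 200)
  expect_lt(abs(unname(r1$statistic)), 0.5)
  expect_error(anosim(d, c("A", "A", "A", "A", "A", "B")), "2 members")
})

test_that("mann_whitney exact p agrees with full enumeration", {
  # the printed 3-vs-3 complete-separation case: one-sided p = 1/20
  mw <- mann_whitney(c(1.9, 1.7, 1.8), c(0.7, 0.61, 0.9), "greater")
  expect_true(mw$exact)
  expect_equal(mw$p.value, 0.05)
  # enumeration across sizes and alternatives (tie-free)
  metawax:::with_seed(77, {
    for (i in 1:12) {
      n1 <- sample(2:4, 1)
      n2 <- sample(2:4, 1)
      x <- round(rnorm(n1), 6)
      y <- round(rnorm(n2, 0.5), 6)
      for (alt in c("two.sided", "greater", "less")) {
        expect_equal(mann_whitney(x, y, alt)$p.value,
                     mw_enumeration_oracle(x, y, alt),
                     info = paste(i, alt))
      }
    }
  })
  # elementwise-identical samples: two-sided p = 1 under midranks
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # cross-check the tie-corrected approximation against the reference
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 2, 4, 5, 6, 8, 8)
  ours <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(unname(ours$statistic), unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon_signed_rank matches an independent formula oracle", {
  metawax:::with_seed(78, {
    x <- rnorm(10)
    y <- rnorm(10)
    got <- wilcoxon_signed_rank(x, y)
    orc <- wsr_formula_oracle(x, y)
    expect_equal(unname(got$statistic["V"]), orc$V, tolerance = 1e-12)
    expect_equal(unname(got$statistic["Z"]), orc$Z, tolerance = 1e-12)
    expect_equal(got$p.value, orc$p, tolerance = 1e-12)
  })
  # one-directional shift: strongly negative Z, p < 0.001
  x <- seq(1, 30)
  sh <- wilcoxon_signed_rank(x, x + 3)
  expect_lt(unname(sh$statistic["Z"]), -4)
  expect_lt(sh$p.value, 0.001)
  # antisymmetric differences sit at the null center
  x2 <- c(1, 2, 3, 4)
  y2 <- c(1 - 0.5, 2 + 0.5, 3 - 1.5, 4 + 1.5)
  anti <- wilcoxon_signed_rank(x2, y2)
  expect_equal(unname(anti$statistic["Z"]), 0)
  expect_equal(anti$p.value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("spearman_test is exact for small n and monotone-extreme", {
  expect_equal(unname(spearman_test(1:5, c(2, 4, 6, 7, 9))$statistic), 1)
  expect_equal(unname(spearman_test(1:5, 5:1)$statistic), -1)
  metawax:::with_seed(79, {
    x <- rnorm(7)
    y <- rnorm(7)
    for (alt in c("two.sided", "greater", "less")) {
      got <- spearman_test(x, y, alt)
      expect_true(got$exact)
      expect_equal(got$p.value, spearman_enumeration_oracle(x, y, alt),
                   info = alt)
    }
  })
  # cross-check rho against the reference implementation
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 4.5)
  expect_equal(unname(spearman_test(x, y)$statistic),
               unname(stats::cor.test(x, y, method = "spearman")$estimate))
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("ancom_w flags a strongly spiked feature and not identical groups", {
  # copied samples: no test can reject
  base <- metawax:::with_seed(80, matrix(rlnorm(6 * 10), 6, 10))
  x <- rbind(base, base)
  g <- rep(c("A", "B"), each = 6)
  res <- ancom_w(x, g)
  expect_true(all(!res$detected))
  expect_true(all(res$W == 0))
  # 10-fold spike in one feature is detected with maximal W
  sp <- metawax:::with_seed(81, matrix(rlnorm(12 * 20, meanlog = 2), 12, 20))
  sp[1:6, 7] <- sp[1:6, 7] * 10
  res2 <- ancom_w(sp, g)
  expect_true(res2$detected[7])
  expect_equal(res2$W[7], max(res2$W))
  expect_error(ancom_w(sp[, 1, drop = FALSE], g), "2 features")
  expect_error(ancom_w(sp, rep(c("A", "B", "C"), 4)), "two groups")
})
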