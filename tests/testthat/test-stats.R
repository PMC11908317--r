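test_that("two-sided FET matches the hypergeometric enumeration oracle", {
  # the three published disease-contrast tables, pinned against the
  # enumeration oracle (values computed independently before the build)
  kabuki <- rbind(c(8L, 17L), c(55L, 8L))
  expect_equal(fisherExactTest(kabuki), 7.4065248326e-07, tolerance = 1e-9)
  expect_equal(fisherExactTest(kabuki), fetOracle2x2(kabuki), tolerance = 1e-12)
  ks2 <- rbind(c(14L, 4L), c(7L, 18L))
  expect_equal(fisherExactTest(ks2), 1.9429988943e-03, tolerance = 1e-9)
  cdls <- rbind(c(37L, 8L), c(2L, 7L))
  expect_equal(fisherExactTest(cdls), 9.4478473497e-04, tolerance = 1e-9)
})

test_that("symmetric and degenerate tables give p = 1", {
  expect_equal(fisherExactTest(rbind(c(5L, 5L), c(5L, 5L))), 1)
  expect_equal(fisherExactTest(rbind(c(0L, 0L), c(3L, 4L))), 1)  # zero row
  expect_equal(fisherExactTest(rbind(c(3L, 0L), c(4L, 0L))), 1)  # zero column
})

test_that("3x2 exact test agrees with Freeman-Halton enumeration", {
  for (s in 1:30) {
    tab <- randomTable(3L, maxTotal = 40L, seed = s)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExactTest(tab), freemanHaltonOracle(tab),
                 tolerance = 1e-9, label = paste("table seed", s))
  }
})

test_that("2x2 FET agrees with the Freeman-Halton path restricted to k = 2", {
  for (s in 1:50) {
    tab <- randomTable(2L, maxTotal = 40L, seed = s + 1000)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExactTest(tab), freemanHaltonOracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment follows the definitional step-up", {
  expect_equal(adjustPvalues(0.04, "BH"), 0.04)  # m = 1 identity
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  for (s in 1:20) {
    p <- withSeed(s, runif(sample(1:30, 1)))
    expect_equal(adjustPvalues(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("correction methods respect their dominance ordering", {
  for (s in 1:10) {
    p <- withSeed(s + 50, runif(15))
    bonf <- adjustPvalues(p, "BONFERRONI")
    holm <- adjustPvalues(p, "HOLM")
    expect_true(all(bonf >= holm - 1e-12))
    expect_true(all(holm >= p - 1e-12))
    expect_true(all(adjustPvalues(p, "SIDAK") >=
                      adjustPvalues(p, "HOLM_SIDAK") - 1e-12))
    expect_identical(adjustPvalues(p, "NONE"), p)
  }
  expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Sidak-family and adaptive two-stage corrections match the reference", {
  # reference adjusted values computed with an independent implementation
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696)
  expect_equal(adjustPvalues(p, "TWO_STAGE_BH")[1:7],
               c(0.019, 0.076, 0.1596, 0.1596, 0.1596, 0.19, 0.200857142857),
               tolerance = 1e-9)
  expect_equal(adjustPvalues(p, "FDR_TSBKY")[1:7],
               c(0.01995, 0.0798, 0.16758, 0.16758, 0.16758, 0.1995, 0.2109),
               tolerance = 1e-9)
  expect_equal(adjustPvalues(p, "SIDAK")[1:3],
               c(0.01981113517, 0.148404332915, 0.548697485389),
               tolerance = 1e-9)
  expect_equal(adjustPvalues(p, "HOLM_SIDAK")[1:4],
               c(0.01981113517, 0.141536625922, 0.511324036366, 0.511324036366),
               tolerance = 1e-9)
})

test_that("Mann-Whitney U: exchangeable groups and the minimal attainable p", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # fully separated n = 3 vs 3: the most extreme of the 20 splits, both tails
  res <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p, 2 / 20)
  expect_equal(res$U, 0)
})

test_that("Mann-Whitney exact regime matches the permutation oracle", {
  for (s in 1:25) {
    ab <- withSeed(s + 300, {
      nA <- sample(2:6, 1); nB <- sample(2:6, 1)
      list(a = sample(1:100, nA), b = sample(setdiff(1:100, 1:50), nB))
    })
    if (anyDuplicated(c(ab$a, ab$b))) next
    expect_equal(mannWhitneyU(ab$a, ab$b)$p,
                 mwuPermutationOracle(ab$a, ab$b), tolerance = 1e-9)
  }
})

test_that("t test matches the closed form and is scale invariant", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  # pooled-variance Student form by hand
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  pHand <- 2 * pt(abs(tHand), df = 4, lower.tail = FALSE)
  res <- studentTTest(a, b)
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$p, pHand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  scaled <- studentTTest(a * 7, b * 7)
  expect_equal(scaled$t, res$t, tolerance = 1e-12)
  identical <- studentTTest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(identical$t, 0)
  expect_equal(identical$p, 1)
})

test_that("logrank matches direct risk-table tabulation", {
  a <- data.frame(duration = c(1, 2), event = TRUE)
  b <- data.frame(duration = c(3, 4), event = TRUE)
  res <- logrankTest(a, b)
  oracle <- logrankOracle(a, b)
  expect_equal(res$chi2, oracle$chi2, tolerance = 1e-9)
  expect_equal(res$p, oracle$p, tolerance = 1e-9)
  # identical groups: no signal
  same <- data.frame(duration = c(1, 3, 5), event = c(TRUE, FALSE, TRUE))
  resSame <- logrankTest(same, same)
  expect_equal(resSame$chi2, 0, tolerance = 1e-12)
  expect_equal(resSame$p, 1, tolerance = 1e-12)
})

test_that("logrank at-risk sets handle censoring-only groups", {
  cens <- data.frame(duration = c(2, 4, 10), event = FALSE)
  ev <- data.frame(duration = c(3, 8, 9), event = TRUE)
  res <- logrankTest(cens, ev)
  oracle <- logrankOracle(cens, ev)
  expect_equal(res$chi2, oracle$chi2, tolerance = 1e-9)
  expect_error(logrankTest(cens, cens), "no events")
})

test_that("tests are invariant to the ordering of inputs", {
  a <- withSeed(9, rnorm(12)); b <- withSeed(10, rnorm(15))
  expect_equal(mannWhitneyU(a, b)$p, mannWhitneyU(rev(a), sample(b))$p)
  expect_equal(studentTTest(a, b)$p, studentTTest(rev(a), rev(b))$p)
  surv <- data.frame(duration = abs(a) + 1, event = a > 0)
  surv2 <- surv[rev(seq_len(nrow(surv))), ]
  ev <- data.frame(duration = abs(b) + 1, event = TRUE)
  expect_equal(logrankTest(surv, ev)$chi2, logrankTest(surv2, ev)$chi2)
})

test_that("Kaplan-Meier estimates start at one and never increase", {
  d <- data.frame(duration = c(1, 2, 2, 3, 5, 8),
                  event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  km <- kaplanMeierTable(d)
  expect_true(all(km$survival <= 1 + 1e-12))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_equal(km$nRisk[1], 6)
})
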