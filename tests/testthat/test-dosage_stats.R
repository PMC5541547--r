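test_that("zaSummary reproduces hand-computed ratios", {
  s <- zaSummary(c(1, 2, 4), c(1, 2), "toy")
  expect_equal(s$median_za, 1.5 / 2)
  expect_equal(s$mean_za, 1.5 / (7 / 3))
  expect_identical(c(s$n_A, s$n_Z), c(3L, 2L))
  expect_equal(s$mean_za, s$mean_Z / s$mean_A, tolerance = 1e-9)
  expect_equal(s$median_za, s$median_Z / s$median_A, tolerance = 1e-9)

  same <- zaSummary(c(1, 2, 3), c(1, 2, 3), "id")
  expect_equal(same$mean_za, 1)
  expect_equal(same$median_za, 1)
  expect_equal(same$p_A_vs_Z, 1)

  expect_error(zaSummary(numeric(0), 1), "non-empty")
  expect_error(zaSummary(c(1, 0), c(1, 2)), "positive")
})

test_that("median Z:A commutes with monotone transforms for odd lengths", {
  set.seed(3)
  for (i in 1:10) {
    a <- rlnorm(2 * sample(3:30, 1) + 1, 1, 1)
    z <- rlnorm(2 * sample(3:30, 1) + 1, 0.5, 1)
    linear <- median(z) / median(a)
    viaLog <- 2^(median(log2(z))) / 2^(median(log2(a)))
    expect_equal(viaLog, linear, tolerance = 1e-12)
  }
})

test_that("mfRatios pairs genes and reports both scales", {
  r <- mfRatios(c(g1 = 2, g2 = 1), c(g1 = 1, g2 = 1))
  expect_equal(unname(r$ratio), c(2, 1))
  expect_equal(unname(r$log2_ratio), c(1, 0))
  expect_equal(median(mfRatios(c(4, 1, 6, 2), c(2, 2, 2, 2))$ratio),
               median(c(2, 0.5, 3, 1)))
  expect_error(mfRatios(1:3, 1:2), "length")
})

test_that("mfSummary composes the ratio-of-medians and its tests", {
  s <- mfSummary(c(2, 2.2, 1.8), c(1, 1.1, 0.9), stage = "96h")
  expect_equal(s$za_ratio_of_medians, 2 / 1, tolerance = 1e-9)
  expect_equal(s$median_mf_Z / s$median_mf_A, s$za_ratio_of_medians,
               tolerance = 1e-9)
  expect_true(is.na(s$p_Z_MvsF))  # no per-sex vectors supplied

  # identical ratio vectors: quotient 1, A-vs-Z test sees no difference
  r <- rlnorm(25)
  same <- mfSummary(r, r, "x")
  expect_equal(same$za_ratio_of_medians, 1)
  expect_equal(same$p_AvsZ_dist, 1)

  # scaling both sexes by a common constant changes nothing
  m <- rlnorm(30, 1, 0.5); f <- rlnorm(30, 1, 0.5)
  s1 <- mfSummary(m / f, rlnorm(50), "x",
                  log2FpkmZ = list(male = log2(m), female = log2(f)))
  s2 <- mfSummary((7 * m) / (7 * f), rlnorm(50), "x",
                  log2FpkmZ = list(male = log2(7 * m),
                                   female = log2(7 * f)))
  expect_equal(s1$median_mf_Z, s2$median_mf_Z, tolerance = 1e-12)
  expect_equal(s1$p_Z_MvsF, s2$p_Z_MvsF, tolerance = 1e-9)
})

test_that("mwuTest matches its spec examples and handles ties", {
  t1 <- mwuTest(c(1, 2), c(3, 4))
  expect_equal(t1$U, 0)
  expect_equal(t1$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(t1$method, "exact")

  t2 <- mwuTest(c(1, 3, 5), c(2, 4, 6))
  expect_equal(t2$U, 3)
  expect_equal(t2$p_value, 0.7, tolerance = 1e-12)

  # identical multisets: symmetric tails double to exactly 1
  t3 <- mwuTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t3$p_value, 1)
  expect_equal(t3$U, 4.5)  # 9 cross pairs, all but 3 exact ties

  # one-sided alternatives match the enumeration oracle directly
  x <- c(1, 2, 6); y <- c(3, 4, 5)
  expect_equal(mwuTest(x, y, "less")$p_value, mwuOracle(x, y, "less"),
               tolerance = 1e-12)
  expect_equal(mwuTest(x, y, "greater")$p_value,
               mwuOracle(x, y, "greater"), tolerance = 1e-12)

  expect_error(mwuTest(numeric(0), 1), "non-empty")
})

test_that("mwuTest agrees with enumeration under ties and approximation at scale", {
  # tied data, small n: exact path must equal the assignment enumeration
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:4, sample(2:6, 1), replace = TRUE)
    y <- sample(1:4, sample(2:6, 1), replace = TRUE)
    for (alt in c("two_sided", "less", "greater")) {
      expect_equal(mwuTest(x, y, alt)$p_value, mwuOracle(x, y, alt),
                   tolerance = 1e-12,
                   info = sprintf("alt=%s x=%s y=%s", alt,
                                  paste(x, collapse = ","),
                                  paste(y, collapse = ",")))
    }
  }
  # large tie-free samples: normal approximation close to wilcox.test
  x <- rnorm(60); y <- rnorm(75, 0.4)
  got <- mwuTest(x, y)
  expect_identical(got$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
})

test_that("deltaCtFold computes 2^-ddCt with the female calibrator at 1", {
  expect_equal(deltaCtFold(20, 18, 22, 20), 1)
  expect_equal(deltaCtFold(20, 18, 21, 18), 2)
  expect_equal(deltaCtFold(22, 18, 20, 18), 0.25)
  expect_error(deltaCtFold(NA, 1, 1, 1))
})
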