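makeCounts <- function(m, lengths = NULL, ...) {
  DosageExperiment(m, unit = "raw_counts",
                   sampleData = toyMeta(colnames(m), ...),
                   geneLengths = lengths)
}

test_that("computeFpkm applies the closed-form FPKM formula", {
  m <- matrix(c(10L, 10L, 0L), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  de <- makeCounts(m, lengths = c(g1 = 1000, g2 = 2000, g3 = 500))
  fp <- computeFpkm(de, librarySizes = c(s1 = 1e6))
  expect_identical(exprUnit(fp), "fpkm")
  expect_equal(unname(assay(fp)[, 1]), c(10, 5, 0))

  # library sizes default to column sums
  fp2 <- computeFpkm(de)
  expect_equal(assay(fp2)["g1", 1], 1e9 * 10 / (1000 * 20))

  noLen <- makeCounts(m)
  expect_error(computeFpkm(noLen), "gene length")
})

test_that("computeFpkm is linear in counts, inverse-linear in length and depth", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(3:30, 1)
    m <- matrix(rpois(n * 2, 50), n, 2,
                dimnames = list(sprintf("g%02d", 1:n), c("s1", "s2")))
    len <- setNames(sample(200:5000, n), rownames(m))
    N <- c(s1 = 1e6, s2 = 2e6)
    base <- assay(computeFpkm(makeCounts(m, len), N))
    tripled <- assay(computeFpkm(makeCounts(m * 3L, len), N))
    expect_equal(tripled, 3 * base, tolerance = 1e-12)
    halfLen <- assay(computeFpkm(makeCounts(m, len * 2), N))
    expect_equal(halfLen, base / 2, tolerance = 1e-12)
    deeper <- assay(computeFpkm(makeCounts(m, len), N * 10))
    expect_equal(deeper, base / 10, tolerance = 1e-12)
  }
})

test_that("averageReplicates collapses technical replicates by the mean", {
  m <- matrix(c(1, 0, 3, 0, 7.2, 5), 2, 3,
              dimnames = list(c("g1", "g2"),
                              c("m78_r1", "m78_r2", "f78_r1")))
  de <- DosageExperiment(m, "fpkm", data.frame(
    sample_id = colnames(m),
    sex = c("male", "male", "female"),
    stage = "78h", replicate = c(1L, 2L, 1L)))
  avg <- averageReplicates(de)
  expect_identical(ncol(avg), 2L)
  expect_equal(assay(avg)["g1", "male_78h"], 2)    # mean(1, 3)
  expect_equal(assay(avg)["g2", "male_78h"], 0)    # mean(0, 0)
  expect_equal(assay(avg)["g1", "female_78h"], 7.2)  # singleton unchanged
})

test_that("true-expression filtering matches both universes", {
  m <- matrix(c(0, 0.5, 1, 0, 2,
                1.2, 1.2, 0, 0, 3), 5, 2,
              dimnames = list(paste0("g", 1:5), c("m", "f")))
  de <- DosageExperiment(m, "fpkm", data.frame(
    sample_id = c("m", "f"), sex = c("male", "female"),
    stage = "96h", replicate = 1L))
  perSample <- filterTrueExpression(de, "per_sample")
  expect_identical(names(perSample$m), c("g2", "g3", "g5"))
  expect_identical(names(perSample$f), c("g1", "g2", "g5"))
  both <- filterTrueExpression(de, "both_sexes")
  # expressed in BOTH sexes: g2 (0.5/1.2) and g5; g1 (M=0) excluded
  expect_identical(rownames(both[["96h"]]), c("g2", "g5"))
  # idempotent: re-filtering the filtered object changes nothing
  expect_identical(rownames(filterTrueExpression(both[["96h"]],
                                                 "both_sexes")[["96h"]]),
                   rownames(both[["96h"]]))
})

test_that("the four-sample low-count filter keeps only genes >= 4 everywhere", {
  m <- matrix(c(4L, 3L, 0L,  4L, 10L, 0L,  4L, 10L, 0L,  4L, 10L, 0L),
              3, 4, dimnames = list(c("g1", "g2", "g3"),
                                    c("m1", "m2", "f1", "f2")))
  de <- DosageExperiment(m, "raw_counts", data.frame(
    sample_id = colnames(m), sex = c("male", "male", "female", "female"),
    stage = "96h", replicate = c(1L, 2L, 1L, 2L)))
  kept <- filterLowCounts(de, comparisonSamples = colnames(m))
  expect_identical(rownames(kept), "g1")  # 4 is not "less than four"
  # idempotent
  expect_identical(rownames(filterLowCounts(kept, colnames(m))), "g1")
  expect_error(filterLowCounts(de, c("m1", "m2", "f1")), "exactly 4")
})

test_that("TMM factors are 1 for identical and genewise-scaled libraries", {
  set.seed(9)
  base <- rpois(500, 60) + 1L
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("g%03d", seq_len(500))
  f <- tmmFactors(makeCounts(m), reference = "s1")
  expect_equal(unname(f$factors), c(1, 1), tolerance = 1e-12)
  # exact genewise doubling is absorbed by the library-size term
  m2 <- cbind(s1 = base, s2 = base * 2L)
  rownames(m2) <- rownames(m)
  f2 <- tmmFactors(makeCounts(m2), reference = "s1")
  expect_equal(unname(f2$factors), c(1, 1), tolerance = 1e-12)
})

test_that("TMM factors are invariant to library scaling and multiply to 1", {
  m <- simCountPair(800, deFraction = 0.1, fold = 3, seed = 21)
  de <- makeCounts(m)
  f <- tmmFactors(de, reference = "s1")
  expect_equal(prod(f$factors), 1, tolerance = 1e-9)
  scaled <- m
  scaled[, 2] <- scaled[, 2] * 5L
  fScaled <- tmmFactors(makeCounts(scaled), reference = "s1")
  expect_equal(fScaled$factors, f$factors, tolerance = 1e-10)
  # genes up in s2 inflate its library size, so after trimming them the
  # remaining genes pull its factor below 1
  expect_lt(f$factors[["s2"]] / f$factors[["s1"]], 1)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  m <- simCountPair(1200, deFraction = 0.05, fold = 4, seed = 31)
  mine <- tmmFactors(makeCounts(m), reference = "s1")
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  expect_equal(unname(mine$factors), unname(theirs), tolerance = 1e-10)
})
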